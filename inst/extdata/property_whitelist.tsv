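property	sct_relationship
Affects	Finding site
After-Of	After
Associated-With	Associated with
Caused-By-Agent	Causative agent
Due-To	Due to
Has-Associated-Finding	Associated finding
Has-Associated-Morphology	Associated morphology
Has-Definitional-Manifestation	Has definitional manifestation
Has-Occurrence	Occurrence
Has-Pathological-Process	Pathological process
Interprets	Interprets
IsPartOf	Part of
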