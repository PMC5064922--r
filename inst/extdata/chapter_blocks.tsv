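start	end	label
A00	B99	Certain infectious and parasitic diseases
C00	D49	Neoplasms
D50	D89	Diseases of the blood and blood-forming organs and certain disorders involving the immune mechanism
E00	E89	Endocrine, nutritional and metabolic diseases
F01	F99	Mental, behavioural and neurodevelopmental disorders
G00	G99	Diseases of the nervous system
H00	H59	Diseases of the eye and adnexa
H60	H95	Diseases of the ear and mastoid process
I00	I99	Diseases of the circulatory system
J00	J99	Diseases of the respiratory system
K00	K95	Diseases of the digestive system
L00	L99	Diseases of the skin and subcutaneous tissue
M00	M99	Diseases of the musculoskeletal system and connective tissue
N00	N99	Diseases of the genitourinary system
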