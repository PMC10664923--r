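code	parent	depth	name
II		0	Neoplasms
C64-C68	II	1	Malignant neoplasms of urinary tract
C67	C64-C68	2	Malignant neoplasm of bladder
C67.2	C67	3	Malignant neoplasm of lateral wall of urinary bladder
C67.9	C67	3	Malignant neoplasm of bladder, unspecified
C76-C80	II	1	Malignant neoplasms of ill-defined, secondary and unspecified sites
C77	C76-C80	2	Secondary and unspecified malignant neoplasm of lymph nodes
C78	C76-C80	2	Secondary malignant neoplasm of respiratory and digestive organs
C79	C76-C80	2	Secondary malignant neoplasm of other and unspecified sites
C17	II	2	Malignant neoplasm of small intestine
IV		0	Endocrine, nutritional and metabolic diseases
E10-E14	IV	1	Diabetes mellitus
E11	E10-E14	2	Type 2 diabetes mellitus
IX		0	Diseases of the circulatory system
I10-I15	IX	1	Hypertensive diseases
I10	I10-I15	2	Essential (primary) hypertension
I20-I25	IX	1	Ischaemic heart diseases
I25	I20-I25	2	Chronic ischaemic heart disease
X		0	Diseases of the respiratory system
J40-J47	X	1	Chronic lower respiratory diseases
J43	J40-J47	2	Emphysema
J44	J40-J47	2	Other chronic obstructive pulmonary disease
J45	J40-J47	2	Asthma
XI		0	Diseases of the digestive system
K20-K31	XI	1	Diseases of oesophagus, stomach and duodenum
K21	K20-K31	2	Gastro-oesophageal reflux disease
XIV		0	Diseases of the genitourinary system
N30-N39	XIV	1	Other diseases of the urinary system
N39	N30-N39	2	Other disorders of urinary system
XV		0	Pregnancy, childbirth and the puerperium
O10-O16	XV	1	Oedema, proteinuria and hypertensive disorders in pregnancy
O10	O10-O16	2	Pre-existing hypertension complicating pregnancy
XXI		0	Factors influencing health status and contact with health services
Z80-Z99	XXI	1	Persons with potential health hazards related to family and personal history
Z85	Z80-Z99	2	Personal history of malignant neoplasm
Z85.5	Z85	3	Personal history of malignant neoplasm of urinary tract
Z85.51	Z85.5	4	Personal history of malignant neoplasm of bladder
F17	V	1	Nicotine dependence
V		0	Mental and behavioural disorders
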