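ICD10,CCSR_CATEGORY,CCSR_DESCRIPTION
C67,GEN025,Cancer of bladder
C67.2,GEN025,Cancer of bladder
C67.9,GEN025,Cancer of bladder
C77,NEO070,Secondary malignancies
C78,NEO070,Secondary malignancies
C79,NEO070,Secondary malignancies
C17,NEO030,Cancer of small intestine
E11,END005,Diabetes mellitus type 2
I10,CIR007,Essential hypertension
I25,CIR011,Coronary atherosclerosis and other heart disease
J43,RSP008,Chronic obstructive pulmonary disease
J44,RSP008,Chronic obstructive pulmonary disease
J45,RSP009,Asthma
K21,DIG004,Esophageal disorders
N39,GEN004,Urinary tract infections
F17,MBD027,Tobacco-related disorders
Z85.51,FAC021,Personal history of malignant neoplasm
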