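icd10_prefix,concept
I50,heart_failure
I20,coronary_artery_disease
I21,coronary_artery_disease
I22,coronary_artery_disease
I25,coronary_artery_disease
I60,cerebrovascular_disease
I61,cerebrovascular_disease
I63,cerebrovascular_disease
I64,cerebrovascular_disease
I65,cerebrovascular_disease
I69,cerebrovascular_disease
G45,cerebrovascular_disease
I70,peripheral_arterial_disease
I73,peripheral_arterial_disease
I48,atrial_fibrillation
I10,hypertension
I11,hypertension
E10,diabetes
E11,diabetes
E14,diabetes
F00,dementia
F01,dementia
F02,dementia
F03,dementia
G30,dementia
F32,depression
F33,depression
C,malignant_neoplasm
C77,metastatic_cancer
C78,metastatic_cancer
C79,metastatic_cancer
J44,asthma_copd
J45,asthma_copd
N18,renal_disease
K70,liver_disease
K74,liver_disease
M05,connective_tissue_disease
M06,connective_tissue_disease
M32,connective_tissue_disease
K25,peptic_ulcer
K26,peptic_ulcer
K27,peptic_ulcer
G81,hemiplegia
G82,hemiplegia
W0,falls
W1,falls
R296,falls
M81,osteoporosis
D64,anemia
J18,pneumonia
N39,urinary_tract_infection
A41,sepsis
F05,delirium
M15,arthritis
M16,arthritis
M17,arthritis
K21,gerd
E03,hypothyroidism
E66,obesity
G47,sleep_disorder
R52,chronic_pain
H25,cataract
N40,benign_prostatic_hyperplasia
K59,constipation
E86,dehydration
E87,electrolyte_disorder
L89,pressure_ulcer
R13,dysphagia
H90,hearing_loss
H54,visual_impairment
G20,parkinsons_disease
G40,epilepsy
M10,gout
I35,valvular_heart_disease
I26,venous_thromboembolism
I80,venous_thromboembolism
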