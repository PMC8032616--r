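concept,charlson,description
heart_failure,TRUE,congestive heart failure
coronary_artery_disease,TRUE,coronary artery disease / myocardial infarction
cerebrovascular_disease,TRUE,cerebrovascular disease incl. stroke and TIA
peripheral_arterial_disease,TRUE,peripheral arterial disease
atrial_fibrillation,FALSE,atrial fibrillation
hypertension,FALSE,essential hypertension
diabetes,TRUE,diabetes mellitus
dementia,TRUE,dementia
depression,FALSE,depressive disorder
malignant_neoplasm,TRUE,malignant neoplasm (any site)
metastatic_cancer,TRUE,metastatic solid tumour
asthma_copd,TRUE,asthma or COPD
renal_disease,TRUE,moderate or severe chronic kidney disease
liver_disease,TRUE,mild liver disease
connective_tissue_disease,TRUE,connective tissue disease
peptic_ulcer,TRUE,peptic ulcer disease
hemiplegia,TRUE,hemiplegia or paraplegia
falls,FALSE,fall or fall-related injury
osteoporosis,FALSE,osteoporosis
anemia,FALSE,anemia
pneumonia,FALSE,pneumonia
urinary_tract_infection,FALSE,urinary tract infection
sepsis,FALSE,sepsis
delirium,FALSE,delirium
arthritis,FALSE,osteoarthritis or inflammatory arthritis
gerd,FALSE,gastro-esophageal reflux disease
hypothyroidism,FALSE,hypothyroidism
obesity,FALSE,obesity
sleep_disorder,FALSE,sleep disorder
chronic_pain,FALSE,chronic pain
cataract,FALSE,cataract
benign_prostatic_hyperplasia,FALSE,benign prostatic hyperplasia
constipation,FALSE,constipation
dehydration,FALSE,dehydration
electrolyte_disorder,FALSE,electrolyte disorder
pressure_ulcer,FALSE,pressure ulcer
dysphagia,FALSE,dysphagia
hearing_loss,FALSE,hearing loss
visual_impairment,FALSE,visual impairment
parkinsons_disease,FALSE,Parkinson's disease
epilepsy,FALSE,epilepsy
gout,FALSE,gout
valvular_heart_disease,FALSE,valvular heart disease
venous_thromboembolism,FALSE,venous thromboembolism
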