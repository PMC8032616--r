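concept,weight
coronary_artery_disease,1
heart_failure,1
peripheral_arterial_disease,1
cerebrovascular_disease,1
dementia,1
asthma_copd,1
connective_tissue_disease,1
peptic_ulcer,1
liver_disease,1
diabetes,1
hemiplegia,2
renal_disease,2
malignant_neoplasm,2
metastatic_cancer,6
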