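sample_id,cell_type,time_h,sort_delay_min,replicate,metabolite,mass_shift,fraction,corrected
protein_cancer_t24_d0_r1,cancer,24,0,1,asp,0,0.65382041836093,FALSE
protein_cancer_t24_d0_r1,cancer,24,0,1,asp,1,0.213852189453803,FALSE
protein_cancer_t24_d0_r1,cancer,24,0,1,asp,2,0.103659346518654,FALSE
protein_cancer_t24_d0_r1,cancer,24,0,1,asp,3,0.0242797876143107,FALSE
protein_cancer_t24_d0_r1,cancer,24,0,1,asp,4,0.00438615155726757,FALSE
protein_cancer_t24_d0_r1,cancer,24,0,1,asp,5,2.10649503424293e-06,FALSE
protein_cancer_t24_d0_r1,cancer,24,0,1,asp,6,0,FALSE
protein_cancer_t24_d0_r1,cancer,24,0,1,asp,7,0,FALSE
protein_cancer_t24_d0_r1,cancer,24,0,1,glu,0,0.660238752698133,FALSE
protein_cancer_t24_d0_r1,cancer,24,0,1,glu,1,0.207713497629883,FALSE
protein_cancer_t24_d0_r1,cancer,24,0,1,glu,2,0.102353398589956,FALSE
protein_cancer_t24_d0_r1,cancer,24,0,1,glu,3,0.0227001874164869,FALSE
protein_cancer_t24_d0_r1,cancer,24,0,1,glu,4,0.00424038684792051,FALSE
protein_cancer_t24_d0_r1,cancer,24,0,1,glu,5,0.00263610479645376,FALSE
protein_cancer_t24_d0_r1,cancer,24,0,1,glu,6,0,FALSE
protein_cancer_t24_d0_r1,cancer,24,0,1,glu,7,0.000117672021166835,FALSE
protein_cancer_t24_d0_r1,cancer,24,0,1,glu,8,0,FALSE
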