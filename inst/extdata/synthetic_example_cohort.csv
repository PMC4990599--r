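id,age,menopausal_status,he4_pmol_l,ca125_u_ml,label
S01,87,post,990.6,3190,malignant
S02,46.2,pre,125.2,181.7,malignant
S03,56.6,post,1141,531.8,malignant
S04,44.1,pre,37.1,39.7,benign
S05,19.4,pre,51.8,22,benign
S06,43.7,pre,25.5,12.3,benign
S07,56,post,49.6,8.1,benign
S08,33.6,pre,53.9,38.4,benign
S09,30.2,pre,49.7,23.4,benign
S10,49.4,pre,117.2,24,benign
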