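name,kind,member
hypertension,diagnosis,401.9
coronary_artery_disease,diagnosis,414.01
diabetes_mellitus,diagnosis,250.00
osteoarthritis,diagnosis,715.90
congestive_heart_failure,diagnosis,428.0
chronic_kidney_disease,diagnosis,585.9
cerebrovascular_disease,diagnosis,437.9
unstable_angina,diagnosis,411.1
hemorrhoids,diagnosis,455.6
stable_angina,diagnosis,413.9
stroke,diagnosis,434.91
myopathies,diagnosis,359.9
migraine_headache,diagnosis,346.90
diabetic_neuropathy,diagnosis,357.2
myocardial_infarction,diagnosis,410.90
hyperkalemia,diagnosis,276.7
fibromyalgia,diagnosis,729.1
parkinsons_disease,diagnosis,332.0
rheumatoid_arthritis,diagnosis,714.0
irritable_bowel_syndrome,diagnosis,564.1
colitis,diagnosis,558.9
gastroparesis,diagnosis,536.3
hyperparathyroidism,diagnosis,252.00
hypercalcemia,diagnosis,275.42
multiple_sclerosis,diagnosis,340
gi_perforation,diagnosis,569.83
rectal_prolapse,diagnosis,569.1
rectocele,diagnosis,618.04
megacolon,diagnosis,564.7
impaction,diagnosis,560.32
anal_fissure,diagnosis,565.0
anticoagulants_bl110,drug_class,BL110
antilipemic_cv350,drug_class,CV350
beta_blockers_cv100,drug_class,CV100
quinolones_am400,drug_class,AM400
erythromycins_am200,drug_class,AM200
antihistamines_ah000,drug_class,AH000
genitourinary_gu000,drug_class,GU000
insulin_hs501,drug_class,HS501
androgens_hs100,drug_class,HS100
antipsychotics_cn700,drug_class,CN700
nsaid_ms102,drug_class,MS102
topical_analgesics_de650,drug_class,DE650
antigout_ms400,drug_class,MS400
revascularization_cabg,procedure,36.10
constipation_dx,diagnosis,564.00
constipation_dx,diagnosis,564.01
constipation_dx,diagnosis,564.09
constipation_proc,procedure,96.38
constipation_proc,procedure,96.39
cancer,diagnosis,153.3
cancer,diagnosis,162.9
cancer,diagnosis,174.9
cancer,diagnosis,185
cancer,diagnosis,233.0
opioid,drug_ingredient,OXYCODONE
opioid,drug_ingredient,HYDROCODONE
opioid,drug_ingredient,MORPHINE
opioid,drug_ingredient,TRAMADOL
opioid,drug_ingredient,FENTANYL
laxative,drug_class,GA108
laxative,drug_class,GA109
laxative,drug_class,GA110
constipating,drug_ingredient,FERROUS SULFATE
constipating,drug_ingredient,OXYBUTYNIN
constipating,drug_ingredient,DIPHENHYDRAMINE
constipating,drug_ingredient,AMITRIPTYLINE
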