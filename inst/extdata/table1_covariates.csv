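covariate_id,category,description,unit
foodscreen,allergen_screen,FoodScreen (5 food allergens),kUA/L
phadiatop,allergen_screen,Phadiatop (15 aeroallergens),kUA/L
total_serum_ige,allergen_screen,Total Serum IgE,kU/L
c_reactive_protein,blood_chemistry,C-reactive Protein,mg/ml
albumin,blood_chemistry,Albumin,g/dL
alkaline_phosphatase,blood_chemistry,Alkaline Phosphatase,IU/L
sgpt,blood_chemistry,Serum Glutamic Pyruvic Transaminase,IU/L
ast,blood_chemistry,Serum Aspartate Aminotransferase (AST),IU/L
sgot,blood_chemistry,Serum Glutamic-Oxaloacetic Transaminase (SGOT),IU/L
albumin_globulin_ratio,blood_chemistry,Albumin/Globulin ratio,
total_bilirubin,blood_chemistry,Serum Total Bilirubin,mg/dL
blood_urea_nitrogen,blood_chemistry,Serum Blood Urea Nitrogen,mg/dL
bun_creatinine_ratio,blood_chemistry,Serum Blood Urea Nitrogen Creatinine Ratio,
calcium,blood_chemistry,Serum Calcium,mg/dL
chloride,blood_chemistry,Serum Chloride,mmol/L
creatinine,blood_chemistry,Serum Creatinine,mg/dL
ferritin,blood_chemistry,Serum Ferritin,ng/ml
fibrinogen,blood_chemistry,Serum Fibrinogen,mg/dL
ggt,blood_chemistry,Serum Gamma-Glutamyl Transpeptidase (GGT),IU/L
total_globulin,blood_chemistry,Serum Total Globulin,g/dL
hematocrit,blood_chemistry,Blood Hematocrit,%
hemoglobin,blood_chemistry,Blood Hemoglobin,g/dL
iron,blood_chemistry,Serum Iron,ug/dl
lactate_dehydrogenase,blood_chemistry,Serum Lactate Dehydrogenase,IU/L
leptin,blood_chemistry,Plasma Leptin,ng/ml
glycated_hemoglobin,blood_chemistry,Serum Glycated Hemoglobin,%
glucose,blood_chemistry,Serum Glucose,mg/dL
potassium,blood_chemistry,Potassium,mmol/L
urine_creatinine,blood_chemistry,Urine Creatinine,mg/dl
arachidonic_acid,blood_chemistry,Serum Arachidonic Acid,ug/ml
osmolality,blood_chemistry,Serum Osmolality,mOsmol/kg
phospholipids,blood_chemistry,Serum Phospholipids Concentration,mg/dL
phosphorus,blood_chemistry,Serum Phosphorus,mg/dL
total_protein,blood_chemistry,Serum Total Protein,g/dL
sodium,blood_chemistry,Sodium,mmol/L
oxygen_saturation,blood_chemistry,BP Oxygen Saturation (Dissolved Oxygen),%
wbc_count,CBC,White Blood Cell Count,K/uL
basophil_pct,CBC,Basophil percent of sum White Blood Cells,%
eosinophil_pct,CBC,Eosinophil percent of sum White Blood Cells,%
lymphocyte_pct,CBC,Lymphocyte percent of sum White Blood Cells,%
monocyte_pct,CBC,Monocyte percent of sum White Blood Cells,%
neutrophil_pct,CBC,Neutrophils percent of sum White Blood Cells,%
age,clinic,Subject Age,years
height,clinic,Subject Height,cm
bmi,clinic,Subject Body Mass Index,kg/m2
weight,clinic,Subject Weight,kg
diastolic_bp,clinic,Mean of first two Diastolic Blood Pressure Measurements,mmHg
systolic_bp,clinic,Mean of first two Systolic Blood Pressure Measurements,mmHg
pulse,clinic,Blood Pressure Pulse,beats/min
rbc_count,hematology,Red Blood Cell Count,M/uL
platelet_count,hematology,Platelet Count,K/uL
mch,hematology,Mean Corpuscular Hemoglobin,pg
mchc,hematology,Mean Corpuscular Hemoglobin Concentration,g/dL
mcv,hematology,Mean Corpuscular Volume,fL
rdw,hematology,Red Blood Cell Distribution Width,%
interleukin_4,inflammatory,Interleukin-4,pg/ml
antioxidant_status,inflammatory,Serum Total Antioxidant Status,mmol/L
uibc,inflammatory,Serum Unbound Iron-Binding Capacity,ug/dl
uric_acid,inflammatory,Serum Uric Acid,mg/dL
ros,inflammatory,Plasma Average of Reactive Oxygen Species Measurements minus Control,RLU
hdl,lipids,High Density Lipoprotein,mg/dL
ldl,lipids,Low Density Lipoprotein,mg/dL
tc_hdl_ratio,lipids,Total Cholesterol to High Density Lipoprotein Ratio,
total_cholesterol,lipids,Total Cholesterol,mg/dL
triglycerides,lipids,Serum Triglycerides,mg/dL
vldl,lipids,Very Low Density Lipoprotein,mg/dL
fef_25_75,lung_function,Forced Expiratory Flow Between 25% and 75% of Forced Vital Capacity,
feno,lung_function,Fractional Exhaled Nitric Oxide,ppb
fev_fvc_ratio,lung_function,Forced Expiratory Volume Ratio to Forced Vital Capacity,%
pef,lung_function,Peak Expiratory Flow,L/min
serum_alternaria_alternata,serum_allergen,Serum Alternaria Alternata,kUA/L
serum_aspergillus_fumigatus,serum_allergen,Serum Aspergillus Fumigatus,kUA/L
serum_cat_dander,serum_allergen,Serum Cat Dander Epithelium,kUA/L
serum_cladosporium_herbarum,serum_allergen,Serum Cladosporium Herbarum,kUA/L
serum_derm_farinae,serum_allergen,Serum Dermatophagoides Farinae Dust Mite,kUA/L
serum_derm_pteronyssinus,serum_allergen,Serum Dermatophagoides Pteronyssinus Dust Mite,kUA/L
serum_dog_dander,serum_allergen,Serum Dog Dander,kUA/L
serum_german_cockroach,serum_allergen,Serum German Cockroach,kUA/L
serum_mouse_urine_protein,serum_allergen,Serum Mouse Urine Protein,kUA/L
serum_penicillium_notatum,serum_allergen,Serum Penicillium Notatum,kUA/L
serum_rat_urine_protein,serum_allergen,Serum Rat Urine Protein,kUA/L
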