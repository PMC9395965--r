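name,label,group,value,dist,low,high
cost_sintilimab,Sintilimab (200 mg vial),drug_price,441.69,constant,353.36,441.69
cost_pembrolizumab,Pembrolizumab (100 mg vial),drug_price,2783.78,constant,2227.02,2783.78
cost_paclitaxel_high,Paclitaxel high dose (100 mg),drug_price,26.26,gamma,21.00,31.40
cost_paclitaxel_low,Paclitaxel low dose (100 mg),drug_price,11.02,gamma,10.56,11.47
cost_carboplatin_high,Carboplatin high dose (100 mg),drug_price,8.04,gamma,4.72,8.37
cost_carboplatin_low,Carboplatin low dose (100 mg),drug_price,4.72,gamma,3.77,5.66
cost_gemcitabine,Gemcitabine (200 mg vial),drug_price,9.32,gamma,1.24,9.94
cost_cisplatin_low,Cisplatin low dose (30 mg),drug_price,1.86,gamma,1.13,2.96
cost_cisplatin_high,Cisplatin high dose (30 mg),drug_price,2.66,gamma,1.18,6.80
cost_subsequent,Subsequent treatment (per progressor),other_cost,4351.23,constant,3480.98,5221.47
cost_eol,End-of-life care,other_cost,2298.86,gamma,892.71,6140.16
cost_imaging,Imaging examination,followup_cost,57.48,gamma,45.99,68.98
cost_blood_chemistry,Blood chemistry,followup_cost,46.50,gamma,37.20,55.80
cost_blood_routine,Blood routine,followup_cost,3.11,gamma,2.49,3.73
cost_urine_routine,Urine routine,followup_cost,0.62,gamma,0.50,0.75
cost_diagnosis,Diagnosis,service_cost,3.11,gamma,1.55,4.66
cost_iv_injection,Intravenous injection,service_cost,1.71,gamma,1.55,2.14
cost_nursing,Nursing,service_cost,3.73,gamma,2.98,4.47
cost_hospitalization,Hospitalization (per day),service_cost,6.53,gamma,5.22,7.83
cost_ae_neutropenia,Neutrophil count decreased (per episode),ae_cost,115.01,gamma,51.11,357.80
cost_ae_leukopenia,White blood cell count decreased (per episode),ae_cost,115.01,gamma,51.11,357.80
cost_ae_thrombocytopenia,Platelet count decreased (per episode),ae_cost,1505.92,gamma,1240.17,1771.67
cost_ae_anemia,Anemia (per episode),ae_cost,138.75,gamma,106.73,160.10
inc_active_neutropenia,Neutropenia incidence (sintilimab arm),ae_incidence,0.151,beta,0.12,0.18
inc_active_leukopenia,Leukopenia incidence (sintilimab arm),ae_incidence,0.117,beta,0.09,0.14
inc_active_anemia,Anemia incidence (sintilimab arm),ae_incidence,0.128,beta,0.10,0.15
inc_active_thrombocytopenia,Thrombocytopenia incidence (sintilimab arm),ae_incidence,0.134,beta,0.11,0.16
inc_comp_neutropenia,Neutropenia incidence (pembrolizumab arm),ae_incidence,0.23,beta,0.18,0.28
inc_comp_leukopenia,Leukopenia incidence (pembrolizumab arm),ae_incidence,0,constant,0,0
inc_comp_anemia,Anemia incidence (pembrolizumab arm),ae_incidence,0.158,beta,0.13,0.19
inc_comp_thrombocytopenia,Thrombocytopenia incidence (pembrolizumab arm),ae_incidence,0.083,beta,0.07,0.10
dur_neutropenia,Neutropenia duration (days),ae_duration,4.19,normal,3.35,5.03
dur_leukopenia,Leukopenia duration (days),ae_duration,4.5,normal,3.60,5.40
dur_anemia,Anemia duration (days),ae_duration,6.83,normal,5.46,8.20
dur_thrombocytopenia,Thrombocytopenia duration (days),ae_duration,47.29,normal,37.83,56.75
u_pf,Utility progression-free,utility,0.804,beta,0.643,0.965
u_pp,Utility post-progression,utility,0.321,beta,0.257,0.385
disu_neutropenia,Neutropenia disutility,disutility,0.20,beta,0.16,0.24
disu_leukopenia,Leukopenia disutility,disutility,0.20,beta,0.16,0.24
disu_thrombocytopenia,Thrombocytopenia disutility,disutility,0.11,beta,0.09,0.13
disu_anemia,Anemia disutility,disutility,0.07,beta,0.06,0.09
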