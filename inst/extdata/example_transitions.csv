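"site_id","study_phase","protein_id","peptide_id","transition_id","label","sample_id","sample_role","theoretical_conc","replicate","peak_area","retention_time"
"site1","I","PROT1","PEP1","PEP1.t1","analyte","C01","curve_point",1,1,844.56,NA
"site1","I","PROT1","PEP1","PEP1.t1","analyte","C02","curve_point",5,1,3712.65,NA
"site1","I","PROT1","PEP1","PEP1.t1","analyte","C03","curve_point",20,1,13740.09,NA
"site1","I","PROT1","PEP1","PEP1.t1","analyte","C04","curve_point",100,1,67038.18,NA
"site1","I","PROT1","PEP1","PEP1.t2","analyte","C01","curve_point",1,1,704.73,NA
"site1","I","PROT1","PEP1","PEP1.t2","analyte","C02","curve_point",5,1,1684.65,NA
"site1","I","PROT1","PEP1","PEP1.t2","analyte","C03","curve_point",20,1,6738.79,NA
"site1","I","PROT1","PEP1","PEP1.t2","analyte","C04","curve_point",100,1,32529.72,NA
"site1","I","PROT1","PEP1","PEP1.t1","analyte","C01","curve_point",1,2,937.9,NA
"site1","I","PROT1","PEP1","PEP1.t1","analyte","C02","curve_point",5,2,3626.59,NA
"site1","I","PROT1","PEP1","PEP1.t1","analyte","C03","curve_point",20,2,13439.12,NA
"site1","I","PROT1","PEP1","PEP1.t1","analyte","C04","curve_point",100,2,65334.54,NA
"site1","I","PROT1","PEP1","PEP1.t2","analyte","C01","curve_point",1,2,518.91,NA
"site1","I","PROT1","PEP1","PEP1.t2","analyte","C02","curve_point",5,2,1964.34,NA
"site1","I","PROT1","PEP1","PEP1.t2","analyte","C03","curve_point",20,2,6319.45,NA
"site1","I","PROT1","PEP1","PEP1.t2","analyte","C04","curve_point",100,2,35021.48,NA
"site1","I","PROT1","PEP1","PEP1.t1","analyte","B01","blank",0,1,412.83,NA
"site1","I","PROT1","PEP1","PEP1.t2","analyte","B01","blank",0,1,271.07,NA
"site1","I","PROT1","PEP1","PEP1.t1","analyte","B01","blank",0,2,468.65,NA
"site1","I","PROT1","PEP1","PEP1.t2","analyte","B01","blank",0,2,268.03,NA
"site1","I","PROT1","PEP1","PEP1.t1","analyte","B01","blank",0,3,480.01,NA
"site1","I","PROT1","PEP1","PEP1.t2","analyte","B01","blank",0,3,204.04,NA
"site1","I","PROT1","PEP1","PEP1.t1","SIS","C01","curve_point",1,1,32365.79,NA
"site1","I","PROT1","PEP1","PEP1.t1","SIS","C02","curve_point",5,1,35046.14,NA
"site1","I","PROT1","PEP1","PEP1.t1","SIS","C03","curve_point",20,1,34182.29,NA
"site1","I","PROT1","PEP1","PEP1.t1","SIS","C04","curve_point",100,1,32862.64,NA
"site1","I","PROT1","PEP1","PEP1.t2","SIS","C01","curve_point",1,1,17144.11,NA
"site1","I","PROT1","PEP1","PEP1.t2","SIS","C02","curve_point",5,1,16919.72,NA
"site1","I","PROT1","PEP1","PEP1.t2","SIS","C03","curve_point",20,1,15991.77,NA
"site1","I","PROT1","PEP1","PEP1.t2","SIS","C04","curve_point",100,1,16545.68,NA
"site1","I","PROT1","PEP1","PEP1.t1","SIS","C01","curve_point",1,2,32255.11,NA
"site1","I","PROT1","PEP1","PEP1.t1","SIS","C02","curve_point",5,2,33866.85,NA
"site1","I","PROT1","PEP1","PEP1.t1","SIS","C03","curve_point",20,2,32582.48,NA
"site1","I","PROT1","PEP1","PEP1.t1","SIS","C04","curve_point",100,2,33061.88,NA
"site1","I","PROT1","PEP1","PEP1.t2","SIS","C01","curve_point",1,2,15954.26,NA
"site1","I","PROT1","PEP1","PEP1.t2","SIS","C02","curve_point",5,2,16110.27,NA
"site1","I","PROT1","PEP1","PEP1.t2","SIS","C03","curve_point",20,2,16745.74,NA
"site1","I","PROT1","PEP1","PEP1.t2","SIS","C04","curve_point",100,2,16088.6,NA
"site1","I","PROT1","PEP1","PEP1.t1","SIS","B01","blank",0,1,33167.13,NA
"site1","I","PROT1","PEP1","PEP1.t2","SIS","B01","blank",0,1,16765.5,NA
"site1","I","PROT1","PEP1","PEP1.t1","SIS","B01","blank",0,2,33100.03,NA
"site1","I","PROT1","PEP1","PEP1.t2","SIS","B01","blank",0,2,16496.06,NA
"site1","I","PROT1","PEP1","PEP1.t1","SIS","B01","blank",0,3,31351.93,NA
"site1","I","PROT1","PEP1","PEP1.t2","SIS","B01","blank",0,3,16506.83,NA
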