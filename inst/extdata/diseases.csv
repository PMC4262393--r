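disease_id,name,survey_set,set_respondents,group,mean,median,min,max,acmg_acog,assessed_nbs,included_nbs
canavan,Canavan disease,C,94,Profound,3.66,4,2,4,TRUE,FALSE,FALSE
slos,Smith-Lemli-Opitz syndrome,B,46,Profound,3.54,4,2,4,FALSE,TRUE,FALSE
citrullinemia_1,Citrullinemia type 1,A,52,Profound,3.54,4,2,4,FALSE,TRUE,TRUE
pompe,Pompe disease,C,94,Profound,3.48,4,2,4,FALSE,TRUE,FALSE
galactosemia,Galactosemia,C,94,Profound,3.46,4,2,4,FALSE,TRUE,TRUE
homocystinuria,Homocystinuria caused by CBS deficiency,B,46,Severe,3.13,3,2,4,FALSE,TRUE,TRUE
cystic_fibrosis,Cystic fibrosis,B,46,Severe,2.98,3,2,4,TRUE,TRUE,TRUE
scad_deficiency,Short-chain acyl-CoA dehydrogenase deficiency,A,52,Severe,2.92,3,1,4,FALSE,TRUE,FALSE
wilson,Wilson disease,C,94,Severe,2.86,3,2,4,FALSE,TRUE,FALSE
bardet_biedl,Bardet-Biedl syndrome,B,46,Severe,2.83,3,1,4,FALSE,FALSE,FALSE
fragile_x,Fragile X syndrome,B,46,Severe,2.83,3,1,4,FALSE,TRUE,FALSE
beta_thal_sickle,Beta-thalassemia/sickle cell disease,A,52,Severe,2.79,3,2,4,TRUE,TRUE,TRUE
usher_1f,Usher syndrome type 1F,A,52,Severe,2.65,3,1,4,FALSE,FALSE,FALSE
gjb2_deafness,GJB2-related nonsyndromic hearing loss and deafness,A,52,Moderate,1.85,2,1,4,FALSE,TRUE,TRUE
a1at_deficiency,Alpha-1 antitrypsin deficiency,C,94,Moderate,1.84,2,1,4,FALSE,TRUE,FALSE
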