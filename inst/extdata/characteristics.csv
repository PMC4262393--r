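id,name,category,lifespan_flag,tier,co_tier,mean,median,min,max
le_infancy,Shortened life span: infancy,core,TRUE,1,1,9.53,10,1,10
le_childhood_adolescence,Shortened life span: childhood/adolescence,core,TRUE,1,1,9.17,9,2,10
intellectual_disability,Intellectual disability,core,FALSE,1,1,9.07,9,5,10
le_premature_adulthood,Shortened life span: premature adulthood,core,TRUE,2,2,8.01,8,1,10
impaired_mobility,Impaired mobility,core,FALSE,2,2,7.98,8,2,10
internal_malformation,Internal physical malformation,core,FALSE,2,2,7.71,8,3,10
vision_impairment,Sensory impairment: vision,core,FALSE,3,3,6.98,7,1,10
immunodeficiency_cancer,Immunodeficiency/cancer,core,FALSE,3,3,6.76,7,1,10
hearing_impairment,Sensory impairment: hearing,core,FALSE,3,3,6.67,7,1,10
sensory_other,"Sensory impairment: touch, other (including pain)",core,FALSE,3,3,6.65,7,1,10
mental_illness,Mental illness,core,FALSE,3,3,6.54,7,1,10
dysmorphic_features,Dysmorphic features,core,FALSE,3,3,6.43,7,1,10
reduced_fertility,Reduced fertility,core,FALSE,4,4,3.97,3,1,10
availability_of_treatment,Availability of treatment,modifier,FALSE,modifier,2,8.07,9,1,10
variable_expressivity,Variable expressivity,modifier,FALSE,modifier,3,6.14,6,1,10
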