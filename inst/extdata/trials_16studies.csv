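trial_id,test_mean,test_sd,test_n,control_mean,control_sd,control_n,range_low,range_high,variable_name,design,range_estimated
REF9,81.30,4.80,41,81.30,4.80,41,75,95,age,rct,TRUE
REF10,17.30,2.10,211,17.10,2.10,207,13,21,age,rct,FALSE
REF11,36.00,8.00,37,35.00,8.00,34,21,50,age,rct,FALSE
REF12,5.40,0.50,49,5.60,0.50,46,4,6,age_months,rct,FALSE
REF13,29.90,7.00,344,30.20,7.00,339,18,80,age,rct,TRUE
REF14,40.00,11.60,13,34.00,10.90,13,18,80,age,rct,TRUE
REF15,23.68,2.72,16,25.13,5.50,15,19,47,age,rct,FALSE
REF16,57.94,15.83,83,59.48,15.53,84,18,80,age,rct,TRUE
REF17,64.22,12.00,31,50.73,14.00,30,18,80,age,cohort,TRUE
REF18,40.80,12.50,142,44.80,12.30,140,18,80,age,cohort,TRUE
REF19,45.17,12.96,30,50.75,10.27,51,18,80,age,cohort,TRUE
REF20,36.80,8.80,49,41.90,9.20,49,25,80,age,cohort,TRUE
REF21,49.00,17.00,12,59.00,14.00,41,18,80,age,cohort,TRUE
REF22,14.10,2.30,30,14.30,3.10,17,8,18,age,cohort,FALSE
REF23,45.30,10.60,164,53.40,12.40,143,19,88,age,cohort,FALSE
REF24,13.84,2.50,32,14.36,3.20,20,8,18,age,cohort,FALSE
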