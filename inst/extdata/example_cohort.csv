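patient_id,visit_index,time_months,severity_score,dose_mg_per_kg,response,baseline_severity,sex,age_months
101,0,0,57,0.25,0,57,1,84
101,1,3.517241,44,0.25,0,57,1,84
101,2,7.90331,36,0.25,1,57,1,84
102,0,0,49,0.6123456789012,0,49,0,112
102,1,5.25,41,0.6123456789012,0,49,0,112
102,2,11.083333,28,0.6123456789012,1,49,0,112
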