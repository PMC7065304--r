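patient_id,visit_index,time_months,severity_score,dose_mg_per_kg,response,baseline_severity
12456,1,1,45,0.1638,0,45
12456,2,2,42,0.1247,0,45
12456,3,4,39,0.0871,1,45
22378,1,1,67,0.6023,0,67
22378,2,2,65,0.4781,0,67
22378,3,5,39,0.0773,1,67
22378,4,6,30,0.0412,1,67
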