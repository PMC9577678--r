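study_id,outcome,scale,estimate,ci_low,ci_high,se,n_participants,duration_months
study_1,hospitalization_rr,rr,NA,NA,NA,NA,NA,NA
study_2,hospitalization_rr,rr,NA,NA,NA,NA,NA,NA
study_3,expenditure_pct_change,percent_reduction,NA,NA,NA,NA,NA,NA
study_4,expenditure_pct_change,percent_reduction,NA,NA,NA,NA,NA,NA
study_5,duration_months,months,NA,NA,NA,NA,NA,NA
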