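table,variable,group,count,denominator,pct_printed
table3,in_hospital_death,crp_pos_bmi_pos,1375,6059,22.7
table3,in_hospital_death,crp_neg_bmi_pos,430,3989,10.8
table3,in_hospital_death,crp_pos_bmi_neg,2288,15888,14.4
table3,in_hospital_death,crp_neg_bmi_neg,622,13045,4.8
table3,bi_lt_60,crp_pos_bmi_pos,4475,6059,73.9
table3,bi_lt_60,crp_neg_bmi_pos,2448,3989,61.4
table3,bi_lt_60,crp_pos_bmi_neg,7585,15888,47.7
table3,bi_lt_60,crp_neg_bmi_neg,4972,13045,38.1
table3,los_ge_14,crp_pos_bmi_pos,4708,5460,86.2
table3,los_ge_14,crp_neg_bmi_pos,2904,3809,76.2
table3,los_ge_14,crp_pos_bmi_neg,12235,14791,82.7
table3,los_ge_14,crp_neg_bmi_neg,9012,12745,70.7
table3,composite,crp_pos_bmi_pos,5753,6059,94.9
table3,composite,crp_neg_bmi_pos,3469,3989,87.0
table3,composite,crp_pos_bmi_neg,14019,15888,88.2
table3,composite,crp_neg_bmi_neg,10018,13045,76.8
table3,death_by_day14,crp_pos_bmi_pos,599,6059,9.9
table3,death_by_day14,crp_neg_bmi_pos,180,3989,4.5
table3,death_by_day14,crp_pos_bmi_neg,1097,15888,6.9
table3,death_by_day14,crp_neg_bmi_neg,300,13045,2.3
table3,death_by_day28,crp_pos_bmi_pos,952,6059,15.7
table3,death_by_day28,crp_neg_bmi_pos,298,3989,7.5
table3,death_by_day28,crp_pos_bmi_neg,1685,15888,10.6
table3,death_by_day28,crp_neg_bmi_neg,445,13045,3.4
table2,male,overall,22904,38981,58.8
table2,diagnosis_neurology,overall,10721,38981,27.5
table2,diagnosis_sepsis,crp_pos_bmi_pos,1373,6059,22.7
table2,diagnosis_pulmonary,crp_pos_bmi_pos,854,6059,14.1
table2,diagnosis_neurology,crp_neg_bmi_neg,6040,13045,46.3
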