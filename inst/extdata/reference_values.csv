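quantity,value,tolerance
pure_error_ss_sf,0.0212,0.0001
ss_x2sq_sf,0.5852,0.0005
r2_sf_pct,97.82,0.05
r2_adj_sf_pct,94.57,0.05
r2_ji_pct,75.01,0.05
ji_coef_x1,0.3938,0.00006
ji_coef_x2,0.5238,0.00006
ji_coef_x3,0.3625,0.00006
sf_pred_45_3_100,2.71,0.02
sf_pred_30_5_50,2.05,0.02
sf_pred_54_4_120,2.56,0.02
desirability_single,0.94,0.01
opt_temperature_c,46.81,0.47
desirability_multi,0.72,0.01
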