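experiment,dp_av,fos_fc_feed,t_c,tmp_bar,conc_kgm3,sf_predicted_ref,sf_experimental
1,15.4,0.35,45,3,100,2.71,3.50
2,14.6,0.39,30,5,50,2.05,5.78
3,16.8,0.36,60,5,50,1.53,1.63
4,13.5,0.44,54,4,120,2.56,3.25
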