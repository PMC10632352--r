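condition,f_true,seed,n_mt,n_runs,freq_mean,freq_sd,fold_vs_reference,velocity_mean_nms,velocity_sd_nms,p_vs_reference
baseline,0.0002,43,6,9,0.00025410774,0.00019462391,1,496.60962,123.22919,NA
lis1_nde1,0.0032,44,6,122,0.0033596458,0.00055942298,13.221344,548.7758,100.75554,1.0745722e-05
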