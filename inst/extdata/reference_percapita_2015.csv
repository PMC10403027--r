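quantity,value
mean_12m,28085
mean_3m,12385
cohort_n,501121
top_decile_count,50113
top_decile_threshold,65914
top_decile_share_pct,37.5
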