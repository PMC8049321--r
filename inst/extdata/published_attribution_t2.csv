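term,t_squared
monthly_counts,10.24
arrival_day,5.02
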