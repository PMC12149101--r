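statistic,te,pte,se
mean_value,0.932,0.936,0.996
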