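statistic,y2014,y2015,y2016,y2017,y2018,y2019
effective_number,11,13,14,13,13,15
mean_value,0.908,0.915,0.93,0.929,0.934,0.932
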