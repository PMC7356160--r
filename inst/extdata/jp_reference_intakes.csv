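year,rice_ug_day,other_ug_day,total_ug_day
1981,16.2,14.9,31.1
2007,7.8,13.3,21.1
2015,5.7,12.1,17.8
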