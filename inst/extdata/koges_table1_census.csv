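age_group,sex,N
40-49,Men,3886462
40-49,Women,3758072
50-59,Men,2208310
50-59,Women,2245444
60-69,Men,1493790
60-69,Women,1821163
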