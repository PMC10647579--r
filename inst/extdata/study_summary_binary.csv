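variable,stratum,count,n
male,young,28,100
male,old,40,91
smoking,young,24,100
smoking,old,32,91
hypertension,young,62,100
hypertension,old,71,91
diabetes,young,21,100
diabetes,old,27,91
dyslipidemia,young,74,100
dyslipidemia,old,53,91
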