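characteristic,level,count
sex,male,35
sex,female,19
who_grade,1,4
who_grade,2,11
who_grade,3,15
who_grade,4,24
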