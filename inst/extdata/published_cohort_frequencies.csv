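variable,level,count
ebi_grade,1,118
ebi_grade,2,82
ebi_grade,3,66
ebi_grade,4,45
ebi_grade,5,13
lods,1,3
lods,2,10
lods,3,26
lods,4,30
lods,5,49
lods,6,55
lods,7,48
lods,8,17
lods,9,24
lods,10,8
lods,11,39
lods,12,3
lods,13,5
lods,14,4
lods,15,0
lods,16,3
mrs,0,113
mrs,1,87
mrs,2,25
mrs,3,22
mrs,4,32
mrs,5,22
mrs,6,22
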