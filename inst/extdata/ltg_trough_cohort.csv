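subject_id,dose,parent_conc,metabolite_conc
1,100,4.61,0.37
2,200,3.14,1.41
3,250,6.42,1.63
4,400,3.50,2.14
5,100,1.83,0.60
6,300,6.09,2.10
7,100,1.84,0.31
8,250,3.48,1.09
9,400,9.39,3.22
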