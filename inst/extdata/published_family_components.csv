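family,n_lines,sigma_g2,sigma_e2
1,94,0.085,0.132
2,190,0.072,0.092
3,190,0.138,0.107
4,95,0.354,0.134
5,95,0.022,0.315
6,95,0.096,0.077
7,95,0.081,0.103
8,95,0.003,0.211
9,94,0.014,0.321
10,95,0.084,0.177
11,95,0.121,0.130
12,95,0.137,0.112
13,95,0.094,0.117
14,186,0.063,0.160
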