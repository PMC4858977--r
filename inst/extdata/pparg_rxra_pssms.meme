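MEME version 4

ALPHABET= ACGT

strands: +

Background letter frequencies (from uniform background):
A 0.25000 C 0.25000 G 0.25000 T 0.25000

MOTIF Kd_PPARg_RXRa
letter-probability matrix: alength= 4 w= 15 nsites= 20 E= 0
0.110	0.411	0.360	0.120
0.127	0.183	0.183	0.507
0.429	0.120	0.322	0.130
0.144	0.196	0.423	0.237
0.165	0.186	0.359	0.290
0.137	0.149	0.189	0.525
0.226	0.326	0.206	0.242
0.365	0.199	0.233	0.202
0.421	0.208	0.166	0.205
0.404	0.160	0.277	0.159
0.195	0.224	0.367	0.214
0.192	0.293	0.324	0.191
0.194	0.171	0.302	0.333
0.221	0.304	0.276	0.198
0.264	0.228	0.228	0.279

MOTIF KDoD_PPARg_RXRa
letter-probability matrix: alength= 4 w= 15 nsites= 20 E= 0
0.083	0.377	0.241	0.299
0.401	0.062	0.083	0.454
0.363	0.099	0.444	0.093
0.222	0.071	0.415	0.292
0.225	0.238	0.453	0.084
0.171	0.314	0.249	0.266
0.132	0.666	0.084	0.118
0.410	0.401	0.098	0.092
0.447	0.081	0.214	0.258
0.672	0.121	0.113	0.094
0.131	0.132	0.691	0.046
0.153	0.199	0.371	0.277
0.166	0.169	0.220	0.445
0.187	0.334	0.180	0.299
0.300	0.106	0.470	0.125
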