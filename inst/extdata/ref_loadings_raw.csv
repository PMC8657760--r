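indicator,facet,framing,O,C,E,A,N
O1_idpos,O1,identity_pos,0.483,0.158,0.160,-0.184,-0.056
O1_idneg,O1,identity_neg,0.175,0.165,0.295,0.399,-0.152
O1_se,O1,self_efficacy,0.590,0.214,0.071,-0.020,0.105
O2_idpos,O2,identity_pos,0.760,-0.075,0.098,-0.039,-0.020
O2_idneg,O2,identity_neg,0.338,0.093,0.305,0.438,-0.112
O2_se,O2,self_efficacy,0.850,-0.003,-0.022,0.106,0.089
O3_idpos,O3,identity_pos,0.595,0.037,0.009,-0.002,0.020
O3_idneg,O3,identity_neg,0.229,0.250,0.261,0.468,-0.092
O3_se,O3,self_efficacy,0.729,0.042,-0.155,0.136,0.098
C1_idpos,C1,identity_pos,0.007,0.752,-0.131,-0.157,0.026
C1_idneg,C1,identity_neg,-0.182,0.644,-0.015,0.297,0.040
C1_se,C1,self_efficacy,0.047,0.669,-0.161,-0.122,0.175
C2_idpos,C2,identity_pos,0.149,0.709,-0.087,-0.114,-0.028
C2_idneg,C2,identity_neg,0.037,0.339,0.203,0.428,-0.105
C2_se,C2,self_efficacy,0.244,0.481,0.103,-0.208,0.127
C3_idpos,C3,identity_pos,0.194,0.493,-0.113,-0.143,0.093
C3_idneg,C3,identity_neg,0.113,0.431,-0.042,0.553,0.039
C3_se,C3,self_efficacy,0.258,0.508,-0.191,-0.054,0.240
C4_idpos,C4,identity_pos,0.145,0.585,0.033,-0.236,0.010
C4_idneg,C4,identity_neg,-0.052,0.700,0.086,0.336,-0.144
C4_se,C4,self_efficacy,0.253,0.620,-0.150,-0.043,0.079
C5_idpos,C5,identity_pos,0.039,0.599,0.128,-0.283,-0.033
C5_idneg,C5,identity_neg,-0.108,0.493,0.280,0.299,-0.075
C5_se,C5,self_efficacy,0.049,0.583,0.080,-0.211,0.088
E1_idpos,E1,identity_pos,0.055,-0.045,0.605,-0.506,0.051
E1_idneg,E1,identity_neg,0.015,-0.263,0.587,0.086,0.013
E1_se,E1,self_efficacy,0.132,0.052,0.252,-0.333,0.243
E2_idpos,E2,identity_pos,0.402,0.004,0.192,-0.288,-0.096
E2_idneg,E2,identity_neg,0.158,-0.052,0.400,0.327,-0.004
E2_se,E2,self_efficacy,0.288,0.255,0.093,-0.088,0.158
E3_idpos,E3,identity_pos,0.120,-0.025,0.467,-0.360,0.264
E3_idneg,E3,identity_neg,0.007,-0.100,0.575,0.204,-0.021
E3_se,E3,self_efficacy,0.142,0.232,0.279,-0.241,0.329
A1_idpos,A1,identity_pos,0.063,0.243,0.309,-0.401,0.051
A1_idneg,A1,identity_neg,-0.021,0.299,0.423,0.255,-0.078
A1_se,A1,self_efficacy,0.237,0.263,0.279,-0.321,-0.011
A2_idpos,A2,identity_pos,-0.013,0.593,0.107,-0.158,0.056
A2_idneg,A2,identity_neg,-0.153,0.492,0.019,0.438,0.184
A2_se,A2,self_efficacy,0.084,0.402,-0.043,-0.087,0.375
A3_idpos,A3,identity_pos,0.040,0.022,0.220,-0.341,0.232
A3_idneg,A3,identity_neg,-0.126,-0.011,0.201,0.381,0.266
A3_se,A3,self_efficacy,0.088,-0.055,0.124,-0.229,0.347
A4_idpos,A4,identity_pos,0.041,0.129,-0.101,-0.202,0.010
A4_idneg,A4,identity_neg,-0.184,0.375,0.185,0.330,-0.034
A4_se,A4,self_efficacy,0.161,0.313,-0.091,-0.135,0.248
N1_idpos,N1,identity_pos,0.166,-0.003,0.086,-0.227,0.428
N1_idneg,N1,identity_neg,-0.031,-0.113,0.164,0.484,0.434
N1_se,N1,self_efficacy,0.128,-0.001,-0.081,-0.035,0.751
N2_idpos,N2,identity_pos,0.041,0.090,0.217,-0.256,0.368
N2_idneg,N2,identity_neg,-0.183,0.095,0.306,0.403,0.354
N2_se,N2,self_efficacy,0.123,0.137,0.206,-0.210,0.502
N3_idpos,N3,identity_pos,0.000,-0.051,-0.101,-0.057,0.601
N3_idneg,N3,identity_neg,-0.108,-0.033,0.094,0.545,0.640
N3_se,N3,self_efficacy,0.031,-0.004,-0.094,0.027,0.789
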