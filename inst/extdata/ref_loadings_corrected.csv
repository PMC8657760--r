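indicator,facet,framing,O,C,E,A,N
O1_idpos,O1,identity_pos,0.448,0.066,0.143,0.183,-0.114
O1_idneg,O1,identity_neg,0.351,0.021,0.107,0.263,-0.177
O1_se,O1,self_efficacy,0.562,0.169,0.049,0.070,0.123
O2_idpos,O2,identity_pos,0.703,-0.040,0.150,-0.100,-0.050
O2_idneg,O2,identity_neg,0.473,0.029,0.170,0.106,-0.137
O2_se,O2,self_efficacy,0.812,0.021,-0.006,-0.110,0.121
O3_idpos,O3,identity_pos,0.589,-0.062,-0.038,0.123,-0.016
O3_idneg,O3,identity_neg,0.426,0.079,0.046,0.316,-0.132
O3_se,O3,self_efficacy,0.724,0.000,-0.175,-0.033,0.128
C1_idpos,C1,identity_pos,-0.139,0.867,-0.031,-0.014,-0.020
C1_idneg,C1,identity_neg,-0.149,0.727,-0.027,0.010,0.003
C1_se,C1,self_efficacy,-0.051,0.750,-0.063,-0.047,0.183
C2_idpos,C2,identity_pos,0.018,0.797,-0.011,0.006,-0.079
C2_idneg,C2,identity_neg,0.149,0.360,0.106,0.086,-0.132
C2_se,C2,self_efficacy,0.168,0.493,0.148,0.069,0.132
C3_idpos,C3,identity_pos,0.078,0.560,-0.046,0.032,0.046
C3_idneg,C3,identity_neg,0.205,0.524,-0.103,-0.047,0.022
C3_se,C3,self_efficacy,0.182,0.574,-0.110,-0.059,0.253
C4_idpos,C4,identity_pos,0.007,0.673,0.124,0.033,-0.046
C4_idneg,C4,identity_neg,0.013,0.716,0.016,0.103,-0.191
C4_se,C4,self_efficacy,0.165,0.680,-0.074,-0.063,0.099
C5_idpos,C5,identity_pos,-0.042,0.530,0.123,0.265,-0.100
C5_idneg,C5,identity_neg,-0.008,0.459,0.173,0.214,-0.126
C5_se,C5,self_efficacy,0.029,0.456,0.037,0.268,0.085
E1_idpos,E1,identity_pos,-0.050,-0.078,0.649,0.223,0.014
E1_idneg,E1,identity_neg,0.052,-0.181,0.607,-0.073,0.023
E1_se,E1,self_efficacy,0.059,0.072,0.316,0.050,0.259
E2_idpos,E2,identity_pos,0.261,0.139,0.351,-0.188,-0.123
E2_idneg,E2,identity_neg,0.195,0.126,0.445,-0.207,0.010
E2_se,E2,self_efficacy,0.189,0.381,0.191,-0.130,0.179
E3_idpos,E3,identity_pos,-0.017,0.063,0.584,0.060,0.221
E3_idneg,E3,identity_neg,0.079,-0.074,0.534,0.052,-0.041
E3_se,E3,self_efficacy,0.080,0.236,0.300,0.137,0.322
A1_idpos,A1,identity_pos,0.053,-0.022,0.217,0.540,-0.013
A1_idneg,A1,identity_neg,0.148,0.074,0.215,0.451,-0.141
A1_se,A1,self_efficacy,0.245,0.039,0.184,0.388,-0.006
A2_idpos,A2,identity_pos,-0.016,0.366,-0.025,0.508,-0.017
A2_idneg,A2,identity_neg,0.031,0.299,-0.216,0.457,0.138
A2_se,A2,self_efficacy,0.136,0.166,-0.168,0.437,0.353
A3_idpos,A3,identity_pos,-0.002,-0.117,0.202,0.326,0.187
A3_idneg,A3,identity_neg,-0.011,-0.007,0.128,0.087,0.267
A3_se,A3,self_efficacy,0.069,-0.129,0.123,0.173,0.347
A4_idpos,A4,identity_pos,0.050,-0.093,-0.199,0.346,-0.045
A4_idneg,A4,identity_neg,0.036,0.064,-0.109,0.615,-0.083
A4_se,A4,self_efficacy,0.187,0.124,-0.175,0.318,0.249
N1_idpos,N1,identity_pos,0.046,0.102,0.214,-0.033,0.397
N1_idneg,N1,identity_neg,0.031,0.085,0.193,-0.189,0.444
N1_se,N1,self_efficacy,0.110,0.034,-0.028,0.033,0.739
N2_idpos,N2,identity_pos,-0.068,0.134,0.291,0.126,0.300
N2_idneg,N2,identity_neg,-0.127,0.238,0.294,0.009,0.349
N2_se,N2,self_efficacy,0.068,0.169,0.254,0.090,0.496
N3_idpos,N3,identity_pos,-0.036,-0.060,-0.081,0.137,0.527
N3_idneg,N3,identity_neg,0.046,-0.041,-0.023,0.176,0.586
N3_se,N3,self_efficacy,0.071,-0.074,-0.124,0.205,0.747
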