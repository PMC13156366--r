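"scenario","method","metric","mean","sd"
"baseline","CW","ctd",0.699,0.004
"baseline","CW","ibs",0.161,0.001
"baseline","CW","inbll",0.486,0.003
"baseline","CW","nll",0.255,0.003
"baseline","CW","ise",0.512,0.004
"baseline","CW+M","ctd",0.721,0.003
"baseline","CW+M","ibs",0.154,0.002
"baseline","CW+M","inbll",0.469,0.004
"baseline","CW+M","nll",0.239,0.005
"baseline","CW+M","ise",0.374,0.004
"baseline","Mean","ctd",0.747,0.004
"baseline","Mean","ibs",0.144,0.002
"baseline","Mean","inbll",0.444,0.005
"baseline","Mean","nll",0.213,0.006
"baseline","Mean","ise",0.176,0.002
"baseline","ICE","ctd",0.747,0.004
"baseline","ICE","ibs",0.144,0.002
"baseline","ICE","inbll",0.444,0.006
"baseline","ICE","nll",0.213,0.006
"baseline","ICE","ise",0.175,0.006
"baseline","RI","ctd",0.747,0.004
"baseline","RI","ibs",0.144,0.002
"baseline","RI","inbll",0.443,0.006
"baseline","RI","nll",0.211,0.006
"baseline","RI","ise",0.167,0.003
"baseline","MICE_O","ctd",0.746,0.004
"baseline","MICE_O","ibs",0.144,0.002
"baseline","MICE_O","inbll",0.444,0.005
"baseline","MICE_O","nll",0.214,0.005
"baseline","MICE_O","ise",0.182,0.003
"baseline","MICE","ctd",0.743,0.004
"baseline","MICE","ibs",0.146,0.002
"baseline","MICE","inbll",0.448,0.004
"baseline","MICE","nll",0.217,0.005
"baseline","MICE","ise",0.206,0.005
"baseline","-1 Enc.","ctd",0.742,0.004
"baseline","-1 Enc.","ibs",0.146,0.002
"baseline","-1 Enc.","inbll",0.449,0.005
"baseline","-1 Enc.","nll",0.218,0.006
"baseline","-1 Enc.","ise",0.214,0.008
"baseline","MIM","ctd",0.749,0.004
"baseline","MIM","ibs",0.143,0.002
"baseline","MIM","inbll",0.441,0.005
"baseline","MIM","nll",0.21,0.006
"baseline","MIM","ise",0.158,0.005
"baseline","MissCVAE","ctd",0.75,0.003
"baseline","MissCVAE","ibs",0.143,0.002
"baseline","MissCVAE","inbll",0.442,0.005
"baseline","MissCVAE","nll",0.211,0.005
"baseline","MissCVAE","ise",0.158,0.005
"baseline","MissCVAE_hx","ctd",0.75,0.003
"baseline","MissCVAE_hx","ibs",0.143,0.002
"baseline","MissCVAE_hx","inbll",0.442,0.004
"baseline","MissCVAE_hx","nll",0.211,0.005
"baseline","MissCVAE_hx","ise",0.159,0.004
"unseen_patterns","CW","ctd",0.677,0.009
"unseen_patterns","CW","ibs",0.185,0.003
"unseen_patterns","CW","inbll",0.545,0.008
"unseen_patterns","CW","nll",0.234,0.005
"unseen_patterns","CW","ise",0.718,0.023
"unseen_patterns","CW+M","ctd",0.694,0.012
"unseen_patterns","CW+M","ibs",0.173,0.004
"unseen_patterns","CW+M","inbll",0.515,0.009
"unseen_patterns","CW+M","nll",0.205,0.008
"unseen_patterns","CW+M","ise",0.49,0.024
"unseen_patterns","Mean","ctd",0.724,0.007
"unseen_patterns","Mean","ibs",0.16,0.003
"unseen_patterns","Mean","inbll",0.481,0.007
"unseen_patterns","Mean","nll",0.171,0.014
"unseen_patterns","Mean","ise",0.254,0.013
"unseen_patterns","ICE","ctd",0.689,0.034
"unseen_patterns","ICE","ibs",0.185,0.024
"unseen_patterns","ICE","inbll",0.691,0.247
"unseen_patterns","ICE","nll",0.495,0.454
"unseen_patterns","ICE","ise",0.73,0.454
"unseen_patterns","RI","ctd",0.725,0.006
"unseen_patterns","RI","ibs",0.159,0.002
"unseen_patterns","RI","inbll",0.48,0.005
"unseen_patterns","RI","nll",0.17,0.011
"unseen_patterns","RI","ise",0.231,0.015
"unseen_patterns","MICE_O","ctd",0.726,0.006
"unseen_patterns","MICE_O","ibs",0.159,0.001
"unseen_patterns","MICE_O","inbll",0.481,0.005
"unseen_patterns","MICE_O","nll",0.171,0.009
"unseen_patterns","MICE_O","ise",0.222,0.01
"unseen_patterns","MICE","ctd",0.724,0.007
"unseen_patterns","MICE","ibs",0.161,0.002
"unseen_patterns","MICE","inbll",0.486,0.005
"unseen_patterns","MICE","nll",0.175,0.006
"unseen_patterns","MICE","ise",0.256,0.016
"unseen_patterns","-1 Enc.","ctd",0.716,0.009
"unseen_patterns","-1 Enc.","ibs",0.164,0.003
"unseen_patterns","-1 Enc.","inbll",0.494,0.007
"unseen_patterns","-1 Enc.","nll",0.184,0.006
"unseen_patterns","-1 Enc.","ise",0.344,0.02
"unseen_patterns","MIM","ctd",0.727,0.007
"unseen_patterns","MIM","ibs",0.159,0.001
"unseen_patterns","MIM","inbll",0.481,0.004
"unseen_patterns","MIM","nll",0.169,0.011
"unseen_patterns","MIM","ise",0.224,0.02
"unseen_patterns","MissCVAE","ctd",0.728,0.008
"unseen_patterns","MissCVAE","ibs",0.158,0.001
"unseen_patterns","MissCVAE","inbll",0.477,0.003
"unseen_patterns","MissCVAE","nll",0.168,0.01
"unseen_patterns","MissCVAE","ise",0.196,0.01
"unseen_patterns","MissCVAE_hx","ctd",0.728,0.007
"unseen_patterns","MissCVAE_hx","ibs",0.159,0.001
"unseen_patterns","MissCVAE_hx","inbll",0.479,0.003
"unseen_patterns","MissCVAE_hx","nll",0.169,0.011
"unseen_patterns","MissCVAE_hx","ise",0.207,0.013
"missingness_shift","CW","ctd",0.699,0.004
"missingness_shift","CW","ibs",0.161,0.001
"missingness_shift","CW","inbll",0.486,0.003
"missingness_shift","CW","nll",0.255,0.003
"missingness_shift","CW","ise",0.512,0.004
"missingness_shift","CW+M","ctd",0.716,0.004
"missingness_shift","CW+M","ibs",0.158,0.002
"missingness_shift","CW+M","inbll",0.479,0.005
"missingness_shift","CW+M","nll",0.248,0.006
"missingness_shift","CW+M","ise",0.444,0.013
"missingness_shift","Mean","ctd",0.747,0.003
"missingness_shift","Mean","ibs",0.144,0.002
"missingness_shift","Mean","inbll",0.444,0.004
"missingness_shift","Mean","nll",0.213,0.005
"missingness_shift","Mean","ise",0.176,0.004
"missingness_shift","ICE","ctd",0.747,0.004
"missingness_shift","ICE","ibs",0.144,0.002
"missingness_shift","ICE","inbll",0.444,0.005
"missingness_shift","ICE","nll",0.213,0.005
"missingness_shift","ICE","ise",0.175,0.006
"missingness_shift","RI","ctd",0.748,0.003
"missingness_shift","RI","ibs",0.144,0.002
"missingness_shift","RI","inbll",0.443,0.005
"missingness_shift","RI","nll",0.211,0.006
"missingness_shift","RI","ise",0.166,0.005
"missingness_shift","MICE_O","ctd",0.746,0.003
"missingness_shift","MICE_O","ibs",0.144,0.002
"missingness_shift","MICE_O","inbll",0.444,0.005
"missingness_shift","MICE_O","nll",0.213,0.005
"missingness_shift","MICE_O","ise",0.178,0.004
"missingness_shift","MICE","ctd",0.744,0.003
"missingness_shift","MICE","ibs",0.145,0.002
"missingness_shift","MICE","inbll",0.447,0.004
"missingness_shift","MICE","nll",0.216,0.005
"missingness_shift","MICE","ise",0.202,0.006
"missingness_shift","-1 Enc.","ctd",0.739,0.005
"missingness_shift","-1 Enc.","ibs",0.148,0.003
"missingness_shift","-1 Enc.","inbll",0.455,0.006
"missingness_shift","-1 Enc.","nll",0.223,0.007
"missingness_shift","-1 Enc.","ise",0.251,0.012
"missingness_shift","MIM","ctd",0.748,0.004
"missingness_shift","MIM","ibs",0.144,0.002
"missingness_shift","MIM","inbll",0.443,0.005
"missingness_shift","MIM","nll",0.212,0.006
"missingness_shift","MIM","ise",0.171,0.009
"missingness_shift","MissCVAE","ctd",0.749,0.004
"missingness_shift","MissCVAE","ibs",0.144,0.002
"missingness_shift","MissCVAE","inbll",0.443,0.004
"missingness_shift","MissCVAE","nll",0.213,0.006
"missingness_shift","MissCVAE","ise",0.163,0.006
"missingness_shift","MissCVAE_hx","ctd",0.749,0.004
"missingness_shift","MissCVAE_hx","ibs",0.144,0.002
"missingness_shift","MissCVAE_hx","inbll",0.443,0.005
"missingness_shift","MissCVAE_hx","nll",0.212,0.006
"missingness_shift","MissCVAE_hx","ise",0.165,0.01
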