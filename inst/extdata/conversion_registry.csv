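id,group,n,R,adj_R2,C0,se_C0,k,se_k,s_fit_min,s_fit_max
0,Entire data set,15120,0.765,0.585,-0.990,0.006,0.594,0.004,0.0092,0.0400
1,Surface treatment,805,0.735,0.540,-1.046,0.024,0.500,0.016,0.0427,0.1396
2,High temperature processing,2974,0.818,0.668,-0.751,0.011,0.729,0.009,0.0184,0.0708
3,Filling/transport/storage,3473,0.791,0.626,-1.093,0.012,0.586,0.008,0.0192,0.0698
4,Machining/abrasive techniques,4640,0.776,0.602,-1.031,0.016,0.578,0.013,0.0169,0.0553
5,Forming,1348,0.774,0.599,-1.037,0.011,0.579,0.007,0.0272,0.1071
6,Others,1880,0.768,0.590,-1.100,0.016,0.593,0.011,0.0275,0.1106
A,Mineral-dominated,9315,0.785,0.616,-1.058,0.007,0.581,0.005,0.0119,0.0512
B,Metal-dominated,5269,0.748,0.559,-0.851,0.010,0.614,0.008,0.0146,0.0531
C,Fiber-dominated,536,0.761,0.578,-1.176,0.031,0.614,0.023,0.0543,0.1977
1-A,Surface treatment - mineral-dominated,540,0.756,0.571,-1.043,0.059,0.512,0.038,0.0549,0.1660
2-B,High temperature processing - metal-dominated,2265,0.840,0.706,-0.687,0.013,0.758,0.010,0.0268,0.0961
4-A,Machining/abrasive techniques - mineral-dominated,2632,0.802,0.643,-1.015,0.026,0.595,0.017,0.0227,0.0732
6-B,Other - metal-dominated,331,0.779,0.608,-0.898,0.068,0.618,0.054,0.0608,0.1910
alpha,Soldering,34,0.917,0.835,-0.559,0.074,0.946,0.073,0.1634,0.4417
beta,Casting (metalworking),77,0.877,0.767,-0.430,0.058,0.913,0.049,0.0857,0.2322
gamma,Welding,1126,0.875,0.766,-0.601,0.018,0.803,0.014,0.0297,0.1005
delta,High temperature cutting,176,0.897,0.803,-0.716,0.028,0.750,0.028,0.0832,0.2832
epsilon,Blasting,57,0.907,0.819,-1.107,0.080,0.724,0.045,0.1847,0.4479
zeta,"Chiseling, embossing",41,0.912,0.827,-1.264,0.111,0.695,0.050,0.2113,0.4946
eta,Wire drawing,61,0.859,0.733,-1.028,0.087,0.695,0.054,0.1387,0.4000
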