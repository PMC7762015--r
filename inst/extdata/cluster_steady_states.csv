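cluster,TN,Th,TC,Tr,DN,D,M,C,N,H,mu1,mu2,Igamma,Gbeta,M0
1,1.4914e4,4.6358e3,2.5845e3,2.3891e3,3.0504e2,6.0214e2,1.1798e4,9.1531e4,4.5765e4,8.9811e3,1.6328e2,1.2987e3,8.5737,1.9037e4,2.1004e4
2,1.1429e4,6.0411e3,5.3853e3,3.3646e3,1.0329e2,5.1299e2,8.6227e3,9.7064e4,4.8532e4,8.5279e3,1.7552e2,1.3249e3,10.5677,2.2275e4,1.6445e4
3,9.2381e3,1.3864e3,1.1139e3,2.7910e3,1.8878e-1,1.8635e2,6.7972e3,9.0029e4,4.5014e4,9.5122e3,1.9866e2,1.2906e3,0.8287,2.5145e4,3.2146e4
4,1.3878e4,2.4910e3,3.2172e3,2.2783e3,1.4196e2,6.2154e2,1.2931e4,9.6956e4,4.8478e4,5.1782e3,1.1410e2,3.3689e2,1.2703,8.1734e3,1.5761e4
5,1.0262e4,3.7844e3,1.6853e3,2.6394e3,8.0199e1,1.9084e2,1.1603e4,8.0584e4,4.0292e4,7.7848e3,1.2058e2,7.1551e2,5.7892,2.6260e4,2.8198e4
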