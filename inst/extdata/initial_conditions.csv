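cluster,TN,Th,TC,Tr,DN,D,M,C,N,H,mu1,mu2,Igamma,Gbeta
1,0.9311,1.2492,2.4626,0.6872,1.6328,0.0003,0.6737,3.1466e-4,0.0,1.4712,0.4971,0.5124,3.8892,0.2549
2,1.2302,1.3155,1.5210,0.5107,2.0461,2.7822,1.2920,2.9672e-4,0.0,0.6036,0.7578,0.1790,0.9385,0.5566
3,1.1997,0.8555,1.6948e-4,0.6572,1.0000,1.0130e-3,1.4150,3.1991e-4,0.0,1.2566,0.1335,0.8419,0.0,0.6851
4,1.4471,0.1571,0.5823,0.8910,5.6827,4.2945,0.9259,2.9706e-4,0.0,1.4630,0.4137,5.7720,0.0,2.5629
5,0.6794,2.6119,1.6294,1.8819,2.3538e-3,0.4542,0.7749,3.5741e-4,0.0,1.1835,0.4587,2.2979,0.4084,0.3457
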