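compound_id,name,R6,R7,R8,R3p,R4p,pEC50_a1b3,pKi_a1g2,delta_a1b3,delta_a1g2
1,CGS-8216,H,H,H,H,H,4.66,9.77,0,0
2,PZ-II-029,H,OMe,H,H,OMe,4.58,9.52,-0.08,-0.25
3,PWZ-009A1,H,OMe,H,H,H,4.82,8.89,0.16,-0.88
4,CGS 9895,H,H,H,H,OMe,4.89,9.49,0.23,-0.28
5,Xhe-III-24,H,H,tBu,H,F,4.95,9.6,0.29,-0.17
6,CGS 9896,H,H,H,H,Cl,4.96,9.3,0.3,-0.47
7,Xhe-II-087c,tBu,H,H,H,Br,5.21,7.47,0.55,-2.3
8,Xhe-II-006,H,H,tBu,H,Br,5.33,8.33,0.67,-1.44
9,PWZ-007A,H,H,OMe,H,H,5.35,10,0.69,0.23
10,Xhe-III-063,H,H,H,H,CCH,5.37,10.14,0.71,0.37
11,LAU 176,H,H,OMe,H,OMe,5.42,9.85,0.76,0.08
12,Xhe-II-17,H,H,tBu,H,CCH,5.42,8.48,0.76,-1.29
13,LAU 156,H,H,Cl,H,Me,5.64,10.3,0.98,0.53
14,PZ-II-028,H,H,Cl,H,OMe,5.79,9.7,1.13,-0.07
15,LAU 163,H,H,Cl,H,H,5.92,-,1.26,
16,LAU 177,H,H,OMe,H,CN,6,9.12,1.34,-0.65
17,LAU 162,H,H,Cl,H,COOEt,6.1,-,1.44,
18,LAU 206,H,H,Cl,H,NH2,6.22,9.92,1.56,0.15
19,LAU 161,H,H,Cl,H,CN,6.4,-,1.74,
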