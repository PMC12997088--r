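study,author,TP,FP,FN,TN,cutoff
1,Icardi,53,6,3,47,1.19
2,Cid,100,10,15,7,1.5
3,Gamez-Diaz,266,73,138,133,1.7
4,Groselj-Gren,13,6,4,23,1.86
5,Gros,91,16,54,132,2.2
6,Bhandari,89,63,39,102,2.3
7,Groselj-Gren,17,0,7,12,2.38
8,Groselj-Gren,19,3,10,24,2.45
9,Dilli,31,6,4,36,4.39
10,Genel,40,8,9,27,3.05 MFI
11,Tang,50,10,14,32,8.5 MFI
12,Hussein,17,2,1,16,43.5 MFI
13,Mokuda,14,2,1,23,1800 mol
14,Nishino,19,2,6,34,2000 mol
15,Doi,19,1,12,67,2000 mol
16,Tanaka,28,2,18,93,2000 mol
17,Matsui,51,7,4,195,2000 mol
18,Allen,23,4,4,40,2000 mol
19,Cardelli,50,3,2,57,2398 mol
20,Livaditi,35,0,2,10,2566 mol
21,Ng,30,7,2,51,4000 mol
22,Hsu,49,1,6,10,4300 mol
23,Lam,107,37,29,137,6010 mol
24,Ng,72,20,21,175,6136 mol
25,Ng,91,25,24,198,6136 mol
26,Tillinger,21,2,1,74,10000 mol
27,Layseca-Esp,8,1,23,16,
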