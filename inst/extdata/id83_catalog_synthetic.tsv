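# Synthetic ID83 reference catalog (stand-in profiles, not COSMIC v3 estimates).
# ID2 1-bp T-del at long homopolymers; ID4 short repeat deletions;
# ID6 microhomology deletions (HRD); ID7 1-bp C-del at long homopolymers (MMR);
# ID8 long (5+ bp) deletions.
channel	ID2	ID4	ID6	ID7	ID8
1:Del:C:0	0.00180723	0.00240964	0.00180723	0.00180723	0.00180723
1:Del:C:1	0.00180723	0.00240964	0.00180723	0.00180723	0.00180723
1:Del:C:2	0.00180723	0.00240964	0.00180723	0.00180723	0.00180723
1:Del:C:3	0.00180723	0.00240964	0.00180723	0.28514056	0.00180723
1:Del:C:4	0.00180723	0.00240964	0.00180723	0.28514056	0.00180723
1:Del:C:5	0.00180723	0.00240964	0.00180723	0.28514056	0.00180723
1:Del:T:0	0.00180723	0.00240964	0.00180723	0.00180723	0.00180723
1:Del:T:1	0.00180723	0.00240964	0.00180723	0.00180723	0.00180723
1:Del:T:2	0.00180723	0.00240964	0.00180723	0.00180723	0.00180723
1:Del:T:3	0.28514056	0.00240964	0.00180723	0.00180723	0.00180723
1:Del:T:4	0.28514056	0.00240964	0.00180723	0.00180723	0.00180723
1:Del:T:5	0.28514056	0.00240964	0.00180723	0.00180723	0.00180723
1:Ins:C:0	0.00180723	0.00240964	0.00180723	0.00180723	0.00180723
1:Ins:C:1	0.00180723	0.00240964	0.00180723	0.00180723	0.00180723
1:Ins:C:2	0.00180723	0.00240964	0.00180723	0.00180723	0.00180723
1:Ins:C:3	0.00180723	0.00240964	0.00180723	0.00180723	0.00180723
1:Ins:C:4	0.00180723	0.00240964	0.00180723	0.00180723	0.00180723
1:Ins:C:5	0.00180723	0.00240964	0.00180723	0.00180723	0.00180723
1:Ins:T:0	0.00180723	0.00240964	0.00180723	0.00180723	0.00180723
1:Ins:T:1	0.00180723	0.00240964	0.00180723	0.00180723	0.00180723
1:Ins:T:2	0.00180723	0.00240964	0.00180723	0.00180723	0.00180723
1:Ins:T:3	0.00180723	0.00240964	0.00180723	0.00180723	0.00180723
1:Ins:T:4	0.00180723	0.00240964	0.00180723	0.00180723	0.00180723
1:Ins:T:5	0.00180723	0.00240964	0.00180723	0.00180723	0.00180723
2:Del:R:0	0.00180723	0.00240964	0.00180723	0.00180723	0.00180723
2:Del:R:1	0.00180723	0.13574297	0.00180723	0.00180723	0.00180723
2:Del:R:2	0.00180723	0.13574297	0.00180723	0.00180723	0.00180723
2:Del:R:3	0.00180723	0.13574297	0.00180723	0.00180723	0.00180723
2:Del:R:4	0.00180723	0.00240964	0.00180723	0.00180723	0.00180723
2:Del:R:5	0.00180723	0.00240964	0.00180723	0.00180723	0.00180723
3:Del:R:0	0.00180723	0.00240964	0.00180723	0.00180723	0.00180723
3:Del:R:1	0.00180723	0.13574297	0.00180723	0.00180723	0.00180723
3:Del:R:2	0.00180723	0.13574297	0.00180723	0.00180723	0.00180723
3:Del:R:3	0.00180723	0.13574297	0.00180723	0.00180723	0.00180723
3:Del:R:4	0.00180723	0.00240964	0.00180723	0.00180723	0.00180723
3:Del:R:5	0.00180723	0.00240964	0.00180723	0.00180723	0.00180723
4:Del:R:0	0.00180723	0.00240964	0.00180723	0.00180723	0.00180723
4:Del:R:1	0.00180723	0.00240964	0.00180723	0.00180723	0.00180723
4:Del:R:2	0.00180723	0.00240964	0.00180723	0.00180723	0.00180723
4:Del:R:3	0.00180723	0.00240964	0.00180723	0.00180723	0.00180723
4:Del:R:4	0.00180723	0.00240964	0.00180723	0.00180723	0.00180723
4:Del:R:5	0.00180723	0.00240964	0.00180723	0.00180723	0.00180723
5:Del:R:0	0.00180723	0.00240964	0.00180723	0.00180723	0.1434739
5:Del:R:1	0.00180723	0.00240964	0.00180723	0.00180723	0.1434739
5:Del:R:2	0.00180723	0.00240964	0.00180723	0.00180723	0.1434739
5:Del:R:3	0.00180723	0.00240964	0.00180723	0.00180723	0.1434739
5:Del:R:4	0.00180723	0.00240964	0.00180723	0.00180723	0.1434739
5:Del:R:5	0.00180723	0.00240964	0.00180723	0.00180723	0.1434739
2:Ins:R:0	0.00180723	0.00240964	0.00180723	0.00180723	0.00180723
2:Ins:R:1	0.00180723	0.00240964	0.00180723	0.00180723	0.00180723
2:Ins:R:2	0.00180723	0.00240964	0.00180723	0.00180723	0.00180723
2:Ins:R:3	0.00180723	0.00240964	0.00180723	0.00180723	0.00180723
2:Ins:R:4	0.00180723	0.00240964	0.00180723	0.00180723	0.00180723
2:Ins:R:5	0.00180723	0.00240964	0.00180723	0.00180723	0.00180723
3:Ins:R:0	0.00180723	0.00240964	0.00180723	0.00180723	0.00180723
3:Ins:R:1	0.00180723	0.00240964	0.00180723	0.00180723	0.00180723
3:Ins:R:2	0.00180723	0.00240964	0.00180723	0.00180723	0.00180723
3:Ins:R:3	0.00180723	0.00240964	0.00180723	0.00180723	0.00180723
3:Ins:R:4	0.00180723	0.00240964	0.00180723	0.00180723	0.00180723
3:Ins:R:5	0.00180723	0.00240964	0.00180723	0.00180723	0.00180723
4:Ins:R:0	0.00180723	0.00240964	0.00180723	0.00180723	0.00180723
4:Ins:R:1	0.00180723	0.00240964	0.00180723	0.00180723	0.00180723
4:Ins:R:2	0.00180723	0.00240964	0.00180723	0.00180723	0.00180723
4:Ins:R:3	0.00180723	0.00240964	0.00180723	0.00180723	0.00180723
4:Ins:R:4	0.00180723	0.00240964	0.00180723	0.00180723	0.00180723
4:Ins:R:5	0.00180723	0.00240964	0.00180723	0.00180723	0.00180723
5:Ins:R:0	0.00180723	0.00240964	0.00180723	0.00180723	0.00180723
5:Ins:R:1	0.00180723	0.00240964	0.00180723	0.00180723	0.00180723
5:Ins:R:2	0.00180723	0.00240964	0.00180723	0.00180723	0.00180723
5:Ins:R:3	0.00180723	0.00240964	0.00180723	0.00180723	0.00180723
5:Ins:R:4	0.00180723	0.00240964	0.00180723	0.00180723	0.00180723
5:Ins:R:5	0.00180723	0.00240964	0.00180723	0.00180723	0.00180723
2:Del:M:1	0.00180723	0.00240964	0.07907996	0.00180723	0.00180723
3:Del:M:1	0.00180723	0.00240964	0.07907996	0.00180723	0.00180723
3:Del:M:2	0.00180723	0.00240964	0.07907996	0.00180723	0.00180723
4:Del:M:1	0.00180723	0.00240964	0.07907996	0.00180723	0.00180723
4:Del:M:2	0.00180723	0.00240964	0.07907996	0.00180723	0.00180723
4:Del:M:3	0.00180723	0.00240964	0.07907996	0.00180723	0.00180723
5:Del:M:1	0.00180723	0.00240964	0.07907996	0.00180723	0.00180723
5:Del:M:2	0.00180723	0.00240964	0.07907996	0.00180723	0.00180723
5:Del:M:3	0.00180723	0.00240964	0.07907996	0.00180723	0.00180723
5:Del:M:4	0.00180723	0.00240964	0.07907996	0.00180723	0.00180723
5:Del:M:5	0.00180723	0.00240964	0.07907996	0.00180723	0.00180723
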