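assay_no	catalog_no	assay_id	role	target_sequence
1	YP00205943	miR-20b	target	CAAAGUGCUCACAGUGCAGGUA
2	YP02113807	miR-10a	target	UACCCUGUAGAUCCGAAUUUGU
3	YP02110018	miR-141	target	AACACUGUCUGGUAAAGAUGG
4	YP02102101	miR-142	target	CCCAUAAAGUAGAAAGCACUA
5	YP02100678	miR-188	target	CAUCCCUUGCAUGGUGGAGGGU
6	YP02113947	miR-196b	target	UAGGUAGUUUCCUGUUGUUGGGA
7	YP02104713	miR-221	target	AGCUACAUUGUCUGCUGGGUUU
8	YP02116318	miR-32	target	UAUUGCACAUUACUAAGUUGCAU
9	YP02114619	miR-411	target	AUAGUAGACCGUAUAGCGUACG
10	YP02115385	miR-503	target	UAGCAGCGGGAACAGUACUG
11	YP02102538	miR-18a	target	UAAGGUGCAUCUAGUGCAGAUA
12	YP02100265	miR-18b	target	UAAGGUGCAUCUAGUGCAGUUA
13	YP00204130	miR-135b	target	UAUGGCUUUUCAUUCCUAUGUGA
14	YP00204688	miR-146a	target	UGAGAACUGAAUUCCAUGGGUU
15	YP00204660	miR-150	target	UCUCCCAACCCUUGUACCAGUG
16	YP00204018	miR-187	target	UCGUGUCUUGUGUUGCAGCCGG
17	YP00204665	miR-193a	target	UGGGUCUUUGCGGGCGAGAUGA
18	YP00204482	miR-200c	target	UAAUACUGCCGGGUAAUGAUGGA
19	YP00205616	miR-202	target	UUCCUAUGCAUAUACUUCUUUG
20	YP00205914	miR-203a	target	GUGAAAUGUUUAGGACCACUAG
21	YP00204487	miR-205	target	UCCUUCAUUCCACCGGAGUCUG
22	YP00205401	miR-212	target	ACCUUGGCUCUAGACUGCUUACU
23	YP00204364	miR-328	target	CUGGCCCUCUCUGCCCUUCCGU
24	YP02119293	miR-335	target	UCAAGAGCAAUAACGAAAAAUGU
25	YP00204486	miR-34a	target	UGGCAGUGUCUUAGCUGGUUGU
26	YP00205659	miR-34c	target	AGGCAGUGUAGUUAGCUGAUUGC
27	YP00204618	miR-362	target	AAUCCUUGGAACCUAGGUGUGAGU
28	YP00204011	miR-370	target	GCCUGCUGGGGUGGAACCUGGU
29	YP00204362	miR-375	target	UUUGUUCGUUCGGCUCGCGUGA
30	YP00204218	miR-376b	target	AUCAUAGAGGAAAAUCCAUGUU
31	YP00204301	miR-452	target	AACUGUUUGCAGAGGAAACUGA
32	YP00204489	miR-487b	target	AAUCGUACAGGGUCAUCCACUU
33	YP00204579	miR-494	target	UGAAACAUACACGGGAAACCUC
34	YP00205657	miR-505	target	GGGAGCCAGGAAGUAUUGAUGU
35	YP00204447	miR-543	target	AAACAUUCGCGGUGCACUUCUU
36	YP00205983	miR-99b	target	CACCCGUAGAACCGACCUUGCG
37	YP00205427	miR-376c	target	GUGGAUAUUCCUUCUAUGUUUA
38	YP02119694	miR-7a	target	UGGAAGACUAGUGAUUUUGUUGU
39	YP00205120	miR-223	target	UGUCAGUUUGUCAAAUACCCC
40	YP00205141	miR-493	target	UGAAGGUCUACUGUGUGCCAG
41	YP00203907	U6 snRNA	control	
42	YP02119288	UniSP3	control	
43	YP00203954	UniSp6	control	
44	YP02121094	miR-8859a	normalizer	UGGAUCGGAGCCGGGGUCCGGA
45	YP02121097	miR-8859b	normalizer	GGUCGGAUUCCGUGCCUGGAGU
46	YP02121124	miR-8884	normalizer	UUUGAUGGAUUUGCUUAGCACC
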