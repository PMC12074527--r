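rsid	effect_allele	other_allele	beta	freq
rs4922684	G	T	-0.026	0.422
rs5130484	C	T	-0.0901	0.561
rs1984602	T	G	-0.0353	0.25
rs9473373	T	A	-0.0278	0.227
rs6133625	C	T	0.0104	0.438
rs1769712	C	T	-0.0533	0.736
rs4252771	T	C	0.0125	0.342
rs7632783	G	C	0.05	0.939
rs3536071	C	A	-0.0289	0.184
rs8309647	A	G	-0.0288	0.799
rs4510053	C	T	-0.0125	0.762
rs9618382	A	C	-0.0017	0.301
rs5815081	T	G	-0.0236	0.08
rs7987202	C	G	0.0327	0.542
rs6613325	A	T	-0.0532	0.088
rs1120240	T	A	0.069	0.921
rs6775787	A	T	0.0126	0.301
rs8298362	C	A	0.0024	0.663
rs1034656	G	T	-0.0361	0.854
rs2116928	A	T	0.0162	0.242
rs1745842	T	C	0.0242	0.898
rs8793352	C	G	0	0.324
rs6561431	T	G	-0.0608	0.426
rs6106811	A	C	-0.0577	0.507
rs6543529	G	T	0.0478	0.451
rs5844815	T	G	-0.0415	0.157
rs5053274	A	T	-0.0102	0.702
rs1093046	A	C	-0.0827	0.281
rs2399518	C	A	-0.0543	0.115
rs3761584	T	C	0.0495	0.702
rs6606953	T	A	-0.0458	0.056
rs2551535	C	A	0.0573	0.589
rs6137781	C	T	-0.0643	0.748
rs4945010	C	G	-0.0111	0.872
rs6253825	G	A	-0.0515	0.844
rs6078108	G	T	-0.0493	0.569
rs8286609	G	T	0.031	0.238
rs1705654	A	C	-0.048	0.569
rs3354002	C	A	-0.0102	0.517
rs7606856	C	G	0.0642	0.448
rs6715062	C	T	0.0386	0.571
rs5441283	G	T	0.0021	0.626
rs1538590	C	G	-0.0097	0.379
rs6523773	G	C	-0.0172	0.209
rs4220726	A	T	0.0239	0.333
rs7059352	T	C	0.043	0.869
rs1903763	A	C	-0.0835	0.532
rs2456689	C	A	0.0346	0.571
rs9517473	G	A	-0.0165	0.457
rs2658359	T	A	-0.0158	0.743
rs9071610	C	T	0.0652	0.095
rs7623256	A	C	-0.0152	0.168
rs6565509	C	T	-0.0706	0.343
rs6946567	T	A	-0.0564	0.694
rs5497792	G	C	0.1205	0.508
rs4488604	G	C	-0.0381	0.553
rs7175511	C	A	0.0081	0.551
rs5024293	G	C	0.0791	0.722
rs4959612	T	A	-0.0492	0.541
rs5857192	G	C	-0.0215	0.807
rs6330775	G	C	-0.0091	0.815
rs9498123	G	T	0.013	0.379
rs3834284	T	C	2e-04	0.555
rs4209457	T	A	-0.0684	0.538
rs5804076	G	C	0.0163	0.498
rs9561288	G	C	0.0919	0.578
rs2316983	A	C	0.0161	0.43
rs1778419	C	A	0.0194	0.225
rs2380259	T	G	0.0135	0.895
rs9394282	G	A	0.035	0.695
rs6686676	G	C	-0.0352	0.687
rs7195434	G	T	-0.0041	0.884
rs2971530	C	A	0.0653	0.899
rs5637119	C	G	-0.0359	0.381
rs8353336	C	A	-0.0176	0.85
rs2111283	A	G	0.0193	0.431
rs9537756	T	C	-0.0401	0.34
rs4916656	C	A	0.0897	0.601
rs7406249	A	G	-0.0391	0.41
rs8663390	C	A	-0.024	0.094
rs4062352	T	C	0.0427	0.195
rs6782190	C	A	0.0201	0.913
rs4535456	C	T	0.0122	0.157
rs6560818	G	A	-0.0429	0.304
rs5888868	T	C	-0.0279	0.074
rs6546056	C	T	0.0988	0.397
rs7529396	T	A	-0.0991	0.679
rs1578708	T	C	-0.0855	0.189
rs7032873	C	T	-0.0021	0.223
rs1417555	A	T	0.0373	0.395
rs2053768	T	G	0.0727	0.514
rs3062796	A	G	0.0481	0.37
rs9246014	C	A	0.0024	0.836
rs6144037	G	C	-0.0063	0.344
rs3935651	C	T	-0.1711	0.73
rs8864871	C	G	0.0572	0.799
rs2696617	A	C	0.0474	0.533
rs2773463	C	A	-0.0479	0.423
rs1326241	A	T	-0.0085	0.074
rs9370582	A	G	0.0236	0.219
rs4295834	T	A	0.0452	0.224
rs9111870	T	G	0.0629	0.165
rs5771163	T	G	-0.0239	0.903
rs7797946	A	T	0.0142	0.6
rs2023779	C	T	0.0336	0.31
rs2889320	G	A	0.0348	0.141
rs7393425	A	G	-0.0256	0.94
rs3924197	T	C	-0.0557	0.817
rs2875748	G	C	-0.1081	0.231
rs8858466	A	G	0.0172	0.343
rs2728492	C	G	0.0438	0.874
rs4564021	C	A	-0.0086	0.129
rs1188176	C	T	-0.0985	0.436
rs9585791	G	A	-0.0917	0.366
rs1186996	G	C	-0.0524	0.584
rs1023875	G	A	-0.064	0.437
rs2122900	T	A	0.054	0.695
rs1686618	G	C	-0.0399	0.189
rs6451117	A	G	-0.0536	0.185
rs6905514	A	T	-0.0918	0.617
rs5184097	G	A	-0.03	0.078
rs9590190	C	G	0.066	0.548
rs7951457	G	C	-0.059	0.753
rs2850472	A	C	-0.0337	0.439
rs9729118	T	C	-0.0512	0.291
rs5619344	T	A	-0.0185	0.536
rs1013316	C	A	0.1045	0.801
rs3917736	C	G	-0.0367	0.676
rs8875332	C	G	0.0107	0.072
rs7703356	G	T	0.007	0.862
rs1331115	C	G	-0.0308	0.354
rs2445520	T	G	0.0465	0.773
rs2704102	T	A	0.0756	0.088
rs5549119	G	A	0.0468	0.711
rs3482778	C	G	0.0716	0.893
rs8019706	C	A	-2e-04	0.881
rs6841539	A	C	-7e-04	0.057
rs3716422	G	C	0.0174	0.163
rs8722259	T	A	0.0603	0.733
rs4465385	A	C	0.1036	0.69
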