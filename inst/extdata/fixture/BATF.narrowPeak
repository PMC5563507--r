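chr1	320962	321282	BATF_peak_0001	0	.	0	8.114	8.114	160
chr1	460379	460807	BATF_peak_0002	0	.	0	5.364	5.364	214
chr1	1310520	1310750	BATF_peak_0003	0	.	0	4.858	4.858	115
chr1	1540570	1540812	BATF_peak_0004	0	.	0	5.302	5.302	121
chr1	1635933	1636171	BATF_peak_0005	0	.	0	6.215	6.215	119
chr1	1694324	1694650	BATF_peak_0006	0	.	0	10.283	10.283	163
chr1	1785927	1786340	BATF_peak_0007	0	.	0	10.428	10.428	206
chr1	2285289	2285557	BATF_peak_0008	0	.	0	3.867	3.867	134
chr1	2869495	2869962	BATF_peak_0009	0	.	0	6.487	6.487	233
chr1	2943954	2944374	BATF_peak_0010	0	.	0	14.308	14.308	210
chr2	278296	278751	BATF_peak_0011	0	.	0	7.386	7.386	227
chr2	361560	361871	BATF_peak_0012	0	.	0	7.14	7.14	155
chr2	502014	502403	BATF_peak_0013	0	.	0	8.15	8.15	194
chr2	1290519	1290761	BATF_peak_0014	0	.	0	6.691	6.691	121
chr2	1332995	1333319	BATF_peak_0015	0	.	0	5.817	5.817	162
chr2	2805718	2806126	BATF_peak_0016	0	.	0	5.105	5.105	204
chr3	41317	41707	BATF_peak_0017	0	.	0	12.571	12.571	195
chr3	59201	59412	BATF_peak_0018	0	.	0	20.119	20.119	105
chr3	92968	93457	BATF_peak_0019	0	.	0	7.506	7.506	244
chr3	385081	385402	BATF_peak_0020	0	.	0	14.998	14.998	160
chr3	1017445	1017749	BATF_peak_0021	0	.	0	9.038	9.038	152
chr3	1620141	1620348	BATF_peak_0022	0	.	0	2.819	2.819	103
chr3	1717865	1718108	BATF_peak_0023	0	.	0	12.502	12.502	121
chr3	1923506	1923973	BATF_peak_0024	0	.	0	8.394	8.394	233
chr3	2369355	2369730	BATF_peak_0025	0	.	0	5.301	5.301	187
chr3	2680544	2680778	BATF_peak_0026	0	.	0	9.359	9.359	117
chr3	2815969	2816255	BATF_peak_0027	0	.	0	5.189	5.189	143
chr1	2551736	2551971	BATF_peak_0028	0	.	0	8.019	8.019	117
chr2	1924867	1925103	BATF_peak_0029	0	.	0	7.889	7.889	118
chr3	2982758	2983239	BATF_peak_0030	0	.	0	8.702	8.702	240
chr2	2631986	2632455	BATF_peak_0031	0	.	0	9.491	9.491	234
chr3	1601760	1602222	BATF_peak_0032	0	.	0	11.563	11.563	231
chr3	2788007	2788356	BATF_peak_0033	0	.	0	7.091	7.091	174
chr2	2419047	2419395	BATF_peak_0034	0	.	0	5.787	5.787	174
chr2	2882099	2882533	BATF_peak_0035	0	.	0	5.551	5.551	217
chr3	2349554	2349896	BATF_peak_0036	0	.	0	5.645	5.645	171
chr1	813173	813487	BATF_peak_0037	0	.	0	12.599	12.599	157
chr3	2392402	2392879	BATF_peak_0038	0	.	0	14.056	14.056	238
chr2	1605619	1605874	BATF_peak_0039	0	.	0	2.916	2.916	127
chr3	1426105	1426396	BATF_peak_0040	0	.	0	6.316	6.316	145
chr2	940664	940922	BATF_peak_0041	0	.	0	4.318	4.318	129
chr3	1431414	1431669	BATF_peak_0042	0	.	0	4.004	4.004	127
chr1	2195709	2196152	BATF_peak_0043	0	.	0	11.26	11.26	221
chr2	1747773	1748059	BATF_peak_0044	0	.	0	9.327	9.327	143
chr2	2882768	2883089	BATF_peak_0045	0	.	0	11.199	11.199	160
chr1	1597775	1598208	BATF_peak_0046	0	.	0	8.613	8.613	216
chr2	1500877	1501143	BATF_peak_0047	0	.	0	4.474	4.474	133
chr1	2599660	2599863	BATF_peak_0048	0	.	0	9.231	9.231	101
chr1	1184073	1184572	BATF_peak_0049	0	.	0	7.312	7.312	249
chr2	1683198	1683500	BATF_peak_0050	0	.	0	3.039	3.039	151
chr3	2968550	2968782	BATF_peak_0051	0	.	0	19.443	19.443	116
chr3	523318	523638	BATF_peak_0052	0	.	0	3.53	3.53	160
chr3	2796023	2796456	BATF_peak_0053	0	.	0	17.537	17.537	216
chr1	2798743	2799146	BATF_peak_0054	0	.	0	8.75	8.75	201
chr3	1089564	1089886	BATF_peak_0055	0	.	0	2.76	2.76	161
chr2	2687436	2687655	BATF_peak_0056	0	.	0	14.389	14.389	109
chr2	2846351	2846652	BATF_peak_0057	0	.	0	4.487	4.487	150
chr2	2216572	2216885	BATF_peak_0058	0	.	0	6.855	6.855	156
chr3	1425720	1425979	BATF_peak_0059	0	.	0	9.466	9.466	129
chr3	1037986	1038303	BATF_peak_0060	0	.	0	5.752	5.752	158
chr2	2900425	2900828	BATF_peak_0061	0	.	0	6.57	6.57	201
chr1	1129852	1130296	BATF_peak_0062	0	.	0	6.461	6.461	222
chr2	1545121	1545400	BATF_peak_0063	0	.	0	4.08	4.08	139
chr2	2998332	2998547	BATF_peak_0064	0	.	0	10.717	10.717	107
chr3	2003616	2003988	BATF_peak_0065	0	.	0	7.772	7.772	186
chr1	1805369	1805640	BATF_peak_0066	0	.	0	12.457	12.457	135
chr1	2305811	2306033	BATF_peak_0067	0	.	0	10.215	10.215	111
chr3	2974896	2975359	BATF_peak_0068	0	.	0	12.379	12.379	231
chr3	1327857	1328313	BATF_peak_0069	0	.	0	4.17	4.17	228
chr2	986627	986919	BATF_peak_0070	0	.	0	3.924	3.924	146
chr3	1854324	1854810	BATF_peak_0071	0	.	0	13.606	13.606	243
chr3	1433069	1433353	BATF_peak_0072	0	.	0	10.919	10.919	142
chr3	1329558	1329988	BATF_peak_0073	0	.	0	7.221	7.221	215
chr3	1090157	1090587	BATF_peak_0074	0	.	0	6.887	6.887	215
chr1	1595039	1595240	BATF_peak_0075	0	.	0	7.801	7.801	100
chr1	2029095	2029517	BATF_peak_0076	0	.	0	11.13	11.13	211
chr2	1419451	1419736	BATF_peak_0077	0	.	0	8.36	8.36	142
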