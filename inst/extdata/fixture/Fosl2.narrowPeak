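chr1	69604	69818	Fosl2_peak_0001	0	.	0	12.507	12.507	107
chr1	146071	146411	Fosl2_peak_0002	0	.	0	12.978	12.978	170
chr1	188222	188692	Fosl2_peak_0003	0	.	0	11.002	11.002	235
chr1	378295	378775	Fosl2_peak_0004	0	.	0	7.747	7.747	240
chr1	467108	467464	Fosl2_peak_0005	0	.	0	4.278	4.278	178
chr1	1348393	1348667	Fosl2_peak_0006	0	.	0	6.026	6.026	137
chr1	1676345	1676782	Fosl2_peak_0007	0	.	0	4.843	4.843	218
chr1	2109280	2109615	Fosl2_peak_0008	0	.	0	7.866	7.866	167
chr1	2336916	2337332	Fosl2_peak_0009	0	.	0	27.164	27.164	208
chr1	2585622	2585883	Fosl2_peak_0010	0	.	0	13.62	13.62	130
chr2	519525	519823	Fosl2_peak_0011	0	.	0	4.745	4.745	149
chr2	569971	570386	Fosl2_peak_0012	0	.	0	5.386	5.386	207
chr2	712781	713143	Fosl2_peak_0013	0	.	0	12.876	12.876	181
chr2	952231	952515	Fosl2_peak_0014	0	.	0	2.502	2.502	142
chr2	2078816	2079230	Fosl2_peak_0015	0	.	0	10.433	10.433	207
chr2	2124138	2124549	Fosl2_peak_0016	0	.	0	8.097	8.097	205
chr2	2467252	2467712	Fosl2_peak_0017	0	.	0	11.073	11.073	230
chr2	2657492	2657745	Fosl2_peak_0018	0	.	0	7.358	7.358	126
chr3	404273	404549	Fosl2_peak_0019	0	.	0	21.981	21.981	138
chr3	618013	618237	Fosl2_peak_0020	0	.	0	4.163	4.163	112
chr3	1060350	1060612	Fosl2_peak_0021	0	.	0	8.673	8.673	131
chr3	1104815	1105269	Fosl2_peak_0022	0	.	0	10.167	10.167	227
chr3	1151840	1152059	Fosl2_peak_0023	0	.	0	11.222	11.222	109
chr3	1202250	1202698	Fosl2_peak_0024	0	.	0	6.349	6.349	224
chr3	1717382	1717727	Fosl2_peak_0025	0	.	0	20.593	20.593	172
chr3	2199388	2199724	Fosl2_peak_0026	0	.	0	3.575	3.575	168
chr3	2261647	2261862	Fosl2_peak_0027	0	.	0	5.21	5.21	107
chr3	2364428	2364793	Fosl2_peak_0028	0	.	0	6.446	6.446	182
chr3	2754476	2754899	Fosl2_peak_0029	0	.	0	9.639	9.639	211
chr3	1248435	1248725	Fosl2_peak_0030	0	.	0	6.192	6.192	145
chr2	1354758	1355238	Fosl2_peak_0031	0	.	0	7.031	7.031	240
chr1	1330799	1331242	Fosl2_peak_0032	0	.	0	6.442	6.442	221
chr3	1599481	1599871	Fosl2_peak_0033	0	.	0	8.143	8.143	195
chr1	2310896	2311322	Fosl2_peak_0034	0	.	0	4.776	4.776	213
chr3	2840850	2841060	Fosl2_peak_0035	0	.	0	6.315	6.315	105
chr2	2702771	2703154	Fosl2_peak_0036	0	.	0	3.802	3.802	191
chr2	2768696	2769196	Fosl2_peak_0037	0	.	0	5.443	5.443	250
chr2	2672506	2672720	Fosl2_peak_0038	0	.	0	7.744	7.744	107
chr1	2933108	2933528	Fosl2_peak_0039	0	.	0	6.161	6.161	210
chr3	2792878	2793121	Fosl2_peak_0040	0	.	0	6.486	6.486	121
chr1	1093610	1093910	Fosl2_peak_0041	0	.	0	3.959	3.959	150
chr3	1419830	1420127	Fosl2_peak_0042	0	.	0	27.282	27.282	148
chr2	486577	486803	Fosl2_peak_0043	0	.	0	6.572	6.572	113
chr3	2707902	2708260	Fosl2_peak_0044	0	.	0	4.087	4.087	179
chr2	2057534	2057853	Fosl2_peak_0045	0	.	0	6.896	6.896	159
chr3	2453154	2453460	Fosl2_peak_0046	0	.	0	6.329	6.329	153
chr1	1272357	1272802	Fosl2_peak_0047	0	.	0	9.247	9.247	222
chr1	2552993	2553232	Fosl2_peak_0048	0	.	0	10.713	10.713	119
chr2	1557730	1558040	Fosl2_peak_0049	0	.	0	3.101	3.101	155
chr2	2739939	2740259	Fosl2_peak_0050	0	.	0	4.427	4.427	160
chr1	2078774	2079193	Fosl2_peak_0051	0	.	0	7.856	7.856	209
chr3	527989	528206	Fosl2_peak_0052	0	.	0	11.346	11.346	108
chr2	408323	408684	Fosl2_peak_0053	0	.	0	19.609	19.609	180
chr2	1923006	1923274	Fosl2_peak_0054	0	.	0	5.826	5.826	134
chr3	293156	293377	Fosl2_peak_0055	0	.	0	2.138	2.138	110
chr3	450815	451291	Fosl2_peak_0056	0	.	0	12.247	12.247	238
chr2	663098	663373	Fosl2_peak_0057	0	.	0	6.191	6.191	137
chr1	2794244	2794645	Fosl2_peak_0058	0	.	0	9.217	9.217	200
chr2	580702	580902	Fosl2_peak_0059	0	.	0	8.326	8.326	100
chr3	2054121	2054562	Fosl2_peak_0060	0	.	0	6.464	6.464	220
chr1	2790211	2790545	Fosl2_peak_0061	0	.	0	7.179	7.179	167
chr1	2618226	2618525	Fosl2_peak_0062	0	.	0	5.725	5.725	149
chr2	933975	934334	Fosl2_peak_0063	0	.	0	5.283	5.283	179
chr3	1221924	1222129	Fosl2_peak_0064	0	.	0	5.235	5.235	102
chr2	1398047	1398547	Fosl2_peak_0065	0	.	0	4.211	4.211	250
chr1	1476218	1476708	Fosl2_peak_0066	0	.	0	14.686	14.686	245
chr1	1497744	1498066	Fosl2_peak_0067	0	.	0	6.359	6.359	161
chr3	1858016	1858513	Fosl2_peak_0068	0	.	0	12.447	12.447	248
chr2	2114109	2114499	Fosl2_peak_0069	0	.	0	5.157	5.157	195
chr1	2371061	2371343	Fosl2_peak_0070	0	.	0	13.483	13.483	141
chr2	2085048	2085428	Fosl2_peak_0071	0	.	0	4.699	4.699	190
chr2	932494	932975	Fosl2_peak_0072	0	.	0	7.529	7.529	240
chr2	978599	979070	Fosl2_peak_0073	0	.	0	14.204	14.204	235
chr3	2103181	2103558	Fosl2_peak_0074	0	.	0	7.675	7.675	188
chr3	2345541	2345830	Fosl2_peak_0075	0	.	0	4.112	4.112	144
chr2	996053	996261	Fosl2_peak_0076	0	.	0	9.683	9.683	104
chr1	1441818	1442273	Fosl2_peak_0077	0	.	0	5.214	5.214	227
chr2	2981745	2982074	Fosl2_peak_0078	0	.	0	4.522	4.522	164
chr3	451995	452238	Fosl2_peak_0079	0	.	0	7.107	7.107	121
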