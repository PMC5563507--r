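chr1	10060	21349	g0001	0	+
chr1	32620	35871	g0002	0	-
chr1	49378	66883	g0003	0	-
chr1	81852	92677	g0004	0	-
chr1	107754	120042	g0005	0	+
chr1	135973	151412	g0006	0	-
chr1	167377	183736	g0007	0	-
chr1	200223	218962	g0008	0	+
chr1	235477	245176	g0009	0	-
chr1	262612	268565	g0010	0	-
chr1	286412	297502	g0011	0	-
chr1	315635	323037	g0012	0	-
chr1	341247	344178	g0013	0	-
chr1	362787	380358	g0014	0	+
chr1	400563	414698	g0015	0	+
chr1	437530	439788	g0016	0	-
chr1	463641	466121	g0017	0	-
chr1	489977	505586	g0018	0	-
chr1	529749	539074	g0019	0	-
chr1	564617	569070	g0020	0	+
chr1	594660	605833	g0021	0	-
chr1	633071	642859	g0022	0	+
chr1	670120	674671	g0023	0	+
chr1	702617	720922	g0024	0	-
chr1	748922	762540	g0025	0	-
chr1	790635	803858	g0026	0	-
chr1	832541	851651	g0027	0	-
chr1	881400	884344	g0028	0	-
chr1	914625	928133	g0029	0	+
chr1	959124	978133	g0030	0	-
chr1	1011524	1017881	g0031	0	+
chr1	1051366	1065783	g0032	0	-
chr1	1099841	1119620	g0033	0	+
chr1	1154683	1169344	g0034	0	-
chr1	1204684	1222448	g0035	0	-
chr1	1258219	1263036	g0036	0	+
chr1	1298921	1310127	g0037	0	-
chr1	1346426	1362607	g0038	0	+
chr1	1398981	1413918	g0039	0	+
chr1	1450670	1467045	g0040	0	+
chr1	1504299	1506815	g0041	0	+
chr1	1544414	1547358	g0042	0	-
chr1	1587015	1589117	g0043	0	-
chr1	1628842	1636189	g0044	0	-
chr1	1677628	1689976	g0045	0	-
chr1	1731427	1742971	g0046	0	+
chr1	1784634	1790805	g0047	0	+
chr1	1832696	1850011	g0048	0	+
chr1	1892068	1899964	g0049	0	-
chr1	1943375	1950985	g0050	0	-
chr1	1994594	2007566	g0051	0	+
chr1	2051472	2053487	g0052	0	+
chr1	2097523	2113191	g0053	0	+
chr1	2157252	2174593	g0054	0	+
chr1	2219311	2222298	g0055	0	-
chr1	2268014	2286003	g0056	0	-
chr1	2331901	2341710	g0057	0	-
chr1	2387751	2398024	g0058	0	+
chr1	2444251	2460482	g0059	0	+
chr1	2507651	2523843	g0060	0	+
chr1	2571543	2589262	g0061	0	-
chr1	2638754	2656040	g0062	0	-
chr1	2706162	2710505	g0063	0	-
chr1	2760677	2762825	g0064	0	-
chr1	2813680	2822819	g0065	0	+
chr1	2873786	2892269	g0066	0	+
chr1	2943556	2947901	g0067	0	+
chr2	10884	25233	g0068	0	+
chr2	36453	56129	g0069	0	-
chr2	69358	73372	g0070	0	+
chr2	86703	90108	g0071	0	-
chr2	104000	113230	g0072	0	-
chr2	127296	131904	g0073	0	-
chr2	146415	153083	g0074	0	+
chr2	167616	177411	g0075	0	+
chr2	192770	208850	g0076	0	-
chr2	224658	234738	g0077	0	+
chr2	250914	252915	g0078	0	-
chr2	269632	280494	g0079	0	+
chr2	298171	313609	g0080	0	-
chr2	331458	342390	g0081	0	-
chr2	360610	371506	g0082	0	+
chr2	393714	398983	g0083	0	+
chr2	421328	435606	g0084	0	-
chr2	458523	471729	g0085	0	+
chr2	495450	498674	g0086	0	+
chr2	522616	526560	g0087	0	-
chr2	550811	567996	g0088	0	-
chr2	594180	602063	g0089	0	-
chr2	628571	647417	g0090	0	-
chr2	675699	684447	g0091	0	-
chr2	713950	725478	g0092	0	+
chr2	756234	760365	g0093	0	-
chr2	791710	797667	g0094	0	+
chr2	829577	841987	g0095	0	+
chr2	874259	883324	g0096	0	+
chr2	915848	923947	g0097	0	-
chr2	956885	972763	g0098	0	-
chr2	1005941	1017982	g0099	0	-
chr2	1052049	1063349	g0100	0	+
chr2	1098395	1104643	g0101	0	-
chr2	1139734	1156309	g0102	0	+
chr2	1192275	1210707	g0103	0	-
chr2	1246682	1248837	g0104	0	-
chr2	1285233	1297746	g0105	0	+
chr2	1335351	1348840	g0106	0	-
chr2	1386495	1390712	g0107	0	-
chr2	1428408	1436366	g0108	0	+
chr2	1475567	1480220	g0109	0	+
chr2	1519561	1524253	g0110	0	+
chr2	1563903	1570905	g0111	0	-
chr2	1612185	1619012	g0112	0	-
chr2	1662937	1675726	g0113	0	+
chr2	1720694	1738415	g0114	0	-
chr2	1783743	1797901	g0115	0	+
chr2	1843364	1849308	g0116	0	-
chr2	1895120	1907114	g0117	0	+
chr2	1953289	1964717	g0118	0	+
chr2	2011825	2019236	g0119	0	-
chr2	2066723	2076316	g0120	0	-
chr2	2125108	2133054	g0121	0	-
chr2	2181882	2200807	g0122	0	+
chr2	2252647	2261489	g0123	0	+
chr2	2314934	2330714	g0124	0	+
chr2	2384363	2399567	g0125	0	-
chr2	2455562	2464671	g0126	0	+
chr2	2521964	2527594	g0127	0	-
chr2	2585701	2593022	g0128	0	-
chr2	2651804	2660338	g0129	0	+
chr2	2719893	2728304	g0130	0	+
chr2	2788333	2801391	g0131	0	+
chr2	2863309	2870950	g0132	0	-
chr2	2933617	2937241	g0133	0	+
chr3	11951	26425	g0134	0	-
chr3	39915	44015	g0135	0	+
chr3	58051	77517	g0136	0	-
chr3	91746	108763	g0137	0	-
chr3	123650	135269	g0138	0	+
chr3	150457	158687	g0139	0	+
chr3	173949	176176	g0140	0	-
chr3	191774	195814	g0141	0	-
chr3	211440	215032	g0142	0	+
chr3	233547	249518	g0143	0	-
chr3	268065	284281	g0144	0	+
chr3	302914	306111	g0145	0	+
chr3	325396	338833	g0146	0	-
chr3	358164	364262	g0147	0	+
chr3	385829	404819	g0148	0	-
chr3	426943	439885	g0149	0	-
chr3	462505	479242	g0150	0	-
chr3	502415	517469	g0151	0	-
chr3	540718	554577	g0152	0	+
chr3	578583	589595	g0153	0	+
chr3	613741	622753	g0154	0	-
chr3	647698	655783	g0155	0	+
chr3	681598	701480	g0156	0	+
chr3	728128	743607	g0157	0	+
chr3	771476	776634	g0158	0	-
chr3	805875	810418	g0159	0	+
chr3	840281	857842	g0160	0	+
chr3	887784	906277	g0161	0	+
chr3	936566	939708	g0162	0	+
chr3	970446	989448	g0163	0	-
chr3	1020543	1031461	g0164	0	-
chr3	1062773	1078138	g0165	0	-
chr3	1109768	1111794	g0166	0	+
chr3	1143698	1159235	g0167	0	+
chr3	1191192	1201975	g0168	0	-
chr3	1234542	1237675	g0169	0	+
chr3	1270817	1274569	g0170	0	-
chr3	1308230	1317297	g0171	0	-
chr3	1351561	1358183	g0172	0	+
chr3	1393861	1411973	g0173	0	-
chr3	1451259	1464545	g0174	0	-
chr3	1503972	1515504	g0175	0	+
chr3	1555339	1570989	g0176	0	+
chr3	1611145	1627225	g0177	0	-
chr3	1667487	1672027	g0178	0	+
chr3	1712752	1718160	g0179	0	-
chr3	1759755	1762774	g0180	0	-
chr3	1805078	1824697	g0181	0	-
chr3	1867026	1879769	g0182	0	+
chr3	1922181	1925715	g0183	0	-
chr3	1968309	1971924	g0184	0	-
chr3	2014874	2029013	g0185	0	-
chr3	2073782	2082749	g0186	0	-
chr3	2127527	2143062	g0187	0	+
chr3	2188145	2195786	g0188	0	+
chr3	2241172	2257848	g0189	0	+
chr3	2303394	2320731	g0190	0	+
chr3	2366692	2378554	g0191	0	+
chr3	2425435	2440381	g0192	0	+
chr3	2487365	2506673	g0193	0	+
chr3	2553749	2570254	g0194	0	+
chr3	2618278	2636045	g0195	0	-
chr3	2684531	2700703	g0196	0	+
chr3	2749621	2767484	g0197	0	+
chr3	2817381	2823634	g0198	0	-
chr3	2873929	2889859	g0199	0	+
chr3	2940166	2949250	g0200	0	-
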