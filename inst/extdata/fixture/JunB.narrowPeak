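chr1	318837	319313	JunB_peak_0001	0	.	0	7.202	7.202	238
chr1	469806	470209	JunB_peak_0002	0	.	0	4.013	4.013	201
chr1	486334	486573	JunB_peak_0003	0	.	0	8.861	8.861	119
chr1	538132	538629	JunB_peak_0004	0	.	0	3.197	3.197	248
chr1	634064	634485	JunB_peak_0005	0	.	0	28.908	28.908	210
chr1	712862	713113	JunB_peak_0006	0	.	0	3.854	3.854	125
chr1	973671	973977	JunB_peak_0007	0	.	0	4.694	4.694	153
chr1	2001120	2001346	JunB_peak_0008	0	.	0	10.793	10.793	113
chr1	2330391	2330660	JunB_peak_0009	0	.	0	14.028	14.028	134
chr1	2461931	2462332	JunB_peak_0010	0	.	0	5.645	5.645	200
chr1	2644212	2644619	JunB_peak_0011	0	.	0	11.803	11.803	203
chr1	2703336	2703543	JunB_peak_0012	0	.	0	13.914	13.914	103
chr1	2820935	2821322	JunB_peak_0013	0	.	0	15.729	15.729	193
chr2	331730	332203	JunB_peak_0014	0	.	0	15.387	15.387	236
chr2	365397	365712	JunB_peak_0015	0	.	0	5.003	5.003	157
chr2	723224	723482	JunB_peak_0016	0	.	0	2.708	2.708	129
chr2	915149	915462	JunB_peak_0017	0	.	0	4.234	4.234	156
chr2	957160	957509	JunB_peak_0018	0	.	0	3.221	3.221	174
chr2	1514843	1515112	JunB_peak_0019	0	.	0	8.76	8.76	134
chr2	1839952	1840415	JunB_peak_0020	0	.	0	1.691	1.691	231
chr2	2204654	2204898	JunB_peak_0021	0	.	0	3.402	3.402	122
chr2	2401284	2401521	JunB_peak_0022	0	.	0	8.794	8.794	118
chr3	727273	727482	JunB_peak_0023	0	.	0	12.166	12.166	104
chr3	1265727	1266183	JunB_peak_0024	0	.	0	8.373	8.373	228
chr3	1352407	1352749	JunB_peak_0025	0	.	0	14.751	14.751	171
chr3	1610064	1610392	JunB_peak_0026	0	.	0	7.732	7.732	164
chr3	1674968	1675185	JunB_peak_0027	0	.	0	9.583	9.583	108
chr3	1924691	1925140	JunB_peak_0028	0	.	0	5.404	5.404	224
chr3	2317709	2318138	JunB_peak_0029	0	.	0	5.154	5.154	214
chr3	2430529	2430872	JunB_peak_0030	0	.	0	3.839	3.839	171
chr3	2926420	2926644	JunB_peak_0031	0	.	0	9.454	9.454	112
chr1	2551374	2551781	JunB_peak_0032	0	.	0	10.686	10.686	203
chr2	1998582	1998997	JunB_peak_0033	0	.	0	5.355	5.355	207
chr3	1587646	1587955	JunB_peak_0034	0	.	0	8.338	8.338	154
chr2	2777016	2777289	JunB_peak_0035	0	.	0	3.849	3.849	136
chr1	1382564	1382979	JunB_peak_0036	0	.	0	16.383	16.383	207
chr3	1753753	1754144	JunB_peak_0037	0	.	0	10.878	10.878	195
chr3	2066783	2067130	JunB_peak_0038	0	.	0	2.839	2.839	173
chr2	1469921	1470388	JunB_peak_0039	0	.	0	7.836	7.836	233
chr2	900550	900952	JunB_peak_0040	0	.	0	3.939	3.939	201
chr1	2209994	2210438	JunB_peak_0041	0	.	0	6.862	6.862	222
chr1	157024	157512	JunB_peak_0042	0	.	0	9.785	9.785	244
chr3	675662	675952	JunB_peak_0043	0	.	0	9.721	9.721	145
chr3	2167533	2167740	JunB_peak_0044	0	.	0	6.958	6.958	103
chr1	2972169	2972439	JunB_peak_0045	0	.	0	13.64	13.64	135
chr1	1879413	1879760	JunB_peak_0046	0	.	0	5.612	5.612	173
chr1	2604833	2605057	JunB_peak_0047	0	.	0	5.715	5.715	112
chr1	1431326	1431596	JunB_peak_0048	0	.	0	8.036	8.036	135
chr2	2772029	2772389	JunB_peak_0049	0	.	0	4.955	4.955	180
chr1	2838255	2838455	JunB_peak_0050	0	.	0	3.932	3.932	100
chr2	1969982	1970413	JunB_peak_0051	0	.	0	7.443	7.443	215
chr1	1073979	1074373	JunB_peak_0052	0	.	0	10.952	10.952	197
chr3	1056303	1056684	JunB_peak_0053	0	.	0	8.633	8.633	190
chr3	945319	945627	JunB_peak_0054	0	.	0	11.7	11.7	154
chr3	1855994	1856257	JunB_peak_0055	0	.	0	3.603	3.603	131
chr1	1616891	1617329	JunB_peak_0056	0	.	0	6.077	6.077	219
chr3	1125668	1126071	JunB_peak_0057	0	.	0	12.5	12.5	201
chr1	2932582	2933079	JunB_peak_0058	0	.	0	13.292	13.292	248
chr3	2542755	2543066	JunB_peak_0059	0	.	0	2.666	2.666	155
chr2	2174351	2174767	JunB_peak_0060	0	.	0	4.305	4.305	208
chr2	2107486	2107766	JunB_peak_0061	0	.	0	3.489	3.489	140
chr3	2800654	2801062	JunB_peak_0062	0	.	0	15.966	15.966	204
chr2	2002725	2003083	JunB_peak_0063	0	.	0	9.266	9.266	179
chr2	690505	691002	JunB_peak_0064	0	.	0	7.445	7.445	248
chr1	939042	939253	JunB_peak_0065	0	.	0	5.421	5.421	105
chr3	2520626	2520967	JunB_peak_0066	0	.	0	3.62	3.62	170
chr1	2848197	2848567	JunB_peak_0067	0	.	0	9.658	9.658	185
chr2	2002397	2002854	JunB_peak_0068	0	.	0	20.698	20.698	228
chr2	1119218	1119530	JunB_peak_0069	0	.	0	16.87	16.87	156
chr3	2234301	2234574	JunB_peak_0070	0	.	0	20.663	20.663	136
chr3	2419217	2419691	JunB_peak_0071	0	.	0	7.319	7.319	237
chr2	2905085	2905405	JunB_peak_0072	0	.	0	8.765	8.765	160
chr2	1681358	1681779	JunB_peak_0073	0	.	0	22.857	22.857	210
chr1	2856296	2856758	JunB_peak_0074	0	.	0	7.606	7.606	231
chr2	577990	578192	JunB_peak_0075	0	.	0	5.069	5.069	101
chr2	2216765	2217155	JunB_peak_0076	0	.	0	8.696	8.696	195
chr1	1436261	1436488	JunB_peak_0077	0	.	0	7.536	7.536	113
chr2	1170391	1170788	JunB_peak_0078	0	.	0	9.764	9.764	198
chr2	1812098	1812451	JunB_peak_0079	0	.	0	8.671	8.671	176
chr1	2543158	2543386	JunB_peak_0080	0	.	0	7.033	7.033	114
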