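position	wt_aa	mut_aa	ddG_fold	ddG_bind_HM	ddG_bind_HET
1	H	A	1.577898	3.006426	0.535563
1	H	C	-1.563221	-0.456326	-0.369176
1	H	D	0.259392	-2.164971	-1.551223
1	H	E	5.578446	1.530961	0.661306
1	H	F	6.721684	4.085738	1.852214
1	H	G	6.70781	-0.417018	-0.143487
1	H	I	6.637685	0.416455	-0.142611
1	H	K	2.765852	1.548062	-0.214949
1	H	L	5.231031	4.716346	1.931699
1	H	M	2.404435	-2.131043	-1.028855
1	H	N	7.238746	2.050999	0.23795
1	H	P	4.06347	0.250576	-0.136983
1	H	Q	-0.984599	-1.441409	-1.336791
1	H	R	-1.472146	0.176907	0.215607
1	H	S	7.652435	-0.758841	-0.8965
1	H	T	6.774582	1.569184	1.788067
1	H	V	10.244801	-0.540014	-0.704516
1	H	W	0.612667	3.915506	1.891637
1	H	Y	6.187546	1.221697	0.73533
2	T	A	-3.559468	1.254391	-0.016909
2	T	C	3.690402	-0.312095	-1.208069
2	T	D	-3.88923	3.053927	1.436623
2	T	E	11.756807	5.253782	1.498799
2	T	F	7.379334	0.679188	0.239447
2	T	G	1.873078	-1.072546	-0.697623
2	T	H	0.294303	-1.965722	-1.640625
2	T	I	6.756939	-0.079945	1.055473
2	T	K	5.216436	-0.116727	-1.070605
2	T	L	6.83912	-1.31454	0.357949
2	T	M	9.66603	2.541834	1.038343
2	T	N	4.952508	4.829999	1.622745
2	T	P	6.430436	3.38531	1.917428
2	T	Q	-0.650978	2.731101	1.069995
2	T	R	2.859523	-3.309237	-2.683695
2	T	S	-1.32601	-0.258831	-0.44919
2	T	V	5.967859	2.727997	0.728164
2	T	W	11.294481	0.355777	-0.969753
2	T	Y	3.705734	-2.826686	-1.78206
3	Y	A	5.883815	3.994593	1.661057
3	Y	C	4.566393	-0.633684	-0.373083
3	Y	D	8.299071	3.359299	0.892518
3	Y	E	-8.02199	-0.318833	-0.451233
3	Y	F	4.293077	2.887753	-0.126058
3	Y	G	6.095918	2.441304	1.172136
3	Y	H	3.877619	-0.63201	-0.012955
3	Y	I	-4.502125	-2.757089	-2.606524
3	Y	K	-6.101573	-2.270787	-0.334869
3	Y	L	2.840629	0.288155	-0.071482
3	Y	M	-6.456053	-1.905257	-1.433447
3	Y	N	7.116619	1.402426	2.340858
3	Y	P	3.612352	2.282737	1.597211
3	Y	Q	6.154188	-3.413225	-1.866967
3	Y	R	10.157442	5.52043	2.402431
3	Y	S	9.584833	3.734827	2.175353
3	Y	T	-2.416698	-1.233288	-0.292884
3	Y	V	4.431855	1.19327	0.982181
3	Y	W	-0.303629	-6.261354	-2.811348
4	Q	A	3.658406	-2.820947	-1.934226
4	Q	C	6.193626	1.857417	0.816585
4	Q	D	6.744957	-0.981641	-0.562469
4	Q	E	-4.173621	-3.10122	-2.447616
4	Q	F	2.124694	-0.326783	-0.345043
4	Q	G	8.601793	3.510144	1.33235
4	Q	H	6.396583	-3.752804	-1.467469
4	Q	I	-4.160752	-1.803679	-1.088496
4	Q	K	3.311444	2.821145	0.407929
4	Q	L	-3.062702	-0.81177	-0.484388
4	Q	M	6.603071	1.15379	0.685803
4	Q	N	2.900279	1.787696	1.21379
4	Q	P	10.063457	-0.42121	-0.293421
4	Q	R	7.621928	0.820658	1.064848
4	Q	S	7.452159	0.507083	-0.226763
4	Q	T	-4.072492	-0.917513	-0.691638
4	Q	V	-0.984775	-2.980851	-2.023517
4	Q	W	-1.661669	-3.481837	-1.480227
4	Q	Y	4.621676	-0.239413	-0.606116
5	K	A	10.731126	-3.140536	-0.426536
5	K	C	1.153994	0.305482	-0.723828
5	K	D	-0.020272	0.23965	-1.039241
5	K	E	8.10993	-1.86384	-1.533523
5	K	F	7.715716	3.319429	1.174429
5	K	G	2.154682	-1.756353	-0.751286
5	K	H	12.388031	-0.147495	0.076836
5	K	I	-4.087549	-3.950785	-1.946356
5	K	L	4.262332	-1.608876	0.067165
5	K	M	0.711166	1.984464	0.479668
5	K	N	3.133049	-0.880711	-0.38835
5	K	P	0.269702	0.246122	-0.522824
5	K	Q	-3.74311	-0.148293	-0.521665
5	K	R	2.370357	-1.464041	-2.405426
5	K	S	-4.751569	-3.818207	-2.676868
5	K	T	1.214107	3.467362	1.435942
5	K	V	-8.848579	-2.148102	-1.439223
5	K	W	-2.191046	-1.627637	-0.232527
5	K	Y	1.462834	0.076893	-0.158401
6	G	A	1.734301	0.952349	1.122355
6	G	C	8.098845	4.595628	1.358207
6	G	D	-6.130569	1.659574	1.105751
6	G	E	3.693921	0.503608	0.589188
6	G	F	4.054398	-2.064326	-0.634255
6	G	H	1.060776	-2.468667	-1.289681
6	G	I	2.925104	3.840411	1.877157
6	G	K	-7.889878	-2.169948	-0.968268
6	G	L	-1.57126	-0.887824	-0.561752
6	G	M	5.454128	1.740109	0.419765
6	G	N	5.620618	1.303644	0.510936
6	G	P	-0.107826	0.959326	0.610832
6	G	Q	-6.818107	-2.22991	-0.325085
6	G	R	4.502521	0.557653	0.675589
6	G	S	-0.3238	3.789319	0.970237
6	G	T	-0.758629	0.477892	-0.550814
6	G	V	7.306664	1.619279	0.084379
6	G	W	-3.808192	1.498793	0.399963
6	G	Y	3.856121	-1.36884	-0.186823
7	G	A	3.614625	0.486721	-0.303619
7	G	C	6.027762	1.156569	0.67983
7	G	D	4.596327	2.275997	1.324551
7	G	E	6.125985	2.011307	1.055478
7	G	F	4.692549	-3.386031	-1.489704
7	G	H	-5.178102	0.961372	0.77599
7	G	I	0.497842	-1.420343	-0.198512
7	G	K	0.598043	-6.948513	-3.013584
7	G	L	-2.613094	0.552315	0.468757
7	G	M	11.08008	2.708241	0.313219
7	G	N	9.469814	-2.549789	-1.108914
7	G	P	1.050774	-1.714954	-0.407737
7	G	Q	3.502485	4.408452	1.370239
7	G	R	11.932146	0.133078	-0.037541
7	G	S	2.683426	-1.275804	-0.384913
7	G	T	-0.981898	1.134674	-0.206445
7	G	V	-6.978995	-2.060821	-1.872993
7	G	W	-0.879909	-0.741787	-1.343772
7	G	Y	8.764507	2.223033	0.686888
8	P	A	3.426289	2.880241	1.089398
8	P	C	4.828518	2.009368	1.267296
8	P	D	2.621107	-0.522234	0.297506
8	P	E	0.38528	-2.438127	-0.9395
8	P	F	-0.096236	-4.052104	-1.999401
8	P	G	1.956344	2.673124	1.304777
8	P	H	9.198621	2.115805	1.072686
8	P	I	2.333508	-1.042064	-0.465278
8	P	K	-0.012264	-3.147157	-1.45241
8	P	L	6.173905	-1.753355	-0.323767
8	P	M	-5.664669	-7.01047	-2.657673
8	P	N	6.501005	0.35581	0.395966
8	P	Q	-1.638377	-3.477071	-1.49875
8	P	R	3.068241	3.009484	1.45995
8	P	S	3.918676	-0.05469	-0.903768
8	P	T	5.741926	2.218313	1.048615
8	P	V	10.300404	4.633416	2.544099
8	P	W	-4.545281	-3.57282	-1.593256
8	P	Y	6.958097	-0.947507	0.036507
9	N	A	5.957169	-2.813798	-2.180347
9	N	C	2.089129	-0.869112	-0.443405
9	N	D	-2.024959	0.991687	0.220355
9	N	E	-3.53091	-1.778632	-0.078943
9	N	F	2.376961	-1.662129	-0.681542
9	N	G	10.485065	0.768534	0.067397
9	N	H	2.944026	-1.169595	-1.098362
9	N	I	-2.948607	-3.373292	-1.076617
9	N	K	4.54454	1.212054	1.541167
9	N	L	-1.605629	-0.538061	0.476356
9	N	M	6.214199	-2.479497	-1.754092
9	N	P	4.14305	-0.34085	-0.365253
9	N	Q	4.221191	0.902324	-0.442879
9	N	R	-1.255334	-0.748161	-0.580932
9	N	S	12.967536	2.346963	1.046915
9	N	T	2.484378	1.989042	1.772429
9	N	V	5.423138	3.89708	0.946061
9	N	W	-2.960206	1.429067	-0.101765
9	N	Y	0.32626	-2.386942	-1.202807
10	C	A	3.622805	0.8949	0.472922
10	C	D	9.30972	1.486039	-0.164243
10	C	E	5.248172	2.979946	0.906393
10	C	F	1.238579	2.019504	0.828744
10	C	G	4.496809	-0.598067	-0.426039
10	C	H	-0.455666	2.178033	0.53189
10	C	I	6.400608	5.293694	2.645259
10	C	K	7.187234	-2.346685	-1.178608
10	C	L	4.785133	1.738377	-0.010873
10	C	M	-0.918577	1.692243	1.424796
10	C	N	2.061365	3.495311	2.472835
10	C	P	1.833753	-0.55959	-1.093943
10	C	Q	0.100591	0.43865	-0.156226
10	C	R	4.193335	-1.560204	-1.076764
10	C	S	-3.011304	-3.31211	-2.013761
10	C	T	0.900019	1.371195	0.204974
10	C	V	1.960545	1.233872	0.869416
10	C	W	5.322115	4.649744	1.705632
10	C	Y	4.702234	-3.302487	-2.02717
11	R	A	2.277688	-0.098644	-0.354762
11	R	C	11.609331	3.389559	0.97736
11	R	D	1.607825	2.882717	1.107439
11	R	E	-10.123469	-3.349905	-1.93665
11	R	F	7.889245	1.436276	0.793993
11	R	G	-0.955361	3.390292	0.808894
11	R	H	0.399896	-1.804807	-0.444514
11	R	I	0.831908	2.893443	1.348232
11	R	K	-1.415054	-2.037467	-1.234641
11	R	L	-0.12375	-2.555772	-1.192409
11	R	M	3.500551	-0.040466	-0.744333
11	R	N	1.295337	-2.641692	-1.492941
11	R	P	-2.135165	2.425108	0.473112
11	R	Q	-0.439477	-0.896386	-1.287614
11	R	S	2.388609	2.712648	0.789503
11	R	T	7.725527	0.9226	-0.227723
11	R	V	-4.27387	-5.369947	-1.893354
11	R	W	-1.302437	3.26005	1.706849
11	R	Y	7.934789	3.712897	1.944995
12	T	A	-0.251451	1.180786	-0.487978
12	T	C	6.776316	0.422762	0.30716
12	T	D	-11.746295	-0.124804	-0.030219
12	T	E	2.314813	1.323984	0.206603
12	T	F	0.678859	-0.367883	-0.422053
12	T	G	3.060602	1.420328	0.548282
12	T	H	8.343743	1.15371	-0.656693
12	T	I	8.606448	-0.197262	0.343578
12	T	K	-4.847203	1.187156	-0.933595
12	T	L	3.465819	-4.561541	-2.078988
12	T	M	5.170239	2.112915	0.380425
12	T	N	-0.988448	-1.820926	-1.421699
12	T	P	1.690838	-1.246792	-0.718318
12	T	Q	3.512782	1.823113	-0.036791
12	T	R	-3.84632	1.52113	-0.151365
12	T	S	0.364473	-1.748414	-1.38833
12	T	V	-2.223149	1.112026	-0.451038
12	T	W	4.641085	-0.740519	-1.028361
12	T	Y	-0.267096	-2.036568	-0.444364
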