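no	annotation	logFC	AvgExpr	AvgHy3	p_value	adj_p_value
1	hsa-miR-320c	1.200823	0.234397	8.424051	6.39E-07	0.00026
2	hsa-miR-30b	1.615031	0.310867	8.365077	3.12E-06	0.0013
3	hsa-miR-320e	1.206532	0.222737	8.432005	5.03E-06	0.0021
4	hsa-miR-320a	1.182796	0.204731	8.699699	5.64E-06	0.0023
5	hsa-miR-320b	1.248647	0.139694	8.734353	8.83E-06	0.0037
6	hsa-miR-29c	2.620266	0.310883	8.044084	1.32E-05	0.0055
7	hsa-miR-10b	1.383596	0.156777	8.122331	1.37E-05	0.0057
8	hsa-miR-19a	0.646275	0.285073	8.533174	1.47E-05	0.0061
9	hsa-miR-101	2.644133	-0.05242	8.501706	1.63E-05	0.0068
10	hsa-miR-320d	1.178505	0.28873	8.23224	1.71E-05	0.0072
11	hsa-miR-148b	0.803186	0.294123	6.764786	2.19E-05	0.0092
12	hsa-miR-29a	1.228473	0.347	12.13131	2.29E-05	0.0096
13	hsa-miR-193b	1.192514	0.18976	8.324068	2.44E-05	0.010
14	hsa-miR-151-5p	0.701698	0.079185	7.519235	2.51E-05	0.010
15	hsa-miR-129*	1.434831	0.064513	6.293654	3.11E-05	0.013
16	hsa-miR-193b*	0.392681	0.04686	5.884442	3.59E-05	0.015
17	hsa-miR-30c	1.44055	0.202695	8.307646	3.74E-05	0.015
18	hsa-miR-374b	1.202467	0.155924	7.191527	3.76E-05	0.015
19	hsa-miR-365	1.24017	0.331153	8.881532	4.11E-05	0.017
20	hsa-miR-103a	0.989911	0.22999	8.47661	4.64E-05	0.019
21	hsa-miR-3647-5p	0.715019	-0.17482	6.152502	4.66E-05	0.019
22	hsa-miR-30e	1.047744	0.480218	7.490472	5.47E-05	0.023
23	hsa-miR-3647-3p	0.872259	0.087001	8.168902	5.85E-05	0.024
24	hsa-miR-190	1.532023	0.435949	6.418949	5.96E-05	0.025
25	hsa-miR-222	-1.15414	-0.14702	10.71594	6.03E-05	0.025
26	hsa-miR-152	0.717162	0.380272	7.531555	6.32E-05	0.026
27	hsa-miR-374a	1.285674	0.256238	7.48288	6.46E-05	0.027
28	hsa-miR-26b	1.519303	0.156895	8.870564	6.49E-05	0.027
29	hsa-miR-28-5p	0.686888	0.012992	5.912515	6.82E-05	0.028
30	hsa-miR-186	1.166416	0.40042	6.430794	7.04E-05	0.029
31	hsa-miR-191	1.222257	0.357161	7.655313	7.42E-05	0.031
32	hsa-miR-26a	1.611705	0.16245	7.403967	7.54E-05	0.031
33	hsa-miR-30a	1.400624	0.282938	7.650121	8.02E-05	0.033
34	hsa-miR-16	0.831693	0.543501	10.61485	8.99E-05	0.037
35	hsa-miR-15a	0.969761	0.440476	9.501428	9.15E-05	0.038
36	hsa-miR-1285	-1.24066	-0.31694	7.180472	9.24E-05	0.038
37	hsa-miR-151-3p	0.491623	0.195363	6.432898	9.56E-05	0.040
38	hsa-miR-30d	1.343111	0.511484	7.202426	0.000103	0.043
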