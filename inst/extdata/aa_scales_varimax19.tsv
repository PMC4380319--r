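aa	V1	V2	V3	V4	V5	V6	V7	V8	V9	V10	V11	V12	V13	V14	V15	V16	V17	V18	V19
A	-0.273603	-1.498785	0.93481	0.420646	-0.46096	-0.197463	-1.649165	0.599331	-0.886683	0.506619	0.967269	-0.089325	0.040927	-1.117079	1.030467	1.741905	-1.786259	-0.432249	0.798686
C	-1.175261	0.647034	-1.76301	-1.273395	-0.146874	-1.01003	-1.398905	-1.580794	1.007831	0.354363	1.521869	-0.319817	0.527129	0.652553	-0.844386	0.429718	-0.511678	0.651325	-0.419227
D	1.048596	0.283161	0.027437	-0.38798	2.23875	0.022227	-0.279584	0.520541	-0.005512	-0.14356	0.530508	2.618048	-0.744012	-0.055394	-0.189006	0.547307	-0.208162	-0.437793	-1.753346
E	1.314318	-1.509949	0.28049	0.249148	2.566603	0.070123	-0.012188	-0.813293	0.529066	0.362726	0.089381	-1.892852	-0.346922	0.605033	-0.523694	-0.163399	0.446223	0.428386	1.214722
F	-1.342196	-0.28353	-0.090236	0.400181	0.060398	0.705492	1.076824	0.296102	-0.379048	0.102412	0.131716	1.619599	0.971043	0.465186	-2.106638	0.757554	0.589945	-0.534376	2.156825
G	-0.098814	1.494318	0.842641	-0.348275	-0.143783	3.310427	-1.3541	-1.168021	-0.278401	0.223461	-0.676528	-0.306072	-0.240918	0.125983	0.167019	-0.002178	0.054554	-0.11669	-0.035072
H	0.191186	-0.415923	-1.535041	0.017438	-0.730597	0.215768	-0.119158	0.625706	-1.712279	-0.363306	0.179517	-1.150886	-1.804822	-1.394592	-1.76118	-0.326483	0.736353	-0.680864	-0.812838
I	-1.352147	-0.164902	0.474093	-0.025306	0.13843	-0.538945	0.116477	0.86896	-0.275474	-0.082732	-1.435604	-0.632994	-0.819358	2.480638	-0.28504	-0.742591	-1.830226	-1.022826	-0.7021
K	1.754011	-0.617008	0.572727	-0.220889	-1.949676	0.055713	0.884286	-0.85892	0.720732	-1.964758	0.054048	0.414407	-0.86633	0.981189	-0.421833	1.116825	-0.505488	0.971315	0.006212
L	-1.189733	-0.816767	2.307563	-0.011762	-0.23345	0.00438	0.745946	-0.579954	0.051776	-0.357278	1.832238	-0.048069	0.452501	-0.674817	-0.244343	-1.943457	0.448033	0.239494	-1.204349
M	-0.837773	-1.716933	-1.599097	1.063382	-0.39522	0.907832	-0.583981	0.419515	1.932322	-0.148797	-0.776191	1.016104	-0.58887	-0.406419	1.184617	-1.207539	0.379288	0.546029	0.092916
N	0.882613	0.843847	-0.263876	-0.68781	-0.209439	0.781255	0.004047	3.149292	0.758873	-0.253025	1.121972	-0.979332	1.360952	0.430219	0.050711	-0.276158	0.006783	0.681669	0.07255
P	0.217734	1.869854	-0.092092	3.648043	0.061563	-0.743986	-0.06263	-0.293327	0.075157	-0.202416	0.488672	-0.338941	0.152247	0.08759	0.021101	0.150325	-0.08361	0.158172	-0.23678
Q	1.13773	-0.77635	-0.821095	-0.042115	-0.233186	-0.223648	-0.262869	-0.890952	-0.904803	-0.888539	-0.940213	-0.000401	2.865407	0.027885	0.471554	-0.557339	0.160561	-1.667313	-0.683656
R	1.186635	-0.149383	0.138247	-0.036631	-1.244909	-0.203046	1.016096	-0.213735	0.344702	3.614096	-0.442754	0.283711	0.094088	0.041962	-0.245527	-0.06613	-0.047794	0.041527	-0.627423
S	0.466952	0.887309	0.579022	-0.750513	-0.634842	-1.375905	-0.960159	0.105559	0.09627	-0.004959	0.463363	0.472933	-1.163135	0.640393	1.193134	-0.792256	1.859113	-1.604705	1.619769
T	0.289359	0.691958	0.242074	-0.556305	0.215759	-1.088636	-0.606546	0.0362	-1.353063	-0.16681	-1.453916	0.776566	0.229553	-0.933226	-0.273188	-1.469058	-0.793872	2.463754	1.042249
V	-1.134886	-0.015839	1.022094	-0.293271	0.153951	-0.884831	-0.308354	0.496531	0.621781	-0.189732	-1.811193	-0.666851	0.41455	-0.539637	-0.019124	2.016878	2.019205	0.657261	-1.137857
W	-0.806866	0.082101	-1.091813	-0.352601	0.432876	0.396239	1.940919	-0.359491	-1.849205	0.081406	0.681815	-0.191277	-0.266235	0.752609	2.381077	0.679439	0.489527	0.946718	-0.055074
Y	-0.277856	1.165788	-0.164937	-0.811986	0.514604	-0.202967	1.813045	-0.359249	1.505958	-0.47917	-0.525967	-0.58455	-0.267794	-2.170075	0.414279	0.106636	-1.422495	-1.288837	0.663792
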