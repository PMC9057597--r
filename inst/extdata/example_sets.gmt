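SYNTH_PATHWAY_A	synthetic	gene_00432	gene_00289	gene_00300	gene_00022	gene_00246	gene_00373	gene_00483	gene_00362	gene_00446	gene_00226	gene_00128	gene_00358	gene_00416	gene_00269	gene_00020	gene_00484	gene_00415	gene_00068	gene_00265	gene_00210	gene_00088	gene_00158	gene_00086	gene_00340	gene_00488	gene_00398	gene_00132	gene_00078	gene_00353	gene_00007	gene_00481	gene_00199	gene_00422	gene_00094	gene_00476	gene_00229	gene_00232	gene_00343	gene_00058	gene_00310
SYNTH_PATHWAY_B	synthetic	gene_00373	gene_00046	gene_00044	gene_00496	gene_00186	gene_00383	gene_00321	gene_00142	gene_00060	gene_00415	gene_00438	gene_00191	gene_00166	gene_00231	gene_00207	gene_00160	gene_00341	gene_00367	gene_00071	gene_00401	gene_00123	gene_00285	gene_00301	gene_00268	gene_00201	gene_00355	gene_00104	gene_00308	gene_00243	gene_00294	gene_00315	gene_00040	gene_00103	gene_00419	gene_00395	gene_00422	gene_00306	gene_00068	gene_00483	gene_00271
SYNTH_PATHWAY_C	synthetic	gene_00375	gene_00285	gene_00095	gene_00459	gene_00434	gene_00439	gene_00362	gene_00188	gene_00387	gene_00091	gene_00058	gene_00106	gene_00181	gene_00312	gene_00469	gene_00284	gene_00288	gene_00015	gene_00100	gene_00273	gene_00456	gene_00099	gene_00039	gene_00185	gene_00179	gene_00307	gene_00248	gene_00101	gene_00389	gene_00068	gene_00030	gene_00003	gene_00368	gene_00317	gene_00093	gene_00011	gene_00272	gene_00443	gene_00186	gene_00043
SYNTH_PATHWAY_D	synthetic	gene_00311	gene_00440	gene_00200	gene_00243	gene_00411	gene_00401	gene_00147	gene_00391	gene_00468	gene_00050	gene_00134	gene_00207	gene_00358	gene_00202	gene_00481	gene_00394	gene_00125	gene_00306	gene_00081	gene_00209	gene_00102	gene_00404	gene_00317	gene_00438	gene_00192	gene_00274	gene_00352	gene_00132	gene_00036	gene_00256	gene_00445	gene_00441	gene_00273	gene_00114	gene_00103	gene_00155	gene_00090	gene_00312	gene_00413	gene_00047
SYNTH_PATHWAY_E	synthetic	gene_00293	gene_00346	gene_00111	gene_00081	gene_00283	gene_00172	gene_00185	gene_00166	gene_00075	gene_00399	gene_00069	gene_00210	gene_00473	gene_00251	gene_00009	gene_00278	gene_00437	gene_00114	gene_00420	gene_00432	gene_00180	gene_00123	gene_00306	gene_00323	gene_00428	gene_00127	gene_00405	gene_00042	gene_00074	gene_00139	gene_00230	gene_00435	gene_00207	gene_00217	gene_00423	gene_00482	gene_00234	gene_00340	gene_00265	gene_00151
SYNTH_PATHWAY_F	synthetic	gene_00424	gene_00106	gene_00175	gene_00361	gene_00128	gene_00274	gene_00148	gene_00214	gene_00317	gene_00311	gene_00498	gene_00090	gene_00157	gene_00330	gene_00089	gene_00206	gene_00441	gene_00109	gene_00325	gene_00029	gene_00245	gene_00161	gene_00201	gene_00350	gene_00360	gene_00167	gene_00168	gene_00335	gene_00267	gene_00470	gene_00442	gene_00048	gene_00094	gene_00084	gene_00312	gene_00246	gene_00454	gene_00338	gene_00031	gene_00098
SYNTH_PATHWAY_G	synthetic	gene_00039	gene_00447	gene_00334	gene_00242	gene_00344	gene_00335	gene_00376	gene_00157	gene_00316	gene_00013	gene_00047	gene_00419	gene_00352	gene_00109	gene_00270	gene_00052	gene_00300	gene_00087	gene_00238	gene_00324	gene_00088	gene_00102	gene_00333	gene_00142	gene_00038	gene_00065	gene_00147	gene_00269	gene_00138	gene_00114	gene_00190	gene_00056	gene_00494	gene_00178	gene_00234	gene_00370	gene_00048	gene_00414	gene_00044	gene_00078
SYNTH_PATHWAY_H	synthetic	gene_00148	gene_00115	gene_00117	gene_00304	gene_00442	gene_00370	gene_00081	gene_00447	gene_00298	gene_00008	gene_00185	gene_00481	gene_00175	gene_00173	gene_00056	gene_00396	gene_00167	gene_00422	gene_00398	gene_00341	gene_00142	gene_00439	gene_00095	gene_00053	gene_00138	gene_00390	gene_00251	gene_00421	gene_00211	gene_00158	gene_00201	gene_00154	gene_00338	gene_00104	gene_00009	gene_00044	gene_00193	gene_00224	gene_00403	gene_00299
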