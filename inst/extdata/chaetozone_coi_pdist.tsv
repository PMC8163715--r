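# Published mean COI p-distances among Norwegian Chaetozone species
# (within-species means on the diagonal, between-species means off it;
# values as printed in the source table, sp numbers are the molecular
# species-delimitation lineage codes).
species	monteverdii_sp1	sp2	barentsensis_sp3	sp4	quinta_sp5	pseudosetosa_sp7	setosa_sp8	sp9	zetlandica_sp10	sp11	chambersae_sp12	sp13	sp14
monteverdii_sp1	0.0019	0.2372	0.2470	0.2677	0.2532	0.2572	0.2452	0.2400	0.2350	0.2268	0.2194	0.2343	0.2557
sp2	0.2372	0.0048	0.2627	0.2674	0.2840	0.2718	0.2625	0.2667	0.2669	0.2466	0.2447	0.2444	0.2737
barentsensis_sp3	0.2470	0.2627	0	0.2356	0.2364	0.2490	0.2328	0.2559	0.2508	0.2459	0.2389	0.1587	0.0953
sp4	0.2677	0.2674	0.2356	0.0015	0.0950	0.2705	0.2594	0.2472	0.2405	0.2457	0.2410	0.2496	0.2353
quinta_sp5	0.2532	0.2840	0.2364	0.0950	0	0.2553	0.2620	0.2458	0.2314	0.2568	0.2585	0.2508	0.2379
pseudosetosa_sp7	0.2572	0.2718	0.2490	0.2705	0.2553	0.011	0.0889	0.2090	0.2079	0.1737	0.1889	0.2299	0.2556
setosa_sp8	0.2452	0.2625	0.2328	0.2594	0.2620	0.0889	0.004	0.2045	0.2041	0.1701	0.1949	0.2214	0.2369
sp9	0.2400	0.2667	0.2559	0.2472	0.2458	0.2090	0.2045	0.0033	0.1069	0.1931	0.1988	0.2486	0.2553
zetlandica_sp10	0.2350	0.2669	0.2508	0.2405	0.2314	0.2079	0.2041	0.1069	0.0014	0.1994	0.1994	0.2492	0.2581
sp11	0.2268	0.2466	0.2459	0.2457	0.2568	0.1737	0.1701	0.1931	0.1994	0.0061	0.1088	0.2219	0.2594
chambersae_sp12	0.2194	0.2447	0.2389	0.2410	0.2585	0.1889	0.1949	0.1988	0.1994	0.1088	0.0053	0.2225	0.2463
sp13	0.2343	0.2444	0.1587	0.2496	0.2508	0.2299	0.2214	0.2486	0.2492	0.2219	0.2225	0.0008	0.1694
sp14	0.2557	0.2737	0.0953	0.2353	0.2379	0.2556	0.2369	0.2553	0.2581	0.2594	0.2463	0.1694	0.0102
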