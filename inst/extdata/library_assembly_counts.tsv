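# per-assembly read/contig/singleton counts for the blueberry 454 EST libraries
sample	n_reads_assembled	n_reads_in_contigs	n_contigs	n_singletons	mean_contig_length	mean_singleton_length
bud_0	69943	43073	2675	26870	804	323
bud_397	74169	39999	2751	34170	760	306
bud_789	69874	37681	2645	32193	785	319
bud_1333	72733	41836	2421	30897	796	302
all_bud	291342	228938	10350	62404	898	280
fruit_green	73168	46708	2241	26460	720	284
fruit_white	69260	42682	2029	26578	700	298
fruit_pink	68767	43975	1964	24792	750	297
fruit_blue	59622	37615	1941	22007	819	311
all_fruit	259527	199643	6726	59884	818	267
leaf	62465	36763	1781	25702	771	298
all	614028	490517	14764	123511	933	253
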