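# amplification/polymorphism screen of 100 EST-SSR primer pairs on
# parents/progeny of a tetraploid and a diploid blueberry mapping population;
# entries are product sizes (bp), - means no product
primer_id	t_draper	t_jewel	t_bb05611	t_bb05612	d_hyb10	d_w8523	d_fla4b	d_w8520	call	polymorphic_in
VCB-S-001	-	-	-	-	-	-	-	-	no_product	
VCB-S-002	-	-	-	-	-	-	-	-	no_product	
VCB-S-003	-	-	-	-	-	-	-	-	no_product	
VCB-S-004	-	-	-	-	-	-	-	-	no_product	
VCB-S-005	-	-	-	-	-	-	-	-	no_product	
VCB-S-006	-	-	-	-	-	-	-	-	no_product	
VCB-S-007	-	-	-	-	-	-	-	-	no_product	
VCB-S-008	-	-	-	-	-	-	-	-	no_product	
VCB-S-009	-	-	-	-	-	-	-	-	no_product	
VCB-S-010	-	-	-	-	-	-	-	-	no_product	
VCB-S-011	-	-	-	-	-	-	-	-	no_product	
VCB-S-012	-	-	-	-	-	-	-	-	no_product	
VCB-S-013	-	-	-	-	-	-	-	-	no_product	
VCB-S-014	-	-	-	-	-	-	-	-	no_product	
VCB-S-015	-	-	-	-	-	-	-	-	no_product	
VCB-S-016	-	-	-	-	-	-	-	-	no_product	
VCB-S-017	-	-	-	-	-	-	-	-	no_product	
VCB-S-018	-	-	-	-	-	-	-	-	no_product	
VCB-S-019	-	-	-	-	-	-	-	-	no_product	
VCB-S-020	-	-	-	-	-	-	-	-	no_product	
VCB-S-021	-	-	-	-	-	-	-	-	no_product	
VCB-S-022	-	-	-	-	-	-	-	-	no_product	
VCB-S-023	-	-	-	-	-	-	-	-	no_product	
VCB-S-024	-	-	-	-	-	-	-	-	no_product	
VCB-S-025	-	-	-	-	-	-	-	-	no_product	
VCB-S-026	-	-	-	-	-	-	-	-	no_product	
VCB-S-027	-	-	-	-	-	-	-	-	no_product	
VCB-S-028	-	-	-	-	-	-	-	-	no_product	
VCB-S-029	-	-	-	-	-	-	-	-	no_product	
VCB-S-030	-	-	-	-	-	-	-	-	no_product	
VCB-S-031	-	-	-	-	-	-	-	-	no_product	
VCB-S-032	-	-	-	-	-	-	-	-	no_product	
VCB-S-033	178	182	178	182	-	-	-	-	polymorphic	tetraploid
VCB-S-034	180	186	180	180	180	180	180	180	polymorphic	tetraploid
VCB-S-035	180	186	180	180	180	180	180	180	polymorphic	tetraploid
VCB-S-036	180	186	180	180	180	180	180	180	polymorphic	tetraploid
VCB-S-037	180	186	180	180	180	180	180	180	polymorphic	tetraploid
VCB-S-038	180	186	180	180	180	180	180	180	polymorphic	tetraploid
VCB-S-039	180	180	180	180	180	180	174	180	polymorphic	diploid
VCB-S-040	180	180	180	180	180	180	174	180	polymorphic	diploid
VCB-S-041	180	180	180	180	180	180	174	180	polymorphic	diploid
VCB-S-042	180	180	180	180	180	180	174	180	polymorphic	diploid
VCB-S-043	180	180	180	180	180	180	174	180	polymorphic	diploid
VCB-S-044	180	180	180	180	180	180	174	180	polymorphic	diploid
VCB-S-045	180	180	180	180	180	180	174	180	polymorphic	diploid
VCB-S-046	180	180	180	180	180	180	174	180	polymorphic	diploid
VCB-S-047	180	180	180	180	180	180	174	180	polymorphic	diploid
VCB-S-048	180	180	180	180	180	180	174	180	polymorphic	diploid
VCB-S-049	180	180	180	180	180	180	174	180	polymorphic	diploid
VCB-S-050	180	188	180	180	180	180	180	176	polymorphic	tetraploid,diploid
VCB-S-051	180	188	180	180	180	180	180	176	polymorphic	tetraploid,diploid
VCB-S-052	180	188	180	180	180	180	180	176	polymorphic	tetraploid,diploid
VCB-S-053	180	188	180	180	180	180	180	176	polymorphic	tetraploid,diploid
VCB-S-054	180	188	180	180	180	180	180	176	polymorphic	tetraploid,diploid
VCB-S-055	180	188	180	180	180	180	180	176	polymorphic	tetraploid,diploid
VCB-S-056	180	188	180	180	180	180	180	176	polymorphic	tetraploid,diploid
VCB-S-057	180	188	180	180	180	180	180	176	polymorphic	tetraploid,diploid
VCB-S-058	180	188	180	180	180	180	180	176	polymorphic	tetraploid,diploid
VCB-S-059	180	188	180	180	180	180	180	176	polymorphic	tetraploid,diploid
VCB-S-060	180	188	180	180	180	180	180	176	polymorphic	tetraploid,diploid
VCB-S-061	180	188	180	180	180	180	180	176	polymorphic	tetraploid,diploid
VCB-S-062	180	188	180	180	180	180	180	176	polymorphic	tetraploid,diploid
VCB-S-063	180	188	180	180	180	180	180	176	polymorphic	tetraploid,diploid
VCB-S-064	180	188	180	180	180	180	180	176	polymorphic	tetraploid,diploid
VCB-S-065	180	188	180	180	180	180	180	176	polymorphic	tetraploid,diploid
VCB-S-066	180	188	180	180	180	180	180	176	polymorphic	tetraploid,diploid
VCB-S-067	180	188	180	180	180	180	180	176	polymorphic	tetraploid,diploid
VCB-S-068	180	188	180	180	180	180	180	176	polymorphic	tetraploid,diploid
VCB-S-069	180	188	180	180	180	180	180	176	polymorphic	tetraploid,diploid
VCB-S-070	180	188	180	180	180	180	180	176	polymorphic	tetraploid,diploid
VCB-S-071	180	188	180	180	180	180	180	176	polymorphic	tetraploid,diploid
VCB-S-072	180	188	180	180	180	180	180	176	polymorphic	tetraploid,diploid
VCB-S-073	180	188	180	180	180	180	180	176	polymorphic	tetraploid,diploid
VCB-S-074	180	188	180	180	180	180	180	176	polymorphic	tetraploid,diploid
VCB-S-075	180	188	180	180	180	180	180	176	polymorphic	tetraploid,diploid
VCB-S-076	180	180	180	180	180	180	180	180	monomorphic	
VCB-S-077	180	180	180	180	180	180	180	180	monomorphic	
VCB-S-078	180	180	180	180	180	180	180	180	monomorphic	
VCB-S-079	180	180	180	180	180	180	180	180	monomorphic	
VCB-S-080	180	180	180	180	180	180	180	180	monomorphic	
VCB-S-081	180	180	180	180	180	180	180	180	monomorphic	
VCB-S-082	180	180	180	180	180	180	180	180	monomorphic	
VCB-S-083	180	180	180	180	180	180	180	180	monomorphic	
VCB-S-084	180	180	180	180	180	180	180	180	monomorphic	
VCB-S-085	180	180	180	180	180	180	180	180	monomorphic	
VCB-S-086	180	180	180	180	180	180	180	180	monomorphic	
VCB-S-087	180	180	180	180	180	180	180	180	monomorphic	
VCB-S-088	180	180	180	180	180	180	180	180	monomorphic	
VCB-S-089	180	180	180	180	180	180	180	180	monomorphic	
VCB-S-090	180	180	180	180	180	180	180	180	monomorphic	
VCB-S-091	180	180	180	180	180	180	180	180	monomorphic	
VCB-S-092	180	180	180	180	180	180	180	180	monomorphic	
VCB-S-093	180	180	180	180	180	180	180	180	monomorphic	
VCB-S-094	180	180	180	180	180	180	180	180	monomorphic	
VCB-S-095	180	180	180	180	180	180	180	180	monomorphic	
VCB-S-096	180	180	180	180	180	180	180	180	monomorphic	
VCB-S-097	180	180	180	180	180	180	180	180	monomorphic	
VCB-S-098	180	180	180	180	180	180	180	180	monomorphic	
VCB-S-099	180	180	180	180	180	180	180	180	monomorphic	
VCB-S-100	180	180	180	180	180	180	180	180	monomorphic	
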