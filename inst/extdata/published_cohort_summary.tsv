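cohort	sample_size	n_lncrna	cis_pair	cis_eqtl	cis_elncrna	trans_pair	trans_eqtl	trans_elncrna
ER-neg-BRCA	96	3434	2810	2765	553	789	754	490
ER-pos-BRCA	459	3530	24866	20379	2713	6408	1844	677
COAD	146	974	1487	1458	313	301	325	190
KIRC	251	3940	18055	15486	2613	4918	1465	725
LIHC	113	2522	3953	3877	817	1088	634	423
LUAD	249	3465	9453	8761	1672	1806	1114	605
OV	331	3698	13575	11976	2125	2965	1292	607
PRAD	283	3600	25906	21547	2779	6459	1606	671
STAD	42	3638	464	461	98	496	617	451
THCA	345	3564	35637	28085	2970	8380	2183	666
UCEC	234	1113	3074	2976	527	1001	292	203
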