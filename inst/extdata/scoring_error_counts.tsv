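locus	tissue_errors	scat_errors
Cfam_STR001	5	1
Cfam_STR002	0	0
Cfam_STR004	3	0
Cfam_STR007	1	0
Cfam_STR008	2	0
Cfam_STR009	15	7
Cfam_STR010	0	1
Cfam_STR011	0	0
Cfam_STR012	9	4
Cfam_STR013	1	0
Cfam_STR014	4	1
Cfam_STR015	0	1
Cfam_STR016	1	0
Cfam_STR017	1	0
Cfam_STR018	0	0
Cfam_STR019	16	1
Cfam_STR020	2	0
Cfam_STR021	1	0
Cfam_STR022	1	0
Cfam_STR026	0	0
Cfam_STR027	0	1
Cfam_STR029	0	1
Cfam_STR030	10	2
Cfam_STR031	4	0
Cfam_STR032	1	0
Cfam_STR033	14	1
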