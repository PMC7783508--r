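support	length_bp	genes	match_status	syndrome	expected_label	expected_rule
0	2e+05	none	none	no	likely_benign	LB
3	2e+05	none	none	no	benign	B-DGV50
0	4e+06	none	none	no	pathogenic	P-SIZE
3	4e+06	none	none	no	benign	B-DGV50
0	2e+05	non_omim	none	no	likely_benign	LB
3	2e+05	non_omim	none	no	benign	B-DGV50
0	4e+06	non_omim	none	no	pathogenic	P-SIZE
3	4e+06	non_omim	none	no	benign	B-DGV50
0	2e+05	omim	none	no	vus	V-2
3	2e+05	omim	none	no	benign	B-DGV50
0	4e+06	omim	none	no	pathogenic	P-SIZE
3	4e+06	omim	none	no	benign	B-DGV50
0	2e+05	none	uncertain	no	vus	V-FALLBACK
3	2e+05	none	uncertain	no	benign	B-DGV50
0	4e+06	none	uncertain	no	pathogenic	P-SIZE
3	4e+06	none	uncertain	no	benign	B-DGV50
0	2e+05	non_omim	uncertain	no	vus	V-1
3	2e+05	non_omim	uncertain	no	benign	B-DGV50
0	4e+06	non_omim	uncertain	no	pathogenic	P-SIZE
3	4e+06	non_omim	uncertain	no	benign	B-DGV50
0	2e+05	omim	uncertain	no	vus	V-3
3	2e+05	omim	uncertain	no	benign	B-DGV50
0	4e+06	omim	uncertain	no	pathogenic	P-SIZE
3	4e+06	omim	uncertain	no	benign	B-DGV50
0	2e+05	none	reported	no	vus	V-FALLBACK
3	2e+05	none	reported	no	benign	B-DGV50
0	4e+06	none	reported	no	pathogenic	P-SIZE
3	4e+06	none	reported	no	benign	B-DGV50
0	2e+05	non_omim	reported	no	vus	V-1
3	2e+05	non_omim	reported	no	benign	B-DGV50
0	4e+06	non_omim	reported	no	pathogenic	P-SIZE
3	4e+06	non_omim	reported	no	benign	B-DGV50
0	2e+05	omim	reported	no	likely_pathogenic	LP-DBCONS
3	2e+05	omim	reported	no	benign	B-DGV50
0	4e+06	omim	reported	no	pathogenic	P-SIZE
3	4e+06	omim	reported	no	benign	B-DGV50
0	2e+05	none	consistent	no	vus	V-FALLBACK
3	2e+05	none	consistent	no	benign	B-DGV50
0	4e+06	none	consistent	no	pathogenic	P-SIZE
3	4e+06	none	consistent	no	benign	B-DGV50
0	2e+05	non_omim	consistent	no	vus	V-1
3	2e+05	non_omim	consistent	no	benign	B-DGV50
0	4e+06	non_omim	consistent	no	pathogenic	P-SIZE
3	4e+06	non_omim	consistent	no	benign	B-DGV50
0	2e+05	omim	consistent	no	pathogenic	P-CONS
3	2e+05	omim	consistent	no	benign	B-DGV50
0	4e+06	omim	consistent	no	pathogenic	P-SIZE
3	4e+06	omim	consistent	no	benign	B-DGV50
0	2e+05	none	none	yes	pathogenic	P-SYND
3	2e+05	none	none	yes	benign	B-DGV50
0	4e+06	none	none	yes	pathogenic	P-SIZE
3	4e+06	none	none	yes	benign	B-DGV50
0	2e+05	non_omim	none	yes	pathogenic	P-SYND
3	2e+05	non_omim	none	yes	benign	B-DGV50
0	4e+06	non_omim	none	yes	pathogenic	P-SIZE
3	4e+06	non_omim	none	yes	benign	B-DGV50
0	2e+05	omim	none	yes	pathogenic	P-SYND
3	2e+05	omim	none	yes	benign	B-DGV50
0	4e+06	omim	none	yes	pathogenic	P-SIZE
3	4e+06	omim	none	yes	benign	B-DGV50
0	2e+05	none	uncertain	yes	pathogenic	P-SYND
3	2e+05	none	uncertain	yes	benign	B-DGV50
0	4e+06	none	uncertain	yes	pathogenic	P-SIZE
3	4e+06	none	uncertain	yes	benign	B-DGV50
0	2e+05	non_omim	uncertain	yes	pathogenic	P-SYND
3	2e+05	non_omim	uncertain	yes	benign	B-DGV50
0	4e+06	non_omim	uncertain	yes	pathogenic	P-SIZE
3	4e+06	non_omim	uncertain	yes	benign	B-DGV50
0	2e+05	omim	uncertain	yes	pathogenic	P-SYND
3	2e+05	omim	uncertain	yes	benign	B-DGV50
0	4e+06	omim	uncertain	yes	pathogenic	P-SIZE
3	4e+06	omim	uncertain	yes	benign	B-DGV50
0	2e+05	none	reported	yes	pathogenic	P-SYND
3	2e+05	none	reported	yes	benign	B-DGV50
0	4e+06	none	reported	yes	pathogenic	P-SIZE
3	4e+06	none	reported	yes	benign	B-DGV50
0	2e+05	non_omim	reported	yes	pathogenic	P-SYND
3	2e+05	non_omim	reported	yes	benign	B-DGV50
0	4e+06	non_omim	reported	yes	pathogenic	P-SIZE
3	4e+06	non_omim	reported	yes	benign	B-DGV50
0	2e+05	omim	reported	yes	pathogenic	P-SYND
3	2e+05	omim	reported	yes	benign	B-DGV50
0	4e+06	omim	reported	yes	pathogenic	P-SIZE
3	4e+06	omim	reported	yes	benign	B-DGV50
0	2e+05	none	consistent	yes	pathogenic	P-SYND
3	2e+05	none	consistent	yes	benign	B-DGV50
0	4e+06	none	consistent	yes	pathogenic	P-SIZE
3	4e+06	none	consistent	yes	benign	B-DGV50
0	2e+05	non_omim	consistent	yes	pathogenic	P-SYND
3	2e+05	non_omim	consistent	yes	benign	B-DGV50
0	4e+06	non_omim	consistent	yes	pathogenic	P-SIZE
3	4e+06	non_omim	consistent	yes	benign	B-DGV50
0	2e+05	omim	consistent	yes	pathogenic	P-SYND
3	2e+05	omim	consistent	yes	benign	B-DGV50
0	4e+06	omim	consistent	yes	pathogenic	P-SIZE
3	4e+06	omim	consistent	yes	benign	B-DGV50
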