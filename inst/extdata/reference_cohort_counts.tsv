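cnv_type	size_bin	label	count	pct_printed
loss	<0.5 Mb	benign	223	91.8
loss	<0.5 Mb	likely_benign	12	4.9
loss	<0.5 Mb	vus	6	2.5
loss	<0.5 Mb	likely_pathogenic	0	0
loss	<0.5 Mb	pathogenic	2	0.8
loss	0.5-1 Mb	benign	13	86.6
loss	0.5-1 Mb	likely_benign	0	0
loss	0.5-1 Mb	vus	0	0
loss	0.5-1 Mb	likely_pathogenic	1	6.7
loss	0.5-1 Mb	pathogenic	1	6.7
loss	1-3 Mb	benign	8	50
loss	1-3 Mb	likely_benign	1	6.3
loss	1-3 Mb	vus	4	25
loss	1-3 Mb	likely_pathogenic	1	6.3
loss	1-3 Mb	pathogenic	2	12.4
loss	3-5 Mb	benign	0	0
loss	3-5 Mb	likely_benign	0	0
loss	3-5 Mb	vus	0	0
loss	3-5 Mb	likely_pathogenic	0	0
loss	3-5 Mb	pathogenic	7	100
loss	>5 Mb	benign	0	0
loss	>5 Mb	likely_benign	0	0
loss	>5 Mb	vus	0	0
loss	>5 Mb	likely_pathogenic	0	0
loss	>5 Mb	pathogenic	16	100
gain	<0.5 Mb	benign	651	96.1
gain	<0.5 Mb	likely_benign	8	1.2
gain	<0.5 Mb	vus	18	2.7
gain	<0.5 Mb	likely_pathogenic	0	0
gain	<0.5 Mb	pathogenic	0	0
gain	0.5-1 Mb	benign	361	97.3
gain	0.5-1 Mb	likely_benign	1	0.3
gain	0.5-1 Mb	vus	9	2.4
gain	0.5-1 Mb	likely_pathogenic	0	0
gain	0.5-1 Mb	pathogenic	0	0
gain	1-3 Mb	benign	129	92.1
gain	1-3 Mb	likely_benign	3	2.1
gain	1-3 Mb	vus	2	1.5
gain	1-3 Mb	likely_pathogenic	1	0.7
gain	1-3 Mb	pathogenic	5	3.6
gain	3-5 Mb	benign	11	84.6
gain	3-5 Mb	likely_benign	0	0
gain	3-5 Mb	vus	0	0
gain	3-5 Mb	likely_pathogenic	0	0
gain	3-5 Mb	pathogenic	2	15.4
gain	>5 Mb	benign	1	16.7
gain	>5 Mb	likely_benign	0	0
gain	>5 Mb	vus	0	0
gain	>5 Mb	likely_pathogenic	0	0
gain	>5 Mb	pathogenic	5	83.3
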