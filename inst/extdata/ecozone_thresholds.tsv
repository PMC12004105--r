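ecozone	ffmc_mean	ffmc_sd	dmc_mean	dmc_sd	dc_mean	dc_sd	isi_mean	isi_sd	bui_mean	bui_sd	fwi_mean	fwi_sd
TP	88.8	0.3	48.3	5.4	366.1	41.8	6.5	0.3	68.4	7.9	19.2	1.4
TSW	89.1	0.4	47.8	6.6	302.2	27.2	7.8	0.5	66.5	7.5	21.1	1.6
BSW	89.3	0.3	41.5	1.5	255.5	12.8	7.4	0.4	58.0	2.2	19.3	0.8
BP	90.1	0.4	47.0	2.6	256.3	36.7	8.0	0.4	62.7	3.9	22.0	1.1
TC	86.9	1.3	43.7	5.8	238.2	49.5	4.7	0.6	53.0	8.2	12.9	1.9
BC	88.1	0.5	38.7	3.5	274.6	33.1	5.5	0.6	55.9	4.9	14.7	1.4
PM	88.3	1.1	41.7	5.2	286.3	33.8	4.9	0.6	60.5	7.0	13.9	2.6
MC	90.8	0.7	75.3	7.6	442.4	27.4	7.6	0.7	106.2	10.2	25.3	3.0
HP	89.1	0.9	37.6	5.0	227.9	46.0	8.5	1.5	50.9	4.9	19.5	3.4
BSE	90.2	0.3	39.0	2.5	147.7	18.8	10.1	0.3	46.7	3.2	21.7	1.0
TSE	89.3	0.4	28.8	3.0	119.2	13.0	9.3	1.4	35.6	3.2	17.7	1.6
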