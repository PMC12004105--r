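ecozone	ffmc	dmc	dc	isi	bui	fwi
TP	63.7	65.5	63.5	67.3	64.2	70.2
TSW	62.8	64.4	52.9	68.1	63.8	69.7
BSW	67.6	66.0	46.9	68.7	65.0	71.2
BP	65.1	60.6	38.2	66.3	54.5	68.4
TC	58.4	64.1	50.8	61.6	57.4	63.2
BC	63.3	58.4	50.7	69.3	58.6	68.0
PM	57.3	53.9	51.5	55.3	53.6	53.2
MC	52.7	58.8	64.0	56.6	62.3	58.2
HP	67.5	68.3	44.0	69.6	62.7	68.7
BSE	64.4	65.8	58.2	70.0	68.7	73.1
TSE	68.9	57.1	45.2	72.5	54.3	70.7
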