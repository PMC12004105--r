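ecozone	nat_ffmc_mean	nat_ffmc_sd	nat_isi_mean	nat_isi_sd	nat_fwi_mean	nat_fwi_sd	ez_ffmc_mean	ez_ffmc_sd	ez_isi_mean	ez_isi_sd	ez_fwi_mean	ez_fwi_sd
TP	14.4	19.6	13.9	19.6	23.8	30.2	22.2	24.0	21.2	23.7	28.8	31.8
TSW	19.3	22.5	17.4	18.8	26.9	28.9	22.0	23.7	20.4	21.7	28.4	30.6
BSW	14.6	17.9	13.2	15.3	23.3	27.9	21.0	23.2	20.1	21.4	27.7	29.5
BP	12.9	18.7	11.5	16.5	16.4	22.8	21.6	25.7	21.2	23.2	25.0	28.7
TC	26.2	32.9	23.1	33.4	46.0	39.9	28.8	28.8	27.9	29.4	36.8	36.1
BC	21.9	25.7	21.4	27.9	40.2	38.8	31.7	27.4	32.1	28.0	42.1	34.2
PM	21.3	30.5	23.8	39.9	27.9	40.0	21.1	30.1	21.6	27.0	32.0	33.8
MC	17.5	20.4	19.7	23.0	26.0	28.3	24.5	26.7	24.3	26.3	32.7	32.8
HP	14.6	18.5	14.0	15.3	21.3	25.2	17.8	22.4	19.2	22.4	23.8	27.2
BSE	16.4	21.0	14.4	16.3	28.0	30.5	19.5	25.0	24.5	27.5	35.4	34.2
TSE	18.8	25.4	14.0	16.3	21.4	28.6	20.7	25.4	16.0	21.5	21.8	26.3
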