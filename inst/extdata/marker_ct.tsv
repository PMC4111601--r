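assay	sample	group	mean_ct	sd_ct
miR-124	NTC	ntc	39.0	0.3
miR-124	Day2	neuronal	21.1	0.7
miR-124	Day4	neuronal	21.0	0.7
miR-124	Day6	neuronal	21.1	0.3
miR-124	Day8	neuronal	21.0	0.0
miR-124	OGD0h	neuronal	21.7	0.8
miR-124	OGD2h	neuronal	21.3	0.1
miR-124	OGD4h	neuronal	21.1	0.1
miR-124	E18	astrocyte	38.5	0.6
miR-143	NTC	ntc	34.4	0.9
miR-143	Day2	neuronal	32.3	1.6
miR-143	Day4	neuronal	32.6	0.7
miR-143	Day6	neuronal	33.9	1.0
miR-143	Day8	neuronal	33.0	0.0
miR-143	OGD0h	neuronal	34.1	0.3
miR-143	OGD2h	neuronal	33.6	0.4
miR-143	OGD4h	neuronal	34.1	0.6
miR-143	E18	astrocyte	30.4	0.0
miR-223	NTC	ntc	38.4	0.6
miR-223	Day2	neuronal	36.3	0.2
miR-223	Day4	neuronal	38.4	0.2
miR-223	Day6	neuronal	39.0	0.4
miR-223	Day8	neuronal	38.8	0.4
miR-223	OGD0h	neuronal	39.3	0.2
miR-223	OGD2h	neuronal	38.8	0.4
miR-223	OGD4h	neuronal	39.3	0.3
miR-223	E18	astrocyte	33.0	0.2
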