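# Frozen layer manifest of the compact 3D U-Net variant.
# Selected by scripts/search_architecture.R: the unique block composition in
# the enumerated design space whose closed-form trainable-parameter count and
# single-axis receptive field match the published network simultaneously.
# Columns: kind kernel dilation stride in out skip norm activation bias block
conv	3	1	1	1	8	0	batch	prelu:contracting	0	enc1
conv	3	1	1	8	16	0	batch	prelu:contracting	0	enc1
down	2	1	2	16	16	0	none	none	0	enc1
conv	3	2	1	16	32	0	batch	prelu:contracting	0	enc2
down	2	1	2	32	32	0	none	none	0	enc2
conv	3	3	1	32	64	0	batch	prelu:contracting	0	bottleneck
up	2	1	1	64	64	0	none	none	0	dec1
concat	0	1	1	64	96	32	none	none	0	dec1
conv	3	3	1	96	32	0	batch	prelu:expanding	0	dec1
conv	3	3	1	32	32	0	batch	prelu:expanding	0	dec1
conv	3	3	1	32	32	0	batch	prelu:expanding	0	dec1
up	2	1	1	32	32	0	none	none	0	dec2
concat	0	1	1	32	48	16	none	none	0	dec2
conv	3	2	1	48	16	0	batch	prelu:expanding	0	dec2
conv	3	2	1	16	16	0	batch	prelu:expanding	0	dec2
conv	3	2	1	16	16	0	batch	prelu:expanding	0	dec2
conv	1	1	1	16	2	0	none	none	1	classifier
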