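# version: synthetic-test-definitions-0.1
# SYNTHETIC stereotyped-subset definitions for testing only. These are NOT
# the published CLL subset definitions: motifs and lengths are invented to
# exercise the length gate, the V-gene gate and positionwise matching.
# Supply a curated definitions file for real analyses.
subset_id	v_genes	cdr3_length_aa	motif	max_mismatches
CLL#1	IGHV1-2,IGHV1-3,IGHV1-18	13	X[RK]DXXGXXXXDXX	2
CLL#2	IGHV3-21	9	XXDXXXMDX	1
CLL#4	IGHV4-34	20	XX[RK]GXXXXXXXXXXXXYXXX	3
CLL#8	IGHV4-39	19	XXRGXXXXXXXXXXXNXXX	2
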