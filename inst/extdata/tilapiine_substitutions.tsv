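gene	species	syn_count	nonsyn_count	omega_printed
ATP6	C_zillii	90	4	0.04
ATP8	C_zillii	11	2	0.18
COX1	C_zillii	159	7	0.04
COX2	C_zillii	66	7	0.11
COX3	C_zillii	73	1	0.01
CYTB	C_zillii	161	7	0.04
ND1	C_zillii	113	10	0.09
ND2	C_zillii	159	21	0.13
ND3	C_zillii	50	10	0.20
ND4	C_zillii	240	19	0.08
ND4L	C_zillii	45	4	0.09
ND5	C_zillii	224	30	0.13
ND6	C_zillii	76	24	0.32
ATP6	O_niloticus	42	6	0.14
ATP8	O_niloticus	9	3	0.33
COX1	O_niloticus	105	7	0.07
COX2	O_niloticus	41	0	0.00
COX3	O_niloticus	46	0	0.00
CYTB	O_niloticus	60	9	0.15
ND1	O_niloticus	69	7	0.10
ND2	O_niloticus	41	4	0.10
ND3	O_niloticus	18	4	0.22
ND4	O_niloticus	50	9	0.18
ND4L	O_niloticus	11	0	0.00
ND5	O_niloticus	118	24	0.20
ND6	O_niloticus	25	6	0.24
ATP6	S_galilaeus	3	1	0.33
ATP8	S_galilaeus	0	0	0
COX1	S_galilaeus	2	0	0
COX2	S_galilaeus	0	0	0
COX3	S_galilaeus	1	0	0
CYTB	S_galilaeus	5	2	0.40
ND1	S_galilaeus	5	1	0.20
ND2	S_galilaeus	3	1	0.33
ND3	S_galilaeus	1	0	0
ND4	S_galilaeus	7	0	0
ND4L	S_galilaeus	1	0	0
ND5	S_galilaeus	7	1	0.14
ND6	S_galilaeus	3	3	1.00
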