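unit	unit_len	copies_C_zillii	copies_O_niloticus	copies_S_galilaeus	location	location_kind
TA	2	2	6	10	D-loop	control_region
TG	2	0	1	0	D-loop	control_region
CAA	3	2	6	5	trnS2	pseudogene
TTA	3	2	5	5	D-loop	control_region
CCCG	4	2	6	5	trnN-trnC	IGS
AATGC	5	0	5	0	D-loop	control_region
AATAC	5	1	0	5	D-loop	control_region
TTATT	5	0	5	0	D-loop	control_region
TTTAATT	7	0	0	3	D-loop	control_region
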