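id	sex	months	chest_depth	chest_width	thurl_width	pinbone_width	flagsPrinted	externalDiagnosis	group
48	M	3.0	NA	NA	-2.9	-2.2	A	FALSE	affected
A-8	M	3.2	1.8	-2.5	2.8	3.0	B	FALSE	affected
A-6	M	5.7	1.6	-0.3	3.9	3.1	B	FALSE	affected
49	M	6.6	-2.1	-2.1	-1.4	0.0	A	FALSE	affected
A-9	M	6.7	-4.5	-4.6	-2.6	-3.4	A	FALSE	affected
A-3	M	7.3	2.5	0.2	2.7	-0.4	B,C	FALSE	affected
S-16	M	8.2	-0.2	-1.4	0.4	0.7	B	FALSE	affected
S-13	M	8.3	1.8	-2.4	3.3	-0.4	B,C	FALSE	affected
S-12	M	8.5	-0.1	-1.2	1.7	-1.6	B,C	FALSE	affected
S-8	M	10.0	-2.1	0.7	1.5	-2.6	A,C	FALSE	affected
A-2	M	10.8	-0.6	-4.3	0.9	-2.4	A,B,C	FALSE	affected
A-14	M	10.8	2.1	-2.2	1.4	0.0	B,C	FALSE	affected
A-12	M	15.1	-0.8	-0.6	2.8	-2.8	C	FALSE	affected
A-11	M	26.2	0.3	-2.4	2.1	-1.7	B,C	FALSE	affected
SH	M	26.7	1.9	0.3	3.3	0.1	B,C	FALSE	affected
A-10	F	2.5	2.9	-0.7	5.0	0.1	B,C	FALSE	affected
47	F	5.4	-1.7	-0.9	1.2	0.4	A	TRUE	affected
A-15	F	21.9	2.6	1.3	4.4	-1.2	B,C	FALSE	affected
D-1	F	42.0	1.5	-0.2	2.4	2.4	B	FALSE	affected
D-2	F	85.7	0.2	-0.5	1.9	1.0		FALSE	affected
D-3	F	70.0	1.8	0.2	4.0	2.2	B,C	FALSE	affected
NLBC-2	F	85.3	4.0	1.3	4.0	2.6	B,C	FALSE	affected
D-1	F	17.6	1.5	0.7	2.6	2.5		FALSE	affected
NLBC-2	F	14.5	2.2	2.5	2.8	1.4	C	FALSE	affected
NLBC-1	F	22.0	1.3	0.8	1.2	-0.4	C	FALSE	affected
K	F	27.1	0.3	NA	-1.9	NA		FALSE	affected
T	F	99.2	0.6	0.2	1.0	1.0		FALSE	control
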