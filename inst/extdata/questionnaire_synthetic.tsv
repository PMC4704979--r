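patient_id	q1	q2	q3	q4	q5	q6	q7	q8	q9
p01	yes	yes	no	yes	yes	3	3	2	2
p02	yes	yes	yes	yes	yes	3	3	3	3
p03	yes	yes	yes	no	yes	4	3	2	1
p04	yes	yes	yes	yes	no	2	2	2	4
p05	yes	yes	no	no	no	1	2	2	2
p06	yes	yes	yes	yes	yes	3	4	3	3
p07	yes	yes	yes	yes	yes	2	4	2	3
p08	yes	yes	yes	yes	yes	3	3	3	4
p09	yes	yes	yes	yes	yes	3	2	2	3
p10	yes	yes	yes	yes	yes	4	2	2	2
p11	yes	yes	yes	no	yes	4	2	4	2
p12	yes	yes	no	yes	no	3	3	2	1
p13	yes	yes	yes	yes	yes	2	4	4	2
p14	yes	yes	no	yes	yes	3	3	3	3
p15	yes	yes	yes	yes	yes	2	3	2	2
p16	no	yes	yes	yes	yes	1	3	3	2
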