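class	total	sens_original	sens_novel	diag_original	diag_novel
C1	13	0.000	0.231	0.0	3.0
C2	70	0.776	0.971	54.3	68.0
C3	237	0.858	0.797	203.3	189.0
C4	174	0.870	0.895	151.3	155.7
C5	58	0.523	0.926	30.3	53.7
C6	36	0.213	0.861	7.7	31.0
C7	40	0.217	0.758	8.7	30.3
C8	122	0.418	0.830	51.0	101.3
C9	40	0.442	0.933	17.7	37.3
C10	37	0.667	0.865	24.7	32.0
C11	28	0.238	1.000	6.7	28.0
C12	38	0.000	0.526	NA	NA
C13	351	0.890	0.899	312.3	315.7
C14	48	0.000	0.188	NA	NA
C15	448	0.979	0.993	438.7	445.0
C16	76	0.750	0.886	57.0	67.3
C17	206	0.841	0.866	173.3	178.3
C18	74	0.167	0.536	12.3	39.7
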