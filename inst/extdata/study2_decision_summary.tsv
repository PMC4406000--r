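decision	mean	sd
C0	1.00	3.37
C1	1.67	3.64
C2	2.19	3.70
C3	2.53	3.55
C4	3.01	3.75
C5	3.63	4.04
C6	4.15	4.23
C7	4.52	4.48
C8	5.06	4.79
C9	5.57	5.08
C10	6.22	5.21
C11	6.84	5.59
C12	7.26	5.84
C13	7.71	6.18
C14	7.89	6.49
C15	8.43	6.98
C16	8.80	7.37
C17	8.89	7.76
C18	9.50	8.13
C19	9.74	8.58
C20	9.98	9.14
UC	7.03	6.21
LC2	2.60	3.33
MC2	6.17	4.98
HC2	9.03	7.48
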