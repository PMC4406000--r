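decision	mean	sd
C1	2.38	4.85
C2	2.82	4.59
C3	3.25	4.54
C4	3.87	4.43
C5	4.35	4.45
C6	4.69	4.35
C7	5.09	4.37
C8	5.56	4.53
C9	5.99	4.75
C10	6.73	5.24
C11	7.11	5.59
C12	7.35	5.79
C13	7.51	6.02
C14	7.76	6.28
C15	8.13	6.68
C16	8.32	7.06
C17	8.28	7.33
C18	8.61	7.70
C19	9.01	8.11
C20	9.73	8.72
UC	7.25	5.74
LC	3.34	4.31
MLC	5.61	4.27
MHC	7.57	5.81
HC	8.79	7.38
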