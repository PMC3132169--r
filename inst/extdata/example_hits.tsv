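readA.F	chr1	98.00	200	4	0	1	200	100001	100200	1e-80	350
readA.R	chr1	95.50	180	8	0	10	189	180200	180021	1e-60	280
readB.F	chr2	91.00	120	10	1	5	124	5000	5119	1e-20	120
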