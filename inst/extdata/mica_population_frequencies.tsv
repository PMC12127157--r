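class	Chinese	American	Japanese	European	African
common_29	73.27	84.60	88.10	90.59	98.70
MICA*010	22.22	7.00	10.80	4.55	0.70
other	4.51	8.40	1.20	4.86	0.60
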