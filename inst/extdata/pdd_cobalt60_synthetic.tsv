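# SYNTHETIC illustrative cobalt-60 percent-depth-dose table
# (80 cm SSD, 15 x 15 cm field shape). Not measured commissioning data:
# values are a smooth plausible curve calibrated for the bundled pediatric
# phantom validation scenario. Replace with machine data for real use.
depth_cm	value_pct
0.5	100
2	94.8
5	82.5
10	62.8
15	48.3
16	45.9
17	43.6
20	36.6
25	27.3
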