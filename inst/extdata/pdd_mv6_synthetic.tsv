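# SYNTHETIC illustrative 6 MV percent-depth-dose table
# (100 cm SSD, 30 x 30 cm field shape). Not measured commissioning data:
# values are a smooth plausible curve calibrated for the bundled adult
# mantle validation scenario. Replace with machine data for real use.
depth_cm	value_pct
1.5	100
5	86.9
10	71.6
15	59.0
18	51.8
20	46.8
21	44.0
22	41.2
25	34.5
30	26.5
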