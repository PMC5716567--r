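# SYNTHETIC illustrative out-of-field dose at depth (percent of Dmax)
# versus distance from the field edge, 6 MV, 30 x 30 cm field.
# Stand-in for generic peripheral-dose compilations; calibrated for the
# bundled adult mantle validation scenario.
distance_cm	value_pct
3	9.4
4.6	6.47
5	6.08
8	3.6
12	1.8
15	1.11
15.4	1.06
20	0.55
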