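# SYNTHETIC illustrative out-of-field dose at depth (percent of Dmax)
# versus distance from the field edge, cobalt-60, 15 x 15 cm field.
# Stand-in for generic peripheral-dose compilations; calibrated for the
# bundled pediatric phantom validation scenario.
distance_cm	value_pct
3	6.5
6	4.0
10	2.0
15	0.9
20	0.45
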