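onset_s	trial	pulse	type
9.342	1	1	electric_pulse
11.3187	1	2	electric_pulse
13.2321	1	3	electric_pulse
24.1145	2	1	electric_pulse
25.9905	2	2	electric_pulse
27.9112	2	3	electric_pulse
38.0447	3	1	electric_pulse
40.1025	3	2	electric_pulse
42.2697	3	3	electric_pulse
52.3268	4	1	electric_pulse
54.4357	4	2	electric_pulse
56.4547	4	3	electric_pulse
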