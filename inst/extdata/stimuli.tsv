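name	genre	tempo_bpm	duration_s	beat_saliency_z	familiarity_z	is_metronome
Metronome_125	metronome	125	115	1.14	NA	TRUE
Metronome_116	metronome	116	115	1.14	NA	TRUE
What_a_feeling	pop_dance	132	115	0.49	-0.50	FALSE
The_flow	dance_lounge	120	115	0.41	-0.40	FALSE
Suavemente_124	merengue	124	115	-0.13	1.16	FALSE
Suavemente_116	merengue	116	115	-0.13	1.16	FALSE
Brand_new_carpet	pop_rock	126	115	-0.76	-0.68	FALSE
Since_youve_been_gone	soul	117	115	-1.15	0.42	FALSE
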