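family	n_species	n_correct	in_reference
Actinoposthiidae	5	0	FALSE
Convolutidae	15	12	TRUE
Dakuidae	7	6	TRUE
Diopisthoporidae	1	1	TRUE
Hallangiidae	1	0	FALSE
Hofsteniidae	1	1	TRUE
Isodiametridae	19	18	TRUE
Mecynostomidae	13	13	TRUE
Otocelididae	2	0	FALSE
Paratomellidae	1	1	TRUE
Proporidae	13	5	TRUE
Solenofilomorphidae	5	3	TRUE
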