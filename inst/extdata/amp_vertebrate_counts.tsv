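taxon	amp	extant
Actinopterygii	934	30000
Cyclostomata	12	120
Chondrichthyes	200	1120
Actinistia	1	2
Dipnoi	2	6
Tetrapoda	1286	33278
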