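model	set_id	reaction_type	nc	n
reactivity_only	all	aliphatic_hydroxylation	23	40
reactivity_only	all	n_dealkylation	8	10
mechanism_based	training	aliphatic_hydroxylation	20	25
mechanism_based	training	n_dealkylation	3	3
mechanism_based	test	aliphatic_hydroxylation	12	15
mechanism_based	test	n_dealkylation	7	7
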