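variant_id	fraction_id	count
v_hand	rib1	10
v_hand	rib2	10
v_hand	rib3	40
v_fill	rib1	90
v_fill	rib2	90
v_fill	rib3	160
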