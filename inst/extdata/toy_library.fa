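>v_hand
ACGTACGTACGTACGTACGTACGTA
>v_fill
TTCTTCTTCTTCTTCTTCTTCTTCT
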