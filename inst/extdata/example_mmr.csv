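"country_id","mmr"
"ALPHA",45
"BRAVO",210
"CHARLIE",650
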