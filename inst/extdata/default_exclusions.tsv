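role	code
exclude	XV
exclude	XVI
exclude	XX
exclude	XXI
whitelist	Z8551
whitelist	V1052
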