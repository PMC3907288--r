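group	n_families
ABE	484
BE	414
AB	90
AE	40
A	89
B	522
E	758
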