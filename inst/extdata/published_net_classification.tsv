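model	gained	lost	informative
abundance	1955	236	2262
occurrence	1353	686	2249
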