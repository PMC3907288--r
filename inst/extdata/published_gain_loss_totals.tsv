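analysis	model	gains	losses
total	abundance	80904	47848
total	occurrence	17319	13280
archaea	abundance	4616	2009
bacteria	abundance	36606	20196
eukarya	abundance	40515	25036
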