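# sent_id = e1/cause
1	My	my	PRON	_	_	2	nmod:poss	_	_
2	boss	boss	NOUN	_	_	3	nsubj	_	_
3	cut	cut	VERB	_	_	0	root	_	_
4	my	my	PRON	_	_	5	nmod:poss	_	_
5	salary	salary	NOUN	_	_	3	obj	_	_

# sent_id = e1/effect
1	I	I	PRON	_	_	3	nsubj	_	_
2	couldn't	can	AUX	_	_	3	aux	_	_
3	sleep	sleep	VERB	_	_	0	root	_	_
4	for	for	ADP	_	_	6	case	_	_
5	several	several	ADJ	_	_	6	amod	_	_
6	days	day	NOUN	_	_	3	obl	_	_
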