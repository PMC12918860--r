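name	pattern	ref_base	alt_base	parent
nCg	nCg	C	T
aTn	aTn	T	C
yCn	yCn	C	T
nTt	nTt	T	C
tCw>tTw	tCw	C	T
tCw>tGw	tCw	C	G
hTg	hTg	T	C
aTr	aTr	T	C	aTn
rCg	rCg	C	T	nCg
yCg	yCg	C	T	nCg
yCh	yCh	C	T	yCn
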