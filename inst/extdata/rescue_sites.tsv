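position	ref	alt
381	T	A
1481	T	C
1683	T	C
2682	G	A
2683	G	A
3028	A	C
6629	T	C
6882	A	G
7014	T	G
8281	T	C
8368	C	T
8703	G	A
9825	G	A
9896	T	C
13708	C	T
14977	T	C
15524	C	T
15526	C	T
16660	T	C
16663	C	T
16671	T	C
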