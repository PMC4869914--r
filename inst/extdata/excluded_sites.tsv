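position	ref	alt	justification
15493	G	A	Inconsistently called due to low coverage and decreased mapping quality in this region
15505	T	C	Inconsistently called due to low coverage and decreased mapping quality in this region
15632	C	T	Frequently miscalled due to decreased mapping quality in this region
15639	T	A	Frequently miscalled due to decreased mapping quality in this region
15639	T	G	Frequently miscalled due to decreased mapping quality in this region
15931	A	G	Frequently miscalled due to co-location with a frequently miscalled indel (homopolymer tract)
16672	C	T	Frequently miscalled due to proximity to a frequently miscalled indel (long homopolymer tract)
16705	C	T	Frequently miscalled due to low coverage in this region
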