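id	sequence	nt	note
1	ACCCG CAAGG CCGAC GGC	18	unmodified 18-mer reference
2	ACCC[c3G] CAAGG CCGAC GGC	18	3-deazaguanosine at position 5
3	ACCC[c1G] CAAGG CCGAC GGC	18	1-deazaguanosine at position 5
4	ACCC[I] CAAGG CCGAC GGC	18	inosine at position 5
5	ACCC[I] CAA[I]G CC[I]AC GGC	18	inosine at positions 5, 9, 13
6	AUCUG CUUGC CCAUC GGGGC CGCGG AU	27	unmodified 27-mer reference
7	AUCU[m2G] CUUGC CCAUC GGGGC CGCGG AU	27	N2-methylguanosine at position 5
8	AUCUG CUUGC CCAUC G[m2G]GGC CGCGG AU	27	N2-methylguanosine at position 17
9	AUCUG CUUGC CCAUC GGGGC C[m22G]CGG AU	27	N2,N2-dimethylguanosine at position 22
10	GGCUA GCC	8	unmodified 8-mer reference
11	GGCUA [c3G]CC	8	3-deazaguanosine at position 6
12	GGCUA [c7G]CC	8	7-deazaguanosine at position 6
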