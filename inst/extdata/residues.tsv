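code	nucleoside	base	g_class	description
A	C10H13N5O4	C5H5N5	FALSE	adenosine
C	C9H13N3O5	C4H5N3O	FALSE	cytidine
G	C10H13N5O5	C5H5N5O	TRUE	guanosine
U	C9H12N2O6	C4H4N2O2	FALSE	uridine
I	C10H12N4O5	C5H4N4O	FALSE	inosine (guanosine minus NH)
c1G	C11H14N4O5	C6H6N4O	TRUE	1-deazaguanosine (-N +CH)
c3G	C11H14N4O5	C6H6N4O	TRUE	3-deazaguanosine (-N +CH)
c7G	C11H14N4O5	C6H6N4O	TRUE	7-deazaguanosine (-N +CH)
m2G	C11H15N5O5	C6H7N5O	TRUE	N2-methylguanosine (+CH2)
m22G	C12H17N5O5	C7H9N5O	TRUE	N2,N2-dimethylguanosine (+C2H4)
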