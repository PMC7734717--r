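# term	relation	related_term	depth  (hyper: related_term is a hypernym of term)
cancer	hyper	disease	1
throat	hypo	body	2
hpv	hyper	virus	1
male	hyper	people	2
female	hyper	people	2
child	hyper	people	1
vaccine	syn	vaccination	1
vaccine	syn	shot	2
vaccine	hyper	medicine	2
insurance	syn	coverage	2
cover	syn	insure	2
affect	syn	impact	1
dose	syn	shot	2
dose	hyper	amount	2
count	syn	number	1
age	syn	year	3
disease	hyper	condition	1
virus	hyper	pathogen	1
prevent	syn	protect	2
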