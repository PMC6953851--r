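genus	n	class
Rhizobium	59	Alphaproteobacteria
Pseudomonas	12	Gammaproteobacteria
Burkholderia	11	Betaproteobacteria
Enterobacter	5	Gammaproteobacteria
Variovorax	4	Betaproteobacteria
Cupriavidus	3	Betaproteobacteria
Stenotrophomonas	2	Gammaproteobacteria
Caulobacter	1	Alphaproteobacteria
Novosphingobium	1	Alphaproteobacteria
Pelomonas	1	Betaproteobacteria
Xanthomonas	1	Gammaproteobacteria
unclassified	1	unclassified
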