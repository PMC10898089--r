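taxid	species	division	kingdom
9606	Homo sapiens	anml:primates	Metazoa
10090	Mus musculus	anml:rodents	Metazoa
7227	Drosophila melanogaster	anml:insects	Metazoa
562	Escherichia coli	prok:g-proteobacteria	Bacteria
1423	Bacillus subtilis	prok:firmicutes	Bacteria
953	Wolbachia pipientis	prok:endosymbionts	Bacteria
2190	Methanocaldococcus jannaschii	arch:euryarchaeota	Archaea
4932	Saccharomyces cerevisiae	fung:ascomycetes	Fungi
5207	Cryptococcus neoformans	fung:basidiomycetes	Fungi
4577	Zea mays	plnt:monocots	Viridiplantae
3702	Arabidopsis thaliana	plnt:dicots	Viridiplantae
5691	Trypanosoma brucei	prst:kinetoplastids	other-Eukaryota
10847	Escherichia phage phiX174	virs:prokaryotic-virus	Viruses
10632	JC polyomavirus	virs:eukaryotic-virus	Viruses
11676	Human immunodeficiency virus 1	virs:eukaryotic-virus	Viruses
32630	synthetic construct	synt:constructs	Synthetic
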