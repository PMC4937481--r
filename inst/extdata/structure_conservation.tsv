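# conservation of predicted intronic RNA structures; paralog columns list the duplicated ribosomal gene sharing the structure
no	locus	gene	paralog_locus	paralog_gene	conservation	note
1	YBR189W	RPS9B	YPL081W	RPS9A	Saccharomycetaceae and Candida sp.	
2	YDR064W	RPS13			Saccharomycetaceae	
3	YDR381W	YRA1			Saccharomycetaceae	
4	YER133W	GLC7			Saccharomyces sensu stricto	
5	YFL031W	HAC1			Fungi and Metazoa	
6	YFL034C-A	RPL22B	YLR061W	RPL22A	Saccharomycetaceae	
7	YGL076C	RPL7A	YPL198W	RPL7B	Saccharomycetaceae and Candida sp.	
8	YGL103W	RPL28			Saccharomyces sensu stricto	
9	YGL178W	MPT5			Saccharomyces sensu stricto	
10	YLR367W	RPS22B			Saccharomycetaceae except L. lactis	5' UTR intron
11	YLR367W	RPS22B			Saccharomycotina and Pezizomycotina	snR44
12	YML017W	PSP2			Saccharomyces sensu stricto	
13	YML056C	IMD4			Saccharomycetales and Diptera	snR54
14	YNL301C	RPL18B	YOL120C	RPL18A	Saccharomycetaceae and Candida sp.	
15	YNR053C	NOG2			Saccharomycetaceae and Candida sp.	snR191
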