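#gene_id	pathway_role	chrom	start	end
BrMYBL2.1	negative_regulator	A07	25180918	25181774
BrEGL3.1	positive_regulator	A09	8904764	8908450
BrEGL3.2	positive_regulator	A09	7821182	7824280
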