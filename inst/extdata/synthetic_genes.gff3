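##gff-version 3
##sequence-region A07 1 28000000
##sequence-region A09 1 30000000
A07	synthetic	gene	25180918	25181774	.	-	.	ID=BrMYBL2.1;Name=BrMYBL2.1
A07	synthetic	gene	25100000	25103500	.	+	.	ID=geneA07_1;Name=geneA07_1
A07	synthetic	gene	25250000	25251200	.	+	.	ID=geneA07_2;Name=geneA07_2
A09	synthetic	gene	7821182	7824280	.	+	.	ID=BrEGL3.2;Name=BrEGL3.2
A09	synthetic	gene	8904764	8908450	.	+	.	ID=BrEGL3.1;Name=BrEGL3.1
A09	synthetic	gene	9500000	9503000	.	-	.	ID=geneA09_1;Name=geneA09_1
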