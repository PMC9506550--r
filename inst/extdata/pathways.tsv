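# Miniature SYNTHETIC pathway graph over the bundled 93-compound library.
# Pathway names follow the twelve enriched KEGG pathways reported for
# Brachypodium; compound membership and substrate/product adjacency are
# curated chemically where defensible and otherwise illustrative — the graph
# exists to exercise enrichment and impact scoring offline, it is not a
# biochemical reference. neighbors: within-pathway adjacency (semicolon list).
pathway	compound_id	neighbors
Flavonoid biosynthesis	21	29
Flavonoid biosynthesis	29	21;38
Flavonoid biosynthesis	38	29;26
Flavonoid biosynthesis	26	38;43
Flavonoid biosynthesis	43	26;48
Flavonoid biosynthesis	48	43;33
Flavonoid biosynthesis	33	48;32
Flavonoid biosynthesis	32	33;15
Flavonoid biosynthesis	15	32;34
Flavonoid biosynthesis	34	15;27
Flavonoid biosynthesis	27	34;6
Flavonoid biosynthesis	 6	27;7
Flavonoid biosynthesis	 7	6;20
Flavonoid biosynthesis	20	7;24
Flavonoid biosynthesis	24	20;25
Flavonoid biosynthesis	25	24;92
Flavonoid biosynthesis	92	25;39
Flavonoid biosynthesis	39	92
Flavone and flavonol biosynthesis	83	76
Flavone and flavonol biosynthesis	76	83;68
Flavone and flavonol biosynthesis	68	76;69
Flavone and flavonol biosynthesis	69	68;57
Flavone and flavonol biosynthesis	57	69;72
Flavone and flavonol biosynthesis	72	57;73
Flavone and flavonol biosynthesis	73	72;75
Flavone and flavonol biosynthesis	75	73;80
Flavone and flavonol biosynthesis	80	75;86
Flavone and flavonol biosynthesis	86	80;30
Flavone and flavonol biosynthesis	30	86;71
Flavone and flavonol biosynthesis	71	30;51
Flavone and flavonol biosynthesis	51	71;70
Flavone and flavonol biosynthesis	70	51;66
Flavone and flavonol biosynthesis	66	70;50
Flavone and flavonol biosynthesis	50	66;31
Flavone and flavonol biosynthesis	31	50;58
Flavone and flavonol biosynthesis	58	31;64
Flavone and flavonol biosynthesis	64	58;46
Flavone and flavonol biosynthesis	46	64;74
Flavone and flavonol biosynthesis	74	46;41
Flavone and flavonol biosynthesis	41	74;52
Flavone and flavonol biosynthesis	52	41;53
Flavone and flavonol biosynthesis	53	52;60
Flavone and flavonol biosynthesis	60	53;87
Flavone and flavonol biosynthesis	87	60;84
Flavone and flavonol biosynthesis	84	87;79
Flavone and flavonol biosynthesis	79	84;81
Flavone and flavonol biosynthesis	81	79;45
Flavone and flavonol biosynthesis	45	81;92
Flavone and flavonol biosynthesis	92	45;88
Flavone and flavonol biosynthesis	88	92;77
Flavone and flavonol biosynthesis	77	88;85
Flavone and flavonol biosynthesis	85	77;89
Flavone and flavonol biosynthesis	89	85;90
Flavone and flavonol biosynthesis	90	89;91
Flavone and flavonol biosynthesis	91	90;78
Flavone and flavonol biosynthesis	78	91;28
Flavone and flavonol biosynthesis	28	78;37
Flavone and flavonol biosynthesis	37	28;36
Flavone and flavonol biosynthesis	36	37;67
Flavone and flavonol biosynthesis	67	36;44
Flavone and flavonol biosynthesis	44	67;55
Flavone and flavonol biosynthesis	55	44;56
Flavone and flavonol biosynthesis	56	55;54
Flavone and flavonol biosynthesis	54	56
Galactose metabolism	 9	14
Galactose metabolism	14	9;16
Galactose metabolism	16	14;19
Galactose metabolism	19	16;22
Galactose metabolism	22	19;28
Galactose metabolism	28	22;36
Galactose metabolism	36	28;41
Galactose metabolism	41	36;44
Galactose metabolism	44	41;50
Galactose metabolism	50	44;53
Galactose metabolism	53	50;55
Galactose metabolism	55	53;61
Galactose metabolism	61	55;65
Galactose metabolism	65	61;77
Galactose metabolism	77	65;82
Galactose metabolism	82	77
Amino sugar and nucleotide sugar metabolism	56	67
Amino sugar and nucleotide sugar metabolism	67	56;68
Amino sugar and nucleotide sugar metabolism	68	67;76
Amino sugar and nucleotide sugar metabolism	76	68;84
Amino sugar and nucleotide sugar metabolism	84	76;88
Amino sugar and nucleotide sugar metabolism	88	84;89
Amino sugar and nucleotide sugar metabolism	89	88;91
Amino sugar and nucleotide sugar metabolism	91	89
Pentose and glucuronate interconversions	82	61
Pentose and glucuronate interconversions	61	82;62
Pentose and glucuronate interconversions	62	61;30
Pentose and glucuronate interconversions	30	62;45
Pentose and glucuronate interconversions	45	30;58
Pentose and glucuronate interconversions	58	45;64
Pentose and glucuronate interconversions	64	58;72
Pentose and glucuronate interconversions	72	64;73
Pentose and glucuronate interconversions	73	72;75
Pentose and glucuronate interconversions	75	73;79
Pentose and glucuronate interconversions	79	75;81
Pentose and glucuronate interconversions	81	79;86
Pentose and glucuronate interconversions	86	81
Pentose phosphate pathway	 8	47
Pentose phosphate pathway	47	8;59
Pentose phosphate pathway	59	47;62
Pentose phosphate pathway	62	59;61
Pentose phosphate pathway	61	62
Valine, leucine and isoleucine biosynthesis	 3	5
Valine, leucine and isoleucine biosynthesis	 5	3;13
Valine, leucine and isoleucine biosynthesis	13	5
Tyrosine metabolism	 1	2
Tyrosine metabolism	 2	1;5
Tyrosine metabolism	 5	2;17
Tyrosine metabolism	17	5
2-Oxocarboxylic acid metabolism	93	47
2-Oxocarboxylic acid metabolism	47	93;59
2-Oxocarboxylic acid metabolism	59	47;62
2-Oxocarboxylic acid metabolism	62	59
Purine metabolism	13	17
Purine metabolism	17	13;1
Purine metabolism	 1	17
Ascorbate and aldarate metabolism	18	42
Ascorbate and aldarate metabolism	42	18;63
Ascorbate and aldarate metabolism	63	42;93
Ascorbate and aldarate metabolism	93	63
Vitamin B6 metabolism	 1	17
Vitamin B6 metabolism	17	1;4
Vitamin B6 metabolism	 4	17;10
Vitamin B6 metabolism	10	4;11
Vitamin B6 metabolism	11	10;12
Vitamin B6 metabolism	12	11;23
Vitamin B6 metabolism	23	12;35
Vitamin B6 metabolism	35	23;40
Vitamin B6 metabolism	40	35;49
Vitamin B6 metabolism	49	40
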