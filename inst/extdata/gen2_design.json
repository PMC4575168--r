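{"generation":"gen2","mixes":{"CDR":{"p1":[0.2,0.15,0.25,0.4],"p2":[0.5,0.25,0.15,0.1],"p3":[0,0.45,0.1,0.45]}},"sublibraries":[{"loops":{"BC":{"variants":[{"sites":[{"label":"D23","kind":"conserved","aas":"D"},{"label":"A24","kind":"fixed_set","aas":{},"probs":{"A":0.583333333333333,"S":0.0833333333333333,"Y":0.0833333333333333,"D":0.0833333333333333,"N":0.0833333333333333,"T":0.0833333333333333}},{"label":"P25","kind":"fixed_set","aas":{},"probs":{"P":0.625,"S":0.125,"Y":0.125,"H":0.125}},{"label":"A26","kind":"degenerate_codon","mix":"CDR"},{"label":"V27","kind":"degenerate_codon","mix":"CDR"},{"label":"V29","kind":"fixed_set","aas":"AST"},{"label":"R30","kind":"degenerate_codon","mix":"CDR"},{"label":"Y31","kind":"fixed_set","aas":"GY"}],"weight":1},{"sites":[{"label":"D23","kind":"conserved","aas":"D"},{"label":"A24","kind":"fixed_set","aas":{},"probs":{"A":0.583333333333333,"S":0.0833333333333333,"Y":0.0833333333333333,"D":0.0833333333333333,"N":0.0833333333333333,"T":0.0833333333333333}},{"label":"P25","kind":"fixed_set","aas":{},"probs":{"P":0.625,"S":0.125,"Y":0.125,"H":0.125}},{"label":"A26","kind":"degenerate_codon","mix":"CDR"},{"label":"V27","kind":"degenerate_codon","mix":"CDR"},{"label":"T28","kind":"degenerate_codon","mix":"CDR"},{"label":"V29","kind":"fixed_set","aas":"AST"},{"label":"R30","kind":"degenerate_codon","mix":"CDR"},{"label":"Y31","kind":"fixed_set","aas":"GY"}],"weight":1},{"sites":[{"label":"D23","kind":"conserved","aas":"D"},{"label":"A24","kind":"fixed_set","aas":{},"probs":{"A":0.583333333333333,"S":0.0833333333333333,"Y":0.0833333333333333,"D":0.0833333333333333,"N":0.0833333333333333,"T":0.0833333333333333}},{"label":"P25","kind":"fixed_set","aas":{},"probs":{"P":0.625,"S":0.125,"Y":0.125,"H":0.125}},{"label":"A26","kind":"degenerate_codon","mix":"CDR"},{"label":"V27","kind":"degenerate_codon","mix":"CDR"},{"label":"T28","kind":"degenerate_codon","mix":"CDR"},{"label":"28a","kind":"degenerate_codon","mix":"CDR"},{"label":"V29","kind":"fixed_set","aas":"AST"},{"label":"R30","kind":"degenerate_codon","mix":"CDR"},{"label":"Y31","kind":"fixed_set","aas":"GY"}],"weight":1}]},"DE":{"variants":[{"sites":[{"label":"G52","kind":"conserved","aas":"G"},{"label":"S53","kind":"fixed_set","aas":"SYNT"},{"label":"S55","kind":"fixed_set","aas":"SYNT"},{"label":"T56","kind":"fixed_set","aas":"TSYN"}],"weight":1},{"sites":[{"label":"G52","kind":"conserved","aas":"G"},{"label":"S53","kind":"fixed_set","aas":"SYNT"},{"label":"K54","kind":"fixed_set","aas":"NSYT"},{"label":"S55","kind":"fixed_set","aas":"SYNT"},{"label":"T56","kind":"fixed_set","aas":"TSYN"}],"weight":1}]},"FG":{"variants":[{"sites":[{"label":"T76","kind":"fixed_set","aas":"TSGA"},{"label":"G77","kind":"fixed_set","aas":"GSYADCNT"},{"label":"R78","kind":"degenerate_codon","mix":"CDR"},{"label":"G79","kind":"fixed_set","aas":"GSDN"},{"label":"D80","kind":"degenerate_codon","mix":"CDR"},{"label":"S85","kind":"conserved","aas":"S"},{"label":"K86","kind":"conserved","aas":"N"}],"weight":1},{"sites":[{"label":"T76","kind":"fixed_set","aas":"TSGA"},{"label":"G77","kind":"fixed_set","aas":"GSYADCNT"},{"label":"R78","kind":"degenerate_codon","mix":"CDR"},{"label":"G79","kind":"fixed_set","aas":"GSDN"},{"label":"D80","kind":"degenerate_codon","mix":"CDR"},{"label":"S81","kind":"degenerate_codon","mix":"CDR"},{"label":"S85","kind":"conserved","aas":"S"},{"label":"K86","kind":"conserved","aas":"N"}],"weight":1},{"sites":[{"label":"T76","kind":"fixed_set","aas":"TSGA"},{"label":"G77","kind":"fixed_set","aas":"GSYADCNT"},{"label":"R78","kind":"degenerate_codon","mix":"CDR"},{"label":"G79","kind":"fixed_set","aas":"GSDN"},{"label":"D80","kind":"degenerate_codon","mix":"CDR"},{"label":"S81","kind":"degenerate_codon","mix":"CDR"},{"label":"P82","kind":"degenerate_codon","mix":"CDR"},{"label":"S85","kind":"conserved","aas":"S"},{"label":"K86","kind":"conserved","aas":"N"}],"weight":1},{"sites":[{"label":"T76","kind":"fixed_set","aas":"TSGA"},{"label":"G77","kind":"fixed_set","aas":"GSYADCNT"},{"label":"R78","kind":"degenerate_codon","mix":"CDR"},{"label":"G79","kind":"fixed_set","aas":"GSDN"},{"label":"D80","kind":"degenerate_codon","mix":"CDR"},{"label":"S81","kind":"degenerate_codon","mix":"CDR"},{"label":"P82","kind":"degenerate_codon","mix":"CDR"},{"label":"A83","kind":"degenerate_codon","mix":"CDR"},{"label":"S85","kind":"conserved","aas":"S"},{"label":"K86","kind":"conserved","aas":"N"}],"weight":1},{"sites":[{"label":"T76","kind":"fixed_set","aas":"TSGA"},{"label":"G77","kind":"fixed_set","aas":"GSYADCNT"},{"label":"R78","kind":"degenerate_codon","mix":"CDR"},{"label":"G79","kind":"fixed_set","aas":"GSDN"},{"label":"D80","kind":"degenerate_codon","mix":"CDR"},{"label":"S81","kind":"degenerate_codon","mix":"CDR"},{"label":"P82","kind":"degenerate_codon","mix":"CDR"},{"label":"A83","kind":"degenerate_codon","mix":"CDR"},{"label":"S84","kind":"degenerate_codon","mix":"CDR"},{"label":"S85","kind":"conserved","aas":"S"},{"label":"K86","kind":"conserved","aas":"N"}],"weight":1}]}},"weight":1}]}
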