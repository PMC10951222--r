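# Static snapshot of oncogenic-effect annotations for the resistance-gene
# panel. match_type: exact = exact protein change; position = any missense
# in [pos_min, pos_max]; class = any variant of the listed truncating
# classes anywhere in the gene. Effects: GOF/likely_GOF/LOF/likely_LOF.
gene	match_type	protein_change	pos_min	pos_max	variant_classes	effect	level
ERBB2	exact	L755S	NA	NA		GOF	Level 3a
ERBB2	exact	L869R	NA	NA		GOF	Level 4
ERBB2	exact	V777L	NA	NA		GOF	Level 3a
ESR1	position		536	538	missense	GOF	Level 3a
ESR1	exact	E380Q	NA	NA		GOF	Level 3a
MTOR	exact	T1977R	NA	NA		GOF	Level 4
MTOR	exact	S2215Y	NA	NA		GOF	Level 4
AKT1	exact	E17K	NA	NA		GOF	Level 4
PIK3CA	exact	E542K	NA	NA		GOF	Level 1
PIK3CA	exact	E545K	NA	NA		GOF	Level 1
PIK3CA	exact	H1047L	NA	NA		GOF	Level 1
PIK3CA	exact	H1047R	NA	NA		GOF	Level 1
PIK3CA	exact	G1007R	NA	NA		likely_GOF
BRAF	exact	V600E	NA	NA		GOF	Level 1
FGFR1	exact	N546K	NA	NA		GOF	Level 4
FGFR1	exact	K656E	NA	NA		GOF	Level 4
FGFR2	exact	N549K	NA	NA		GOF	Level 4
KRAS	position		12	13	missense	GOF	Level 4
TP53	exact	R175H	NA	NA		LOF
TP53	exact	R273H	NA	NA		LOF
TP53	class		NA	NA	nonsense,frameshift_del,frameshift_ins,nonstop,splice	LOF
RB1	class		NA	NA	nonsense,frameshift_del,frameshift_ins,nonstop,splice	LOF
PTEN	class		NA	NA	nonsense,frameshift_del,frameshift_ins,nonstop,splice	LOF
PTEN	exact	R130Q	NA	NA		LOF
NF1	class		NA	NA	nonsense,frameshift_del,frameshift_ins,nonstop,splice	LOF
GATA3	class		NA	NA	nonsense,frameshift_del,frameshift_ins,nonstop,splice	LOF
CDH1	class		NA	NA	nonsense,frameshift_del,frameshift_ins,nonstop,splice	LOF
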