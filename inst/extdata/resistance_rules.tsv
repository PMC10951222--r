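# Data-driven resistance-feature rules. trigger: mutation_gof / mutation_lof /
# double_gof / biallelic-or-LOF is folded into mutation_lof / high_amp
# (HIGH_AMP or FOCAL_HIGH_AMP) / deep_del / er_loss (IHC) / subtype /
# signature_high / signature_low / expression_high / expression_low.
# applies_to: semicolon-separated treatments; evidence: known or plausible.
trigger	target	pathway	applies_to	evidence
mutation_gof	ESR1	ER	CDK46i;anti_ER	known
mutation_gof	ERBB2	RTK	CDK46i;anti_ER	known
mutation_gof	FGFR1	RTK	CDK46i;anti_ER	known
mutation_gof	AKT1	PI3K_AKT_mTOR	CDK46i;anti_ER	known
mutation_gof	BRAF	MAPK	CDK46i;anti_ER	plausible
mutation_gof	MTOR	PI3K_AKT_mTOR	CDK46i;anti_ER	plausible
double_gof	PIK3CA	PI3K_AKT_mTOR	CDK46i;anti_ER	plausible
mutation_lof	NF1	MAPK	CDK46i;anti_ER	known
mutation_lof	RB1	cell_cycle	CDK46i	known
mutation_lof	PTEN	PI3K_AKT_mTOR	CDK46i;anti_ER	known
high_amp	FGFR1	RTK	CDK46i	known
high_amp	FGFR2	RTK	CDK46i	known
high_amp	ERBB2	RTK	CDK46i;anti_ER	known
high_amp	AURKA	cell_cycle	CDK46i	known
high_amp	IGF1R	RTK	CDK46i;anti_ER	plausible
high_amp	INSR	RTK	CDK46i;anti_ER	plausible
er_loss	ER_IHC	ER	CDK46i;anti_ER	known
subtype	Basal	ER	CDK46i;anti_ER	known
subtype	HER2E	RTK	CDK46i;anti_ER	plausible
signature_high	RTK_ACT	RTK	CDK46i;anti_ER	plausible
signature_high	HER2_MUT	RTK	CDK46i;anti_ER	plausible
signature_high	FGFR_ACT	RTK	CDK46i;anti_ER	plausible
signature_high	ESTROGEN_RESPONSE_EARLY	ER	CDK46i;anti_ER	plausible
signature_high	ESTROGEN_RESPONSE_LATE	ER	CDK46i;anti_ER	plausible
signature_low	ESTROGEN_RESPONSE_EARLY	ER	CDK46i;anti_ER	plausible
signature_low	ESTROGEN_RESPONSE_LATE	ER	CDK46i;anti_ER	plausible
expression_high	IGF1R	RTK	CDK46i;anti_ER	plausible
expression_high	INSR	RTK	CDK46i;anti_ER	plausible
expression_high	FGFR1	RTK	CDK46i;anti_ER	plausible
expression_high	ERBB2	RTK	CDK46i;anti_ER	plausible
expression_high	ESR1	ER	CDK46i;anti_ER	plausible
expression_low	ESR1	ER	CDK46i;anti_ER	plausible
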