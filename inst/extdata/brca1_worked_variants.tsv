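variant_id	gene	prior	baseline_codes	mave_code	functional_class	is_vus	single_substitution
c.5120T>C	BRCA1	0.1	PM2_supporting	BS3	normal	TRUE	TRUE
c.5288G>T	BRCA1	0.1	PM2_supporting	PS3	abnormal	TRUE	TRUE
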