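target_id	disease_id	drug_id	first_approval_year	phase_1_2_year	phase_3_year
ENSG00000145777	MONDO_0004979	CHEMBL2108735	2021	2011	2019
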