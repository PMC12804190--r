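record_id	target_id	disease_id	datasource_id	datatype_id	score	primary_year	curation_year	clinical_phase
tslp01	ENSG00000145777	MONDO_0004979	gwas	genetic_association	0.7	2011	.	.
tslp02	ENSG00000145777	MONDO_0004979	chembl	known_drug	0.1	2011	.	I
tslp03	ENSG00000145777	MONDO_0004979	europepmc	literature	0.07	2012	.	.
tslp04	ENSG00000145777	MONDO_0004979	europepmc	literature	0.06	2013	.	.
tslp05	ENSG00000145777	MONDO_0004979	europepmc	literature	0.02	2014	.	.
tslp06	ENSG00000145777	MONDO_0004979	chembl	known_drug	0.2	2016	.	II
tslp07	ENSG00000145777	MONDO_0004979	chembl	known_drug	0.7	2019	.	III
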