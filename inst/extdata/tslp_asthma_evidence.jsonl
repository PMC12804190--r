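{"record_id":"tslp01","target_id":"ENSG00000145777","disease_id":"MONDO_0004979","datasource_id":"gwas","datatype_id":"genetic_association","score":0.7,"primary_year":2011}
{"record_id":"tslp02","target_id":"ENSG00000145777","disease_id":"MONDO_0004979","datasource_id":"chembl","datatype_id":"known_drug","score":0.1,"primary_year":2011,"clinical_phase":"I"}
{"record_id":"tslp03","target_id":"ENSG00000145777","disease_id":"MONDO_0004979","datasource_id":"europepmc","datatype_id":"literature","score":0.07,"primary_year":2012}
{"record_id":"tslp04","target_id":"ENSG00000145777","disease_id":"MONDO_0004979","datasource_id":"europepmc","datatype_id":"literature","score":0.06,"primary_year":2013}
{"record_id":"tslp05","target_id":"ENSG00000145777","disease_id":"MONDO_0004979","datasource_id":"europepmc","datatype_id":"literature","score":0.02,"primary_year":2014}
{"record_id":"tslp06","target_id":"ENSG00000145777","disease_id":"MONDO_0004979","datasource_id":"chembl","datatype_id":"known_drug","score":0.2,"primary_year":2016,"clinical_phase":"II"}
{"record_id":"tslp07","target_id":"ENSG00000145777","disease_id":"MONDO_0004979","datasource_id":"chembl","datatype_id":"known_drug","score":0.7,"primary_year":2019,"clinical_phase":"III"}
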