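# Ten published HGT candidates: gene id, expression (FPKM), best bacterial
# match and e-value, closest arthropod match and e-value, predicted function.
# The exon_coverage_fraction column is SYNTHETIC: the publication reports only
# that every candidate exceeded the 10% exon-coverage filter, so plausible
# fractions above 0.10 were assigned (lowest for scaffold537.2, described as
# supported by only a few RNA-seq reads).
gene_id	fpkm	bacterial_taxon	bacterial_evalue	arthropod_match	arthropod_evalue	predicted_function	exon_coverage_fraction
scaffold769.3	1.5e6	Streptomyces	1e-107	Musca domestica (Diptera)	0.016	Xylanase	0.95
scaffold2902.1	3.1e5	Streptomyces	1e-107	Stegodyphus (Araneae)	1.0	Xylanase	0.92
scaffold1203.1	4.3e6	Bacillus	2e-30	Anopheles darling (Diptera)	1.1	Mannanase	0.97
scaffold1827.1	3.7e4	Bacillus	1e-57	Cerapachys biroi (Hymenoptera)	3e-7	Mannanase	0.88
scaffold3436.2	1.5e4	Streptomyces	0.0	Nilaparvata lugens (Homoptera)	2.2	Hydrolase	0.85
scaffold7971.1	4.9e6	Protobacteria	1e-37	Tribolium castaneum (Coleoptera)	1e-21	Lipase/acyl-hydrolase	0.96
scaffold537.2	NA	Rickettsia	2e-31	none	NA	Hypothetical	0.12
scaffold3881.7	3.2e4	Wolbachia	9e-34	none	NA	Regulatory protein RepA	0.80
scaffold1344.1	1.9e4	Citrobacter	2e-23	none	NA	Ig-like protein, Invasin	0.78
C2660673.1	2.3e3	Lactobacillus	1e-53	Ixodes scapularis (Ixodida)	6e-22	Permease	0.60
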