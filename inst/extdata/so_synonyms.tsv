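tool	raw_term	canonical_term
annovar	stopgain	stop_gained
annovar	stoploss	stop_lost
annovar	startloss	start_lost
annovar	startgain	start_lost
annovar	nonsynonymous_snv	missense_variant
annovar	synonymous_snv	synonymous_variant
annovar	frameshift_insertion	frameshift_variant
annovar	frameshift_deletion	frameshift_variant
annovar	frameshift_substitution	frameshift_variant
annovar	frameshift_block_substitution	frameshift_variant
annovar	nonframeshift_insertion	inframe_insertion
annovar	nonframeshift_deletion	inframe_deletion
annovar	nonframeshift_substitution	protein_altering_variant
annovar	nonframeshift_block_substitution	protein_altering_variant
annovar	splicing	splice_region_variant
annovar	exonic	coding_sequence_variant
annovar	intronic	intron_variant
annovar	utr5	5_prime_UTR_variant
annovar	utr3	3_prime_UTR_variant
annovar	ncrna_exonic	non_coding_transcript_exon_variant
annovar	ncrna_intronic	non_coding_transcript_variant
annovar	ncrna_splicing	splice_region_variant
annovar	upstream	upstream_gene_variant
annovar	downstream	downstream_gene_variant
annovar	intergenic	intergenic_variant
annovar	unknown	sequence_variant
snpeff	initiator_codon_variant	start_lost
snpeff	disruptive_inframe_deletion	inframe_deletion
snpeff	disruptive_inframe_insertion	inframe_insertion
snpeff	conservative_inframe_deletion	inframe_deletion
snpeff	conservative_inframe_insertion	inframe_insertion
snpeff	5_prime_utr_premature_start_codon_gain_variant	5_prime_UTR_variant
snpeff	5_prime_utr_truncation	5_prime_UTR_variant
snpeff	3_prime_utr_truncation	3_prime_UTR_variant
snpeff	non_coding_exon_variant	non_coding_transcript_exon_variant
snpeff	nc_transcript_variant	non_coding_transcript_variant
snpeff	exon_loss_variant	transcript_ablation
snpeff	gene_fusion	transcript_ablation
snpeff	splice_branch_variant	splice_region_variant
snpeff	start_retained	start_retained_variant
snpeff	stop_retained	stop_retained_variant
vep	protein_altering_variant	protein_altering_variant
clinvar	nonsense	stop_gained
clinvar	inframe_indel	inframe_deletion
clinvar	initiator_codon_variant	start_lost
clinvar	genic_upstream_transcript_variant	upstream_gene_variant
clinvar	genic_downstream_transcript_variant	downstream_gene_variant
clinvar	no_sequence_alteration	sequence_variant
clinvar	splice_site_variant	splice_region_variant
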