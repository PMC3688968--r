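quantity	value
transfer_consistent_alli	4745
transfer_inconsistent_alli	15040
transfer_consistent_phyi	1019
transfer_inconsistent_phyi	8174
transfer_consistent_geni	901
transfer_inconsistent_geni	5300
transfer_untyped	4391
gold_interactions_total	178367
gold_interactions_physical	55767
gold_interactions_genetic	104926
target_genes	6328
production_direct_transfers	5751775
production_filtered_transfers	1248609
production_experimental_interactions	321808
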