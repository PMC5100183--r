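accession	n_clusters_total	n_clusters_young_total
acc11	96	33
acc8	96	33
acc12	113	59
acc13	111	55
acc3	118	57
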