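taxon,n_cp_max,d_stele_max,d_stem_max
synthetic_imperforate_thick_cortex,0,1.1,16.2
synthetic_sparse_large_stele,18,52.1,95.0
synthetic_dense_small_stele,18,4.0,9.5
synthetic_highly_perforate,75,40.5,120.0
synthetic_four_perforations_dense,4,2.0,5.4
synthetic_thin_cortex,6,10.0,11.4
synthetic_missing_stem,12,8.0,NA
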