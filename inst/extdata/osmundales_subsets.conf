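# Named taxon subsets for the Osmundales axis-anatomy analyses.
#
# RECONSTRUCTED lists: membership follows the published classification
# (genus and clade species listings, including the operational-unit splits
# of synonymous or separately documented specimens).  Labels use the
# Genus_epithet convention; where a species is represented by several
# operational units the suffixes _a/_b distinguish them.  Users matching
# these lists against their own matrix should reconcile labels first; any
# label absent from the matrix is simply ignored by the CLI.
#
# "Millerocaulis" stipabonettiorum is deliberately excluded from the
# millerocaulis subset (it groups with Palaeosmunda in all analyses).

[thamnopteroideae]
Thamnopteris_diploxylon
Thamnopteris_gracilis
Thamnopteris_gwynnevaughanii
Thamnopteris_javorskii
Thamnopteris_kazanensis
Thamnopteris_kidstonii
Thamnopteris_schlechtendalii
Thamnopteris_splendida
Thamnopteris_uralica
Chasmatopteris_principalis
Bathypteris_rhomboidea

[millerocaulis]
Millerocaulis_amarjolensis
Millerocaulis_aucklandicus
Millerocaulis_australis_a
Millerocaulis_australis_b
Millerocaulis_beipiaoensis
Millerocaulis_broganii
Millerocaulis_chubutensis
Millerocaulis_donponii
Millerocaulis_dunlopii
Millerocaulis_gibbianus
Millerocaulis_guptai
Millerocaulis_hebeiensis
Millerocaulis_herbstii
Millerocaulis_indicus
Millerocaulis_juandahensis
Millerocaulis_kolbei
Millerocaulis_limewoodensis
Millerocaulis_livingstonensis
Millerocaulis_lutziae
Millerocaulis_macromedullosus
Millerocaulis_patagonicus
Millerocaulis_rajmahalensis
Millerocaulis_richmondii
Millerocaulis_sahnii
Millerocaulis_santaecrucis
Millerocaulis_spinksii
Millerocaulis_swanensis
Millerocaulis_tuhajkulensis
Millerocaulis_wadei
Millerocaulis_websteri
Millerocaulis_woolfei
Millerocaulis_wrightii

[osmundacaulis]
Osmundacaulis_andrewii
Osmundacaulis_atherstonei
Osmundacaulis_bamfordae
Osmundacaulis_griggsii
Osmundacaulis_hoskingii_hoskingii
Osmundacaulis_hoskingii_tabulatus
Osmundacaulis_janae
Osmundacaulis_jonesii
Osmundacaulis_lemonii
Osmundacaulis_natalensis
Osmundacaulis_nerii
Osmundacaulis_pruchnickii
Osmundacaulis_richmondii
Osmundacaulis_skidegatensis
Osmundacaulis_tasmanensis
Osmundacaulis_tehuelchensis
Osmundacaulis_tidwellii
Osmundacaulis_whittlesii
Osmundacaulis_zululandensis

[guaireaceae]
Guairea_carnieri
Guairea_braziliensis
Guairea_milleriana
Lunea_jonesii
Zhongmingella_spp
Itopsidema_vancleavei
Donwelliacaulis_chlouberii
Tiania_yunnanense

[osmundeae]
Todea_barbara
Todea_papuana
Todea_tidwellii
Leptopteris_fraseri
Leptopteris_hymenophylloides
Leptopteris_superba
Leptopteris_wilkesiana
Leptopteris_estipularis
Claytosmunda_claytoniana
Claytosmunda_beardmorensis
Claytosmunda_chengii
Claytosmunda_johnstonii
Claytosmunda_liaoningensis
Claytosmunda_plumites
Claytosmunda_preosmunda
Claytosmunda_sinica
Claytosmunda_tekelili
Claytosmunda_wangii
Claytosmunda_embreei
Osmundastrum_cinnamomeum_extant
Osmundastrum_cinnamomeum_japan
Osmundastrum_cinnamomeum_cretaceous
Osmundastrum_cinnamomeum_neogene
Osmundastrum_precinnamomeum
Osmundastrum_pulchellum
Osmundastrum_indentatum
Osmunda_regalis
Osmunda_japonica
Osmunda_kidstonii
Plenasium_arnoldii
Plenasium_chandleri
Plenasium_dowkeri
Plenasium_bransonii
Plenasium_burgii
Plenasium_crossii
Plenasium_dakotense
Plenasium_moorei
Plenasium_nebraskense
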