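quantity,value
n_nocturnal,3498
n_crepuscular,113
n_cathemeral,526
n_diurnal,895
n_declining_nocturnal,1402
n_declining_crepuscular,45
n_declining_cathemeral,226
n_declining_diurnal,466
n_niche_imputed,156
n_trend_unclassified_lc,1288
n_trend_unclassified_dd,659
n_literature_trends,1348
n_threats_unknown,676
n_threats_recovered,649
n_decliners_modelled,2067
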