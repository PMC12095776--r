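# Default thresholds for the interactor-prediction pipeline.
oops_fc_min: 2          # OOPS RNase+/- elution fold-change, linear scale
oops_p_max: 0.05        # OOPS two-tailed Student's t-test p-value
r_min: 0.5              # profile Pearson r for a candidate interactor
opposing_compartment_pct: 60   # % in opposing compartment (all replicates)
rpkm_min: 0.5           # expressed-RNA filter: RPKM in all reps of 1 condition
min_reads: 10           # expressed-RNA filter: max raw reads over samples
min_hit_bases: 20       # BLAST hit retention: matched bases
window_bp: 100000       # orthologous-window span, bp
n_fractions: 22         # gradient fractions, top to bottom
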