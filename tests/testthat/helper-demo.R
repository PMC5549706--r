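# Shared demonstration pipeline configuration: default synthetic study
# conditions, a 6000-draw campaign at the relaxed screening thresholds, and
# the frequency slice chosen automatically from the selection density.
demo_config <- function(out_dir, seed = 7L) {
  list(out_dir = out_dir,
       synthetic = list(seed = seed),
       campaign = list(n_samples = 6000L, ln_pval_ic50_max = -6,
                       ln_pval_clinical_max = -4, seed = 5L),
       aggregate = list(min_models = "auto"),
       evaluate = list(n_trees = 200L, n_seeds = 10L))
}
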