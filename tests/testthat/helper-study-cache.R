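# Shared medium-baseline / medium-predictor sweep used by several
# acceptance checks; computed once per test run.
.study_cache <- new.env(parent = emptyenv())

cached_medium_sweep <- function() {
  if (is.null(.study_cache$records)) {
    cfg <- study_config(baseline_hr = 3, predictor_hr = 2,
                        grid_size = 13, n = 2000, replicates = 20,
                        seed = 20140703)
    .study_cache$records <- run_study(cfg)
  }
  .study_cache$records
}
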