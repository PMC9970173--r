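# Shared end-to-end cohort run used by several acceptance-style checks:
# a 20-subject synthetic cohort at the default SNR and effect sizes, with
# shortened recordings (2 trials x 20 s per condition) so the full
# pipeline stays fast; computed once per test session on first use.

cohort_run <- function() {
  if (!is.null(fx$cohort_run)) return(fx$cohort_run)
  cfg <- default_config(
    seed = 7,
    simulate = list(n_subjects = 20, n_trials = 2, trial_s = 20),
    microstate = list(k_fixed = 4, n_restarts = 10),
    stats = list(n_boot = 2000)
  )
  out <- file.path(tempdir(), "microstatr-cohort-run")
  fx$cohort_run <- run_pipeline(cfg, out)
  fx$cohort_run
}
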