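# Small, fast design/config combinations shared across tests. Problem sizes
# are scaled down from the full study defaults (see the methods vignette);
# the statistic's parameters keep their defaults.

tiny_design <- function(n_per_arm = 2, duration_rest = 2,
                        duration_task = 2, n_extra_channels = 0, ...) {
  trial_design(n_per_arm = n_per_arm, duration_rest = duration_rest,
               duration_task = duration_task,
               n_extra_channels = n_extra_channels, ...)
}

tiny_config <- function(...) {
  capen_config(params = capen_params(epoch_len = 400), min_epochs = 1, ...)
}

# the scaled setup used by the stochastic acceptance suites: one 400-sample
# epoch per condition cell
accept_design <- function(n_per_arm = 12) {
  trial_design(n_per_arm = n_per_arm, duration_rest = 0.8,
               duration_task = 0.8, n_extra_channels = 0)
}

accept_config <- function() {
  capen_config(params = capen_params(epoch_len = 400), min_epochs = 1)
}
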