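# Shared builders for desk-scale fixtures: short records at reduced
# sampling rate and a deliberately small model so the suite stays fast.

tiny_dataset <- function(n = 8, seed = 11, duration = 4, fs = 100,
                         priors = NULL, leads = standard_leads()) {
  priors <- priors %||% clinical_priors()
  generate_dataset(n, class_priors = priors, duration = duration, fs = fs,
                   lead_names = leads, seed = seed)
}

two_class_priors <- function(a = "N", b = "AMI", p = 0.5) {
  pr <- stats::setNames(rep(0, 15), task2_classes())
  pr[a] <- p
  pr[b] <- 1 - p
  pr
}

tiny_config <- function(n_leads = 12, l_win = 64, hidden = 8,
                        base_channels = 8, epochs = 8, lr = 3e-3,
                        batch_size = 32, seed = 3, ...) {
  model_config(
    n_leads = n_leads, l_win = l_win,
    encoder = encoder_config(base_channels = base_channels,
                             branch_channels = base_channels %/% 2,
                             stem_kernel = 5),
    recurrent = recurrent_config(hidden_size = hidden),
    batch_size = batch_size, epochs = epochs, lr = lr, seed = seed, ...
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# random per-lead feature maps [d x t x m] for recurrent-module tests
random_feats <- function(n_leads, d, t_len, m, seed = 1) {
  set.seed(seed)
  lapply(seq_len(n_leads), function(i) {
    array(rnorm(d * t_len * m, sd = 0.5), dim = c(d, t_len, m))
  })
}

# random gate parameter sets with the package's layout
random_gates <- function(d_in_f, d_in_other, d_in_cand, dh, seed = 1) {
  set.seed(seed)
  mk <- function(d_in) matrix(rnorm(d_in * dh, sd = 0.4), d_in, dh)
  list(w_f = mk(d_in_f), w_i = mk(d_in_other), w_c = mk(d_in_cand),
       w_o = mk(d_in_other),
       b_f = rnorm(dh, sd = 0.2), b_i = rnorm(dh, sd = 0.2),
       b_c = rnorm(dh, sd = 0.2), b_o = rnorm(dh, sd = 0.2))
}
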