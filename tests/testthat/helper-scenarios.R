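# Shared fixtures built in code.

# Exhaustive pair-count oracle for PIE: expand the sample into individual
# labels and count, over all C(N, 2) pairs, the fraction that belong to
# different groups. Independent of the closed-form estimator.
pie_pair_oracle <- function(counts) {
  labels <- rep(seq_along(counts), counts)
  prs <- utils::combn(length(labels), 2)
  mean(labels[prs[1, ]] != labels[prs[2, ]])
}

# Minimal two-group scenario with explicit quality parameters.
tiny_scenario <- function(f = 0.5, q = 0.4, ovules = 20, d = c(0, 0),
                          seed = 1L) {
  scenario_config(
    groups = c("bees", "flies"),
    p_spring = c(0.7, 0.3), p_summer = c(0.3, 0.7),
    d_spring = d,
    qtc_spring = c(4, 1), qtc_summer = c(1, 4),
    f_spring = c(f, f), f_summer = c(f, f),
    q_spring = c(q, q), q_summer = c(q, q),
    ovules = ovules, seed = seed)
}

# Three well-separated Gaussian blobs in the unit square.
gaussian_blobs <- function(n_per = 20, sd = 0.03, seed = 1) {
  set.seed(seed)
  centers <- rbind(c(0.2, 0.2), c(0.8, 0.3), c(0.4, 0.85))
  do.call(rbind, lapply(1:3, function(i)
    cbind(rnorm(n_per, centers[i, 1], sd), rnorm(n_per, centers[i, 2], sd))))
}
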