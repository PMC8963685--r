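# Shared fixtures: small hand-built samples and scaled-down generator calls.

# six-row sample with binary negative controls, used for hand-summed oracles
hand_sample <- function() {
  tnd_sample(data.frame(
    a = c(1, 0, 1, 0, 1, 0),
    y = c(0, 0, 0, 0, 1, 1),
    z = c(1, 0, 0, 1, 1, 0),
    w = c(1, 1, 0, 0, 1, 0)
  ), z = "z", w = "w")
}

# a moderately sized binary-setting sample for estimator tests
quick_binary_sample <- function(beta0 = -0.693, seed = 421, n_pop = 1e6) {
  cfg <- binary_dgp_config(beta0 = beta0, n_pop = n_pop)
  select_tnd_sample(simulate_population(cfg, seed = seed))
}

# random nonsingular cell-probability tables p[z, a, u]
random_cell_probs <- function(seed) {
  set.seed(seed)
  repeat {
    p <- array(stats::runif(8, 0.02, 1), c(2, 2, 2))
    for (u in 1:2) p[, , u] <- p[, , u] / sum(p[, , u])
    ok <- TRUE
    for (a in 0:1) {
      M <- rbind(p[, a + 1, 1], p[, a + 1, 2])
      if (abs(det(M)) < 0.01) ok <- FALSE
    }
    if (ok) return(p)
  }
}
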