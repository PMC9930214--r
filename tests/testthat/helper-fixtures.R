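# Shared test fixtures, built in code.

# a random 6x6 row-stochastic matrix (rows renormalized Dirichlet-style)
rand_stochastic_matrix <- function() {
  M <- matrix(stats::rexp(36), 6, 6)
  M <- M / rowSums(M)
  dimnames(M) <- list(CEA_STATES, CEA_STATES)
  M
}

# reward set with given per-state vectors (defaults: zero everywhere)
make_rewards <- function(utility = numeric(6), cost_recurring = numeric(6),
                         cost_transition = numeric(6)) {
  z <- function(v) stats::setNames(rep_len(v, 6), CEA_STATES)
  structure(list(utility = z(utility), cost_recurring = z(cost_recurring),
                 cost_transition = z(cost_transition),
                 arm = "CABG", instrument = "SAQ"),
            class = "cea_rewards")
}

# a PSA result object with prescribed incremental draws, for testing the
# CEAC/acceptance summaries independently of the Markov engine
make_psa <- function(delta_cost, delta_qaly, wtp = 3 * 8329) {
  structure(list(trials = data.frame(trial = seq_along(delta_cost),
                                     delta_cost = delta_cost,
                                     delta_qaly = delta_qaly),
                 n_trials = length(delta_cost), seed = 0L,
                 instrument = "SAQ",
                 settings = cea_settings(wtp = wtp), draws = NULL),
            class = "cea_psa")
}

# explicit matrix-power oracle: init %*% M^k computed by repeated
# multiplication of full matrices (independent of the engine's
# vector-propagation path)
matrix_power <- function(M, k) {
  P <- diag(6)
  for (i in seq_len(k)) P <- P %*% M
  P
}

# parameter set identical to the packaged base case except both arms share
# the CABG entries (for symmetry checks)
symmetric_parameters <- function() {
  p <- default_parameters()
  e <- p$entries
  for (id in grep("^(transition|cost)\\.CABG\\.", e$id, value = TRUE)) {
    twin <- sub("\\.CABG\\.", ".PCI.", id)
    p$entries[twin, c("mean", "low", "high")] <-
      p$entries[id, c("mean", "low", "high")]
  }
  for (id in grep("^utility\\.(SAQ|SF36)\\.CABG\\.", e$id, value = TRUE)) {
    twin <- sub("(utility\\.[^.]+)\\.CABG\\.", "\\1.PCI.", id)
    p$entries[twin, c("mean", "low", "high")] <-
      p$entries[id, c("mean", "low", "high")]
  }
  p
}
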