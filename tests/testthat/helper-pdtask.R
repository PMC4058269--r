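# Shared fixtures and independent oracles for the test suite.

# Hand-build an event-log tibble from parallel vectors.
make_log <- function(choice, delivered, pellets,
                     subject_id = "s1", species = "rat",
                     session_index = 1L, p_set = 0.5,
                     inadequate_SS = 0L, inadequate_LLL = 0L) {
  n <- length(choice)
  tibble::tibble(
    subject_id = rep_len(subject_id, n),
    species = rep_len(species, n),
    session_index = as.integer(rep_len(session_index, n)),
    p_set = rep_len(p_set, n),
    choice = choice,
    delivered = delivered,
    pellets = as.integer(pellets),
    inadequate_SS = as.integer(rep_len(inadequate_SS, n)),
    inadequate_LLL = as.integer(rep_len(inadequate_LLL, n))
  )
}

# Independent least-squares slope oracle: explicit normal equations,
# beta = (X'X)^{-1} X'y, no calls into lm() or the package.
slope_oracle <- function(x, y) {
  X <- cbind(1, x)
  beta <- solve(t(X) %*% X, t(X) %*% y)
  unname(beta[2, 1])
}

# Session-metrics rows shaped for the classification functions.
make_metrics <- function(subject_id, p_set, pref_LLL, experienced_odds,
                         species = "rat",
                         session_index = seq_along(p_set)) {
  tibble::tibble(
    subject_id = subject_id, species = species,
    session_index = as.integer(session_index), p_set = p_set,
    n_trials = 50L, pref_LLL = pref_LLL,
    trials_per_min = 2, pellets_per_min = 2,
    persistence = 0.5, restlessness = 0.5,
    experienced_p = 100 / (experienced_odds + 1),
    experienced_odds = experienced_odds
  )
}
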