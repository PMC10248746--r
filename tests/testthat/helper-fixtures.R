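# Shared fixtures and independent oracles.

# Minimal risk_expansion constructor for hand-built counting-process rows.
make_expansion <- function(df, exposure_cols = NULL, covariate_cols = NULL,
                           horizon = 180L, window_start = -7L) {
  if (is.null(exposure_cols))
    exposure_cols <- setdiff(names(df), c("patient_id", "start", "stop",
                                          "event", "competing", "fg_wt"))
  if (!"competing" %in% names(df)) df$competing <- 0L
  structure(df, class = c("risk_expansion", "data.frame"),
            exposure_cols = exposure_cols,
            covariate_cols = covariate_cols %||% character(0),
            horizon = horizon, window_start = window_start)
}
`%||%` <- function(a, b) if (is.null(a)) b else a

# Independent partial-likelihood oracle: direct risk-set enumeration on
# day-inclusive rows (at risk on days start..stop, event at stop).
# Weighted, Efron or Breslow ties.  Deliberately written with plain loops.
oracle_partial_loglik <- function(df, beta, x_cols, w = NULL,
                                  ties = "efron") {
  if (is.null(w)) w <- rep(1, nrow(df))
  X <- as.matrix(df[x_cols])
  eta <- drop(X %*% beta)
  r <- exp(eta)
  ll <- 0
  for (t in sort(unique(df$stop[df$event == 1]))) {
    at_risk <- which(df$start <= t & t <= df$stop)
    deaths <- which(df$event == 1 & df$stop == t)
    S0 <- sum(w[at_risk] * r[at_risk])
    S0d <- sum(w[deaths] * r[deaths])
    wd <- sum(w[deaths])
    d <- length(deaths)
    ll <- ll + sum(w[deaths] * eta[deaths])
    if (ties == "efron") {
      for (k in seq_len(d) - 1) ll <- ll - (wd / d) * log(S0 - (k / d) * S0d)
    } else {
      ll <- ll - wd * log(S0)
    }
  }
  ll
}

# Toy cohort used across survival tests: 6 patients, one binary covariate,
# integer event days with a tie.
toy6 <- function() {
  make_expansion(data.frame(
    patient_id = paste0("P", 1:6),
    start = rep(1L, 6),
    stop = c(5L, 8L, 8L, 12L, 15L, 20L),
    event = c(1L, 1L, 0L, 1L, 1L, 0L),
    x = c(1, 1, 0, 0, 1, 0)))
}

# Small simulated cohort -> encoded design, shared by selection/boruta
# tests.  Returns list(cohort, design).
small_cohort <- function(seed, n = 250L, preset = "null") {
  cfg <- preset_scenarios()[[preset]]
  cfg$n_patients <- as.integer(n)
  co <- simulate_cohort(cfg, seed = seed)
  d <- encode_exposures(co$records, cfg$scheme, cfg$catalogue,
                        patients = co$covariates$patient_id)
  list(cohort = co, design = d, config = cfg)
}
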