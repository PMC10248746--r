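#' Pooled logistic treatment models for daily antibiotic initiation
#'
#' For each antibiotic class, models the probability of initiating that
#' class on day t of the exposure window, among person-days still "at risk"
#' of initiation (the class's column for the current interval not yet
#' switched on; once on, the indicator is deterministic and contributes
#' probability 1).  Person-days are pooled across the window with interval
#' fixed effects rather than fitting a separate model per calendar day.
#'
#' The denominator model conditions on the previous-day exposure vector
#' (one persistent on/off indicator per class), interval fixed effects,
#' baseline covariates, and any time-varying confounders supplied; the
#' numerator model conditions on the previous-day exposure vector and
#' interval effects only, so baseline terms in the outcome model absorb the
#' baseline dependence.
#'
#' @param design An `exposure_design` (unmerged, persistent coding).
#' @param covariates Optional baseline covariate table (denominator only).
#' @param confounder_paths Optional long data.frame `patient_id`, `day`,
#'   plus one column per time-varying confounder (denominator only).
#' @param per_day Replace the interval fixed effects by calendar-day fixed
#'   effects (one level per window day), approximating a separate model
#'   per day; needs many initiations per day to be fittable.
#' @return Object of class `treatment_models`: per class, numerator and
#'   denominator `glm` fits (classes with no initiation are skipped with a
#'   warning and contribute weight 1).
#' @export
fit_treatment_models <- function(design, covariates = NULL,
                                 confounder_paths = NULL,
                                 per_day = FALSE) {
  pd <- person_day_table(design, covariates, confounder_paths)
  classes <- design$catalogue
  prev_cols <- paste0("prev_", classes)
  time_term <- if (per_day) "day_f" else "interval_f"
  den_terms <- c(prev_cols, time_term, attr(pd, "baseline_cols"),
                 attr(pd, "confounder_cols"))
  num_terms <- c(prev_cols, time_term)

  fit_one <- function(cls, terms) {
    rows <- pd[pd$abx_class == cls, , drop = FALSE]
    if (nrow(rows) == 0L || sum(rows$y) == 0L) return(NULL)
    # drop constant predictors within this class's at-risk person-days
    keep <- vapply(terms, function(tm) {
      v <- rows[[tm]]
      if (is.factor(v)) length(unique(as.character(v))) > 1L
      else diff(range(v)) > 0
    }, logical(1))
    terms <- terms[keep]
    f <- if (length(terms))
      as.formula(paste("y ~", paste(terms, collapse = " + ")))
    else y ~ 1
    m <- suppressWarnings(glm(f, data = rows, family = binomial()))
    pr <- predict(m, type = "response")
    if (any(pr < 1e-10) || any(pr > 1 - 1e-10)) {
      worst <- names(which.max(abs(coef(m))[-1]))
      stop(sprintf(
        "perfect separation in treatment model for class '%s' (predictor '%s')",
        cls, if (length(worst)) worst else "(intercept)"), call. = FALSE)
    }
    m
  }

  models <- lapply(classes, function(cls) {
    den <- fit_one(cls, den_terms)
    if (is.null(den)) {
      warning("class '", cls,
              "' has no initiation events; skipped (weight contribution 1)",
              call. = FALSE)
      return(NULL)
    }
    list(denominator = den, numerator = fit_one(cls, num_terms))
  })
  names(models) <- classes
  structure(list(models = models, classes = classes,
                 has_baseline = !is.null(covariates),
                 has_confounders = !is.null(confounder_paths)),
            class = "treatment_models")
}

# Person-day table of initiation decisions.  One row per (patient, day,
# class) with the class at risk of initiation on that day: y = 1 on the
# initiation day, 0 before it within the interval.  Previous-day exposure
# is the persistent class-level path at day - 1.
person_day_table <- function(design, covariates = NULL,
                             confounder_paths = NULL) {
  if (design$coding != "persistent")
    stop("treatment models require persistent exposure coding", call. = FALSE)
  win <- scheme_window(design$scheme)
  days <- win[1]:win[2]
  patients <- design$patients
  np <- length(patients)
  classes <- design$catalogue
  cols <- design$columns

  # class-level first initiation day per interval column
  fd <- design$first_day

  blocks <- vector("list", length(days))
  # persistent class-level path: earliest first_day across a class's columns
  class_first <- sapply(classes, function(cls) {
    m <- fd[, cols$abx_class == cls, drop = FALSE]
    suppressWarnings(apply(m, 1L, function(v)
      if (all(is.na(v))) NA_integer_ else min(v, na.rm = TRUE)))
  })
  class_first <- matrix(class_first, nrow = np,
                        dimnames = list(patients, classes))

  for (di in seq_along(days)) {
    d <- days[di]
    iv <- interval_of_day(design$scheme, d)
    prev <- !is.na(class_first) & class_first <= (d - 1L)
    storage.mode(prev) <- "integer"
    colnames(prev) <- paste0("prev_", classes)
    sub <- vector("list", length(classes))
    for (ci in seq_along(classes)) {
      cls <- classes[ci]
      j <- which(cols$abx_class == cls & cols$start_idx <= iv &
                   cols$end_idx >= iv)
      if (length(j) != 1L) next
      f <- fd[, j]
      at_risk <- is.na(f) | f >= d
      if (!any(at_risk)) next
      sub[[ci]] <- data.frame(
        patient_id = patients[at_risk], day = d,
        abx_class = cls,
        y = as.integer(!is.na(f[at_risk]) & f[at_risk] == d),
        interval_f = factor(iv, levels = design$scheme$interval),
        day_f = factor(d, levels = days),
        prev[at_risk, , drop = FALSE],
        stringsAsFactors = FALSE, check.names = FALSE)
    }
    blocks[[di]] <- do.call(rbind, sub[!vapply(sub, is.null, logical(1))])
  }
  pd <- do.call(rbind, blocks)

  baseline_cols <- character(0)
  if (!is.null(covariates)) {
    mm <- baseline_model_matrix(covariates)
    baseline_cols <- make.names(colnames(mm))
    colnames(mm) <- baseline_cols
    pd <- cbind(pd, as.data.frame(
      mm[match(pd$patient_id, rownames(mm)), , drop = FALSE],
      check.names = FALSE))
  }
  confounder_cols <- character(0)
  if (!is.null(confounder_paths)) {
    cp <- confounder_paths
    confounder_cols <- setdiff(names(cp), c("patient_id", "day"))
    key <- paste(pd$patient_id, pd$day)
    m <- match(key, paste(cp$patient_id, cp$day))
    if (anyNA(m))
      stop("confounder_paths must cover every person-day in the window",
           call. = FALSE)
    for (cc in confounder_cols) pd[[cc]] <- cp[[cc]][m]
  }
  rownames(pd) <- NULL
  structure(pd, baseline_cols = baseline_cols,
            confounder_cols = confounder_cols)
}

#' Stabilized inverse-probability-of-treatment weights
#'
#' For each patient and day of the exposure window, multiplies over classes
#' at risk of initiation the ratio p_num/p_den of the probability of the
#' action actually observed (initiate or not), and accumulates the product
#' over days: sw(t) = prod over s <= t.  Classes already switched on in the
#' current interval (and skipped classes) contribute 1.  After the window,
#' the weight is carried forward unchanged.
#'
#' @param models A `treatment_models` object.
#' @param design The `exposure_design` the models were fitted on.
#' @param covariates,confounder_paths As used for the denominator models.
#' @return Object of class `weight_series`: data.frame `patient_id`, `day`,
#'   `sw` over the window, with a `diagnostics` attribute (mean, sd, min,
#'   max, percentiles of the full person-day series).
#' @export
stabilized_weights <- function(models, design, covariates = NULL,
                               confounder_paths = NULL) {
  pd <- person_day_table(design, covariates, confounder_paths)
  win <- scheme_window(design$scheme)
  days <- win[1]:win[2]
  patients <- design$patients

  ratio <- rep(1, nrow(pd))
  prob <- function(m, nd) {
    # function-valued models (day -> probability) are allowed, mainly for
    # worked examples and tests
    if (is.function(m)) m(nd) else predict(m, newdata = nd,
                                           type = "response")
  }
  for (cls in models$classes) {
    m <- models$models[[cls]]
    idx <- which(pd$abx_class == cls)
    if (is.null(m) || !length(idx)) next
    p_den <- prob(m$denominator, pd[idx, , drop = FALSE])
    p_num <- prob(m$numerator, pd[idx, , drop = FALSE])
    if (any(p_den <= 0 | p_den >= 1))
      stop("positivity violation: denominator probability 0 or 1 for class '",
           cls, "'", call. = FALSE)
    y <- pd$y[idx]
    ratio[idx] <- ifelse(y == 1L, p_num / p_den,
                         (1 - p_num) / (1 - p_den))
  }

  # per patient-day product over classes, then cumulative over days
  key_p <- match(pd$patient_id, patients)
  key_d <- match(pd$day, days)
  logr <- matrix(0, nrow = length(patients), ncol = length(days),
                 dimnames = list(patients, days))
  cell <- (key_d - 1L) * length(patients) + key_p
  acc <- rowsum(log(ratio), group = cell)
  logr[as.integer(rownames(acc))] <- acc[, 1L]
  sw <- exp(t(apply(logr, 1L, cumsum)))

  out <- data.frame(patient_id = rep(patients, times = length(days)),
                    day = rep(days, each = length(patients)),
                    sw = as.vector(sw),
                    stringsAsFactors = FALSE)
  out <- out[order(out$patient_id, out$day), , drop = FALSE]
  rownames(out) <- NULL
  diag <- list(mean = mean(out$sw), sd = sd(out$sw),
               min = min(out$sw), max = max(out$sw),
               percentiles = quantile(out$sw, c(0.01, 0.05, 0.25, 0.5,
                                                0.75, 0.95, 0.99)))
  structure(out, class = c("weight_series", "data.frame"),
            diagnostics = diag, window = win)
}

#' Weight diagnostics of a stabilized weight series
#' @param ws A `weight_series`.
#' @return List with mean, sd, min, max and percentiles.
#' @export
weight_diagnostics <- function(ws) attr(ws, "diagnostics")

#' Write a weight series to person-day CSV plus a diagnostics JSON
#'
#' @param ws A `weight_series`.
#' @param csv_path Output CSV (`patient_id,day,sw`).
#' @param json_path Optional path for the diagnostic summary.
#' @return Invisibly, the CSV path.
#' @export
write_weight_series <- function(ws, csv_path, json_path = NULL) {
  write.csv(as.data.frame(ws), csv_path, row.names = FALSE)
  if (!is.null(json_path))
    jsonlite::write_json(weight_diagnostics(ws), json_path,
                         auto_unbox = TRUE, digits = NA)
  invisible(csv_path)
}

#' Truncate stabilized weights at percentiles
#'
#' Optional variance-bias tradeoff: weights below the lower or above the
#' upper percentile of the person-day series are set to those percentile
#' values.  The default pipeline applies no truncation.
#'
#' @param ws A `weight_series`.
#' @param lower,upper Percentiles in `[0, 1]`.
#' @return Truncated `weight_series` (diagnostics recomputed).
#' @export
truncate_weights <- function(ws, lower = 0, upper = 1) {
  q <- quantile(ws$sw, c(lower, upper))
  ws$sw <- pmin(pmax(ws$sw, q[1]), q[2])
  attr(ws, "diagnostics") <- list(
    mean = mean(ws$sw), sd = sd(ws$sw), min = min(ws$sw), max = max(ws$sw),
    percentiles = quantile(ws$sw, c(0.01, 0.05, 0.25, 0.5, 0.75, 0.95,
                                    0.99)))
  ws
}

#' Fit the marginal structural model
#'
#' Weighted subdistribution-hazard fit: every counting-process row is
#' weighted by the patient's stabilized IPTW at that day (carried forward
#' after the exposure window) times the Fine-Gray IPCW already on the
#' expansion, with patient-clustered sandwich standard errors.  Rows are
#' re-broken at every day the weight changes, so the expansion passed here
#' should have been built with `break_days` covering the exposure window
#' (see [msm_expand()]), or be the original expansion, which this function
#' re-breaks automatically via the weight series days.
#'
#' @param expansion A `risk_expansion`, already Fine-Gray extended if
#'   competing events are present.
#' @param weight_series A `weight_series` from [stabilized_weights()].
#' @param terms Model columns; default all exposure and covariate columns.
#' @param ... Passed to [fit_td_hazard()] (e.g. `ties`, `control`).
#' @return A `td_hazard_fit` with robust (clustered) standard errors.
#' @export
fit_msm <- function(expansion, weight_series, terms = NULL, ...) {
  w <- msm_row_weights(expansion, weight_series)
  fit_td_hazard(expansion, terms = terms, weights = w, robust = TRUE, ...)
}

# Per-row stabilized weight: sw at the row's start day (rows must be broken
# so that sw is constant within a row); before the window the weight is 1,
# after it the final window value is carried forward.
msm_row_weights <- function(expansion, weight_series) {
  win <- attr(weight_series, "window")
  ws_pat <- unique(weight_series$patient_id)
  miss <- setdiff(unique(expansion$patient_id), ws_pat)
  if (length(miss))
    stop("weight series missing patient(s): ",
         paste(head(miss, 5L), collapse = ", "), call. = FALSE)
  day <- pmin(pmax(expansion$start, win[1]), win[2])
  m <- match(paste(expansion$patient_id, day),
             paste(weight_series$patient_id, weight_series$day))
  w <- weight_series$sw[m]
  w[expansion$stop < win[1]] <- 1
  w
}

#' Counting-process expansion broken at every exposure-window day
#'
#' Convenience wrapper around [expand_counting_process()] that adds a break
#' at each day of the scheme window, so per-day stabilized weights are
#' constant within rows.
#'
#' @inheritParams expand_counting_process
#' @return A `risk_expansion`.
#' @export
msm_expand <- function(design, covariates = NULL, outcomes,
                       horizon = 180L) {
  win <- scheme_window(design$scheme)
  expand_counting_process(design, covariates, outcomes, horizon,
                          break_days = win[1]:(win[2] + 1L))
}
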