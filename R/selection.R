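#' Detect perfect separation of exposure columns on the primary event
#'
#' Flags every design column for which all, or none, of the exposed
#' patients (at least one) experienced the primary event by the horizon:
#' such columns make the corresponding regression coefficient diverge.
#'
#' @param design An `exposure_design`.
#' @param outcomes Outcome records.
#' @param horizon Day horizon for the primary event (default 180).
#' @return data.frame of flagged columns: `name`, `abx_class`, `start_idx`,
#'   `end_idx`, `n_exposed`, `n_events`.
#' @export
detect_perfect_separation <- function(design, outcomes, horizon = 180L) {
  outcomes <- validate_outcomes(outcomes)
  oc <- outcomes[match(design$patients, outcomes$patient_id), ]
  if (anyNA(oc$patient_id))
    stop("outcomes missing for some design patients", call. = FALSE)
  ev <- oc$event_type == "agvhd" & oc$event_day <= horizon
  exposed <- !is.na(design$first_day)
  n_exp <- colSums(exposed)
  n_ev <- colSums(exposed & ev)
  flag <- n_exp >= 1L & (n_ev == 0L | n_ev == n_exp)
  out <- cbind(design$columns[flag, c("name", "abx_class", "start_idx",
                                      "end_idx")],
               data.frame(n_exposed = n_exp[flag], n_events = n_ev[flag]))
  rownames(out) <- NULL
  out
}

#' Merge away perfectly separated exposure columns
#'
#' Repeatedly merges each separated column with an adjacent same-class
#' column (the earlier neighbour preferred, the later one used when no
#' earlier neighbour exists) until no column is separated or a class has
#' collapsed to a single column; a fully merged class still separated is
#' dropped with a warning.
#'
#' @inheritParams detect_perfect_separation
#' @return A new `exposure_design` free of separated columns.
#' @export
resolve_separation <- function(design, outcomes, horizon = 180L) {
  repeat {
    flags <- detect_perfect_separation(design, outcomes, horizon)
    if (nrow(flags) == 0L) return(design)
    f <- flags[1L, ]
    cols <- design$columns
    same <- which(cols$abx_class == f$abx_class)
    if (length(same) == 1L) {
      warning("class '", f$abx_class,
              "' fully merged but still separated; dropping column ",
              f$name, call. = FALSE)
      design <- drop_design_column(design, f$name)
      next
    }
    earlier <- same[cols$end_idx[same] == f$start_idx - 1L]
    later <- same[cols$start_idx[same] == f$end_idx + 1L]
    nb <- if (length(earlier)) cols[earlier[1L], ] else cols[later[1L], ]
    design <- merge_columns(design, f$abx_class,
                            min(nb$start_idx, f$start_idx):
                              max(nb$end_idx, f$end_idx))
  }
}

#' AIC-guided backward elimination over exposure terms
#'
#' Iterates candidate model reductions: (a) merging two adjacent
#' same-class interval columns whose current coefficients show a similar
#' association (both significant with the same sign, or both
#' non-significant, 2-sided Wald p against `alpha`), and (b) removing a
#' class whose terms are non-significant in all its intervals.  At each
#' step every candidate is refitted, the candidate with the largest AIC
#' decrease is accepted (ties broken by evaluation order: classes in
#' catalogue order, intervals chronological; merges evaluated before
#' removals per class), and the procedure stops when no candidate strictly
#' decreases the AIC.  Nonantibiotic covariate terms are never candidates.
#'
#' @param design An `exposure_design` (after [resolve_separation()]).
#' @param outcomes Outcome records.
#' @param covariates Optional baseline covariate table.
#' @param fitter Function `design -> td_hazard_fit`; the default builds a
#'   Fine-Gray extended counting-process expansion and fits it with
#'   [fit_td_hazard()].
#' @param alpha Significance threshold (default 0.05).
#' @param horizon Administrative censoring day (default 180).
#' @param ... Passed to [fit_td_hazard()] by the default fitter.
#' @return List: `fit` (final `td_hazard_fit`), `design` (reduced design),
#'   `trace` (a `selection_trace`: every evaluated step with AIC before and
#'   after and whether it was accepted).
#' @export
backward_eliminate <- function(design, outcomes, covariates = NULL,
                               fitter = NULL, alpha = 0.05,
                               horizon = 180L, ...) {
  if (is.null(fitter)) {
    fitter <- function(d) {
      ex <- expand_counting_process(d, covariates, outcomes, horizon)
      ex <- fine_gray_extend(ex, outcomes)
      fit_td_hazard(ex, on_separation = "warn", ...)
    }
  }
  fit <- fitter(design)
  if (!fit$converged)
    stop("initial full model did not converge", call. = FALSE)
  initial_fit <- fit

  steps <- list()
  repeat {
    cands <- selection_candidates(design, fit, alpha)
    if (nrow(cands) == 0L) break
    evals <- vector("list", nrow(cands))
    for (i in seq_len(nrow(cands))) {
      cand <- cands[i, ]
      d2 <- apply_candidate(design, cand)
      f2 <- tryCatch(fitter(d2), error = function(e) NULL)
      ok <- !is.null(f2) && f2$converged
      evals[[i]] <- data.frame(
        action = cand$action, abx_class = cand$abx_class,
        intervals = cand$intervals,
        aic_before = fit$aic,
        aic_after = if (ok) f2$aic else NA_real_,
        converged = ok, accepted = FALSE,
        stringsAsFactors = FALSE)
      attr(evals[[i]], "design") <- d2
      attr(evals[[i]], "fit") <- f2
    }
    tab <- do.call(rbind, evals)
    delta <- tab$aic_before - tab$aic_after
    delta[is.na(delta)] <- -Inf
    best <- which.max(delta)  # first max wins: evaluation-order tie-break
    if (delta[best] <= 0) {
      steps <- c(steps, list(tab))
      break
    }
    tab$accepted[best] <- TRUE
    steps <- c(steps, list(tab))
    design <- attr(evals[[best]], "design")
    fit <- attr(evals[[best]], "fit")
  }

  trace <- if (length(steps)) do.call(rbind, steps) else
    data.frame(action = character(0), abx_class = character(0),
               intervals = character(0), aic_before = numeric(0),
               aic_after = numeric(0), converged = logical(0),
               accepted = logical(0))
  rownames(trace) <- NULL
  trace <- structure(trace, class = c("selection_trace", "data.frame"),
                     initial_aic = initial_fit$aic, final_aic = fit$aic)
  list(fit = fit, design = design, trace = trace)
}

# Enumerate candidate steps given the current fit.  Candidates are
# returned in evaluation order: for each class (catalogue order), adjacent
# merges chronologically, then the whole-class removal if eligible.
selection_candidates <- function(design, fit, alpha) {
  cols <- design$columns
  out <- list()
  for (cls in design$catalogue) {
    idx <- which(cols$abx_class == cls)
    if (!length(idx)) next
    nm <- cols$name[idx]
    present <- nm %in% fit$terms  # degenerate columns may be absent
    pvals <- fit$p_value[nm[present]]
    coefs <- fit$coefficients[nm[present]]
    if (length(idx) >= 2L) {
      for (k in seq_len(length(idx) - 1L)) {
        a <- nm[k]; b <- nm[k + 1L]
        if (!(a %in% fit$terms) || !(b %in% fit$terms)) next
        if (cols$end_idx[idx[k]] + 1L != cols$start_idx[idx[k + 1L]]) next
        sig_a <- fit$p_value[a] < alpha
        sig_b <- fit$p_value[b] < alpha
        similar <- (!sig_a && !sig_b) ||
          (sig_a && sig_b &&
             sign(fit$coefficients[a]) == sign(fit$coefficients[b]))
        if (similar)
          out[[length(out) + 1L]] <- data.frame(
            action = "merge_intervals", abx_class = cls,
            intervals = paste(cols$start_idx[idx[k]]:cols$end_idx[idx[k + 1L]],
                              collapse = ","),
            stringsAsFactors = FALSE)
      }
    }
    if (length(pvals) && all(pvals >= alpha))
      out[[length(out) + 1L]] <- data.frame(
        action = "remove_class", abx_class = cls, intervals = "",
        stringsAsFactors = FALSE)
  }
  if (!length(out))
    return(data.frame(action = character(0), abx_class = character(0),
                      intervals = character(0), stringsAsFactors = FALSE))
  do.call(rbind, out)
}

apply_candidate <- function(design, cand) {
  if (cand$action == "merge_intervals") {
    merge_columns(design, cand$abx_class,
                  as.integer(strsplit(cand$intervals, ",")[[1]]))
  } else {
    nm <- design$columns$name[design$columns$abx_class == cand$abx_class]
    for (x in nm) design <- drop_design_column(design, x)
    design
  }
}

#' @export
print.selection_trace <- function(x, ...) {
  acc <- x[x$accepted, , drop = FALSE]
  cat(sprintf("Selection trace: %d candidate evaluations, %d accepted; AIC %.2f -> %.2f\n",
              nrow(x), nrow(acc), attr(x, "initial_aic"),
              attr(x, "final_aic")))
  if (nrow(acc)) print.data.frame(acc)
  invisible(x)
}

#' Serialize a selection trace to JSON
#' @param trace A `selection_trace`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_trace_json <- function(trace, path) {
  jsonlite::write_json(
    list(initial_aic = attr(trace, "initial_aic"),
         final_aic = attr(trace, "final_aic"),
         steps = as.data.frame(trace)),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
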