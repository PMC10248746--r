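#' Inverse-probability-of-censoring weights for the Fine-Gray model
#'
#' Estimates the censoring distribution G(t) = P(C >= t) by Kaplan-Meier
#' (censoring counted as the "event"; primary and competing events treated
#' as censored for G, and at tied times events precede censoring).  In the
#' subdistribution-hazard fit, patients with a competing event remain in
#' risk sets after their event with weight G(t)/G(t_competing), evaluated
#' left-continuously on the integer-day grid; everyone else carries weight
#' 1 while at risk.
#'
#' @param outcomes Validated outcome records.
#' @param horizon Administrative censoring day (default 180); event days
#'   beyond it are treated as censored at the horizon.
#' @return Object of class `fg_ipcw`: the censoring KM as a step function
#'   plus its jump times.
#' @export
fine_gray_ipcw <- function(outcomes, horizon = 180L) {
  outcomes <- validate_outcomes(outcomes)
  if (nrow(outcomes) == 0L) stop("outcomes is empty", call. = FALSE)
  time <- pmin(outcomes$event_day, as.integer(horizon))
  cens <- as.integer(outcomes$event_type == "censored" |
                       outcomes$event_day > horizon)
  km <- survival::survfit(survival::Surv(time, cens) ~ 1)
  # G(t-) via a right-continuous step function evaluated at t - 0.5:
  # G drops just after each censoring time.
  gfun <- stats::stepfun(km$time, c(1, km$surv), right = FALSE)
  structure(list(gfun = gfun,
                 jump_days = km$time[km$n.event > 0],
                 horizon = as.integer(horizon)),
            class = "fg_ipcw")
}

# left limit G(t-): probability of being uncensored just before day t
g_left <- function(ipcw, t) ipcw$gfun(t - 0.5)

#' Per-day IPCW weight for an extended patient
#'
#' @param ipcw A `fg_ipcw` object.
#' @param t Integer day(s) after the competing event.
#' @param t_competing Day of the competing event.
#' @return Numeric weights in (0, 1].
#' @export
fg_weight <- function(ipcw, t, t_competing) {
  gref <- g_left(ipcw, t_competing)
  if (gref <= 0)
    stop("censoring survival is 0 at the competing event time; IPCW weight undefined",
         call. = FALSE)
  g_left(ipcw, pmax(t, t_competing)) / gref
}

#' Extend a risk expansion with Fine-Gray weighted rows
#'
#' Appends post-event rows for patients with a competing event: they remain
#' "at risk" from the day after death through `horizon`, covariate paths
#' carried forward from the time of the competing event, with weight
#' G(t)/G(t_competing).  Rows are broken wherever G steps so the weight is
#' constant within a row.  Adds (or multiplies) an `fg_wt` column; all
#' pre-existing rows get weight 1.
#'
#' @param expansion A `risk_expansion`.
#' @param outcomes The outcome records the expansion was built from.
#' @param ipcw Optional precomputed `fg_ipcw` (built from `outcomes` and
#'   the expansion's horizon when omitted).
#' @return The extended `risk_expansion` with an `fg_wt` column.
#' @export
fine_gray_extend <- function(expansion, outcomes, ipcw = NULL) {
  outcomes <- validate_outcomes(outcomes)
  horizon <- attr(expansion, "horizon")
  if (is.null(ipcw)) ipcw <- fine_gray_ipcw(outcomes, horizon)
  expansion$fg_wt <- rep(1, nrow(expansion))

  comp <- outcomes[outcomes$event_type == "death" &
                     outcomes$event_day <= horizon, , drop = FALSE]
  comp <- comp[comp$patient_id %in% expansion$patient_id, , drop = FALSE]
  if (nrow(comp) == 0L) return(expansion)

  ext <- vector("list", nrow(comp))
  for (i in seq_len(nrow(comp))) {
    pid <- comp$patient_id[i]
    td <- comp$event_day[i]
    if (td >= horizon) next
    # break extended follow-up at censoring jump days (weight steps there)
    br <- ipcw$jump_days
    br <- sort(unique(as.integer(br[br > td & br <= horizon])))
    starts <- c(td + 1L, br + 1L)
    stops <- c(br, horizon)
    keep <- starts <= stops
    starts <- starts[keep]; stops <- stops[keep]
    if (!length(starts)) next
    prow <- expansion[expansion$patient_id == pid, , drop = FALSE]
    prow <- prow[which.max(prow$stop), , drop = FALSE]  # LOCF covariates
    block <- prow[rep(1L, length(starts)), , drop = FALSE]
    block$start <- starts
    block$stop <- stops
    block$event <- 0L
    block$fg_wt <- fg_weight(ipcw, starts, td)
    ext[[i]] <- block
  }
  ext <- ext[!vapply(ext, is.null, logical(1))]
  if (length(ext)) {
    out <- rbind(expansion, do.call(rbind, ext))
    rownames(out) <- NULL
    attributes(out)[c("exposure_cols", "covariate_cols", "horizon",
                      "window_start")] <-
      attributes(expansion)[c("exposure_cols", "covariate_cols", "horizon",
                              "window_start")]
    class(out) <- class(expansion)
    expansion <- out
  }
  expansion
}
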