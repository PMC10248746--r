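#' Expand exposures and outcomes into counting-process rows
#'
#' Builds the person-interval representation the hazard engine consumes:
#' each patient's follow-up (from the scheme's window start through the
#' event/censoring day, administratively truncated at `horizon`) is broken
#' at every day an exposure column switches value, so covariates are
#' constant within a row.  Days are inclusive on both ends; a row covering
#' days `[start, stop]` is at risk on that whole run and the primary-event
#' flag is set on the terminal row only.
#'
#' @param design An `exposure_design`.
#' @param covariates Optional baseline covariate table; when supplied, the
#'   encoded baseline columns are appended to every row.
#' @param outcomes Outcome records (one per design patient).
#' @param horizon Administrative censoring day (default 180).
#' @param break_days Optional extra integer days at which to break rows
#'   (used for person-day weighting); breaks outside a patient's follow-up
#'   are ignored.
#' @return data.frame of class `risk_expansion` with columns `patient_id`,
#'   `start`, `stop`, `event`, `competing` plus exposure and covariate
#'   columns; attributes `exposure_cols`, `covariate_cols`, `horizon`.
#' @export
expand_counting_process <- function(design, covariates = NULL, outcomes,
                                    horizon = 180L, break_days = NULL) {
  outcomes <- validate_outcomes(outcomes)
  miss <- setdiff(design$patients, outcomes$patient_id)
  if (length(miss))
    stop("missing outcome record(s) for patient(s): ",
         paste(head(miss, 5L), collapse = ", "), call. = FALSE)
  mm <- NULL
  if (!is.null(covariates)) {
    mm <- baseline_model_matrix(covariates)
    miss <- setdiff(design$patients, rownames(mm))
    if (length(miss))
      stop("missing covariates for patient(s): ",
           paste(head(miss, 5L), collapse = ", "), call. = FALSE)
  }

  horizon <- as.integer(horizon)
  win <- scheme_window(design$scheme)
  oc <- outcomes[match(design$patients, outcomes$patient_id), ]
  end_day <- pmin(oc$event_day, horizon)
  is_event <- oc$event_type == "agvhd" & oc$event_day <= horizon
  is_competing <- oc$event_type == "death" & oc$event_day <= horizon

  switches <- exposure_switch_days(design)
  rows <- vector("list", length(design$patients))
  for (i in seq_along(design$patients)) {
    pid <- design$patients[i]
    stop_i <- end_day[i]
    if (stop_i < win[1])
      stop(sprintf("patient %s: event day %d precedes window start %d",
                   pid, stop_i, win[1]), call. = FALSE)
    br <- switches[[i]]
    if (!is.null(break_days)) br <- c(br, as.integer(break_days))
    br <- sort(unique(br[br > win[1] & br <= stop_i]))
    starts <- c(win[1], br)
    stops <- c(br - 1L, stop_i)
    keep <- starts <= stops
    starts <- starts[keep]; stops <- stops[keep]
    nr <- length(starts)
    ev <- integer(nr)
    if (is_event[i]) ev[nr] <- 1L
    rows[[i]] <- data.frame(patient_id = pid, start = starts, stop = stops,
                            event = ev,
                            competing = rep(as.integer(is_competing[i]), nr),
                            stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)

  # exposure column values: constant within a row, evaluate at row start
  # (rows break exactly at switch days, so start is representative)
  expo <- matrix(0L, nrow = nrow(out), ncol = nrow(design$columns),
                 dimnames = list(NULL, design$columns$name))
  fd <- design$first_day[match(out$patient_id, design$patients), ,
                         drop = FALSE]
  on <- !is.na(fd) & fd <= out$start
  if (design$coding == "transient") {
    span_end <- design$scheme$end[design$columns$end_idx]
    on <- on & outer(out$start, span_end, `<=`)
  }
  expo[on] <- 1L
  out <- cbind(out, as.data.frame(expo, check.names = FALSE))

  covariate_cols <- character(0)
  if (!is.null(mm)) {
    cv <- mm[match(out$patient_id, rownames(mm)), , drop = FALSE]
    rownames(cv) <- NULL
    covariate_cols <- colnames(mm)
    out <- cbind(out, as.data.frame(cv, check.names = FALSE))
  }
  structure(out,
            class = c("risk_expansion", "data.frame"),
            exposure_cols = design$columns$name,
            covariate_cols = covariate_cols,
            horizon = horizon,
            window_start = win[1])
}

expansion_terms <- function(expansion, terms = NULL) {
  if (is.null(terms))
    terms <- c(attr(expansion, "exposure_cols"),
               attr(expansion, "covariate_cols"))
  miss <- setdiff(terms, names(expansion))
  if (length(miss))
    stop("term(s) not present in expansion: ", paste(miss, collapse = ", "),
         call. = FALSE)
  terms
}
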