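#' Fit a weighted proportional hazards model with time-dependent covariates
#'
#' Maximizes the (weighted) partial likelihood over counting-process rows by
#' damped Newton-Raphson with step-halving.  Ties are handled by the Efron
#' approximation by default (Breslow optional).  Row weights are the product
#' of any `fg_wt` column already on the expansion (Fine-Gray IPCW) and the
#' optional `weights` argument (e.g. stabilized IPTW); coefficient estimates
#' are invariant to a positive rescaling of the weights.
#'
#' Columns that are degenerate over the risk experience (all 0 or all 1)
#' are dropped with a warning before fitting.  A monotone likelihood
#' (coefficient diverging, as under perfect separation) is reported as a
#' diagnostic error naming the term unless `on_separation = "warn"`.
#'
#' @param expansion A `risk_expansion` (optionally Fine-Gray extended).
#' @param terms Character vector of model columns; default all exposure and
#'   covariate columns.
#' @param weights Optional per-row weights (length nrow(expansion)).
#' @param ties `"efron"` (default) or `"breslow"`.
#' @param robust Compute a patient-clustered sandwich variance and use it
#'   for CIs and p-values.
#' @param control List: `max_iter` (100), `tol` (1e-8, on both the max
#'   coefficient update and the score max-norm), `max_halvings` (10),
#'   `beta_bound` (15, separation diagnostic threshold).
#' @param on_separation `"error"` or `"warn"`.
#' @return Object of class `td_hazard_fit`: coefficients, standard errors,
#'   hazard ratios with 95 percent CIs, 2-sided Wald p-values, log
#'   likelihood, AIC, convergence diagnostics.
#' @export
fit_td_hazard <- function(expansion, terms = NULL, weights = NULL,
                          ties = c("efron", "breslow"), robust = FALSE,
                          control = list(), on_separation = c("error", "warn")) {
  ties <- match.arg(ties)
  on_separation <- match.arg(on_separation)
  ctl <- utils::modifyList(list(max_iter = 100L, tol = 1e-8,
                                max_halvings = 10L, beta_bound = 15),
                           control)
  terms <- expansion_terms(expansion, terms)

  w <- if (is.null(weights)) rep(1, nrow(expansion)) else as.numeric(weights)
  if (length(w) != nrow(expansion))
    stop("weights must have one entry per expansion row", call. = FALSE)
  if ("fg_wt" %in% names(expansion)) w <- w * expansion$fg_wt
  if (any(w < 0)) stop("negative weights are not allowed", call. = FALSE)

  keep <- w > 0
  dat <- expansion[keep, , drop = FALSE]
  w <- w[keep]
  n_events <- sum(dat$event)
  if (n_events < 1L) stop("no primary events in the expansion", call. = FALSE)

  X <- as.matrix(dat[terms])
  storage.mode(X) <- "double"
  # degenerate-column screening over the risk experience
  rng <- apply(X, 2L, function(v) diff(range(v)))
  if (any(rng == 0)) {
    dropped <- terms[rng == 0]
    warning("dropping degenerate column(s): ",
            paste(dropped, collapse = ", "), call. = FALSE)
    terms <- terms[rng != 0]
    X <- X[, rng != 0, drop = FALSE]
  }
  if (ncol(X) == 0L)
    stop("no non-degenerate model terms remain", call. = FALSE)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    off <- terms[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    stop("design matrix is rank-deficient; offending term(s): ",
         paste(off, collapse = ", "), call. = FALSE)
  }

  tstart <- as.numeric(dat$start - 1L)  # risk on (start-1, stop]
  tstop <- as.numeric(dat$stop)
  event <- as.integer(dat$event)

  p <- ncol(X)
  beta <- rep(0, p)
  ev0 <- cox_eval_cpp(tstart, tstop, event, X, w, beta, ties == "efron", TRUE)
  loglik_null <- ev0$loglik
  ev <- ev0
  converged <- FALSE
  iter <- 0L
  repeat {
    iter <- iter + 1L
    step <- solve(ev$info, ev$score)
    lik_old <- ev$loglik
    halv <- 0L
    repeat {
      cand <- beta + step
      ev_new <- cox_eval_cpp(tstart, tstop, event, X, w, cand,
                             ties == "efron", TRUE)
      if (is.finite(ev_new$loglik) && ev_new$loglik >= lik_old - 1e-12) break
      halv <- halv + 1L
      if (halv > ctl$max_halvings) break
      step <- step / 2
    }
    if (halv > ctl$max_halvings) break
    delta <- max(abs(cand - beta))
    beta <- cand
    ev <- ev_new
    if (delta < ctl$tol || max(abs(ev$score)) < ctl$tol) {
      converged <- TRUE
      break
    }
    if (iter >= ctl$max_iter) break
  }

  big <- abs(beta) > ctl$beta_bound
  if (any(big)) {
    msg <- paste0("monotone likelihood (separation-like divergence) for term(s): ",
                  paste(terms[big], collapse = ", "))
    if (on_separation == "error") stop(msg, call. = FALSE)
    warning(msg, call. = FALSE)
  }

  vc_model <- solve(ev$info)
  se <- sqrt(diag(vc_model))
  vc_robust <- NULL
  if (robust) {
    resid <- cox_score_resid_cpp(tstart, tstop, event, X, w, beta,
                                 ties == "efron")
    U <- rowsum(resid, group = dat$patient_id)
    vc_robust <- vc_model %*% crossprod(U) %*% vc_model
    se <- sqrt(diag(vc_robust))
  }

  names(beta) <- names(se) <- terms
  z <- beta / se
  res <- list(coefficients = beta,
              se = se,
              hazard_ratio = exp(beta),
              ci_lower = exp(beta - qnorm(0.975) * se),
              ci_upper = exp(beta + qnorm(0.975) * se),
              p_value = 2 * pnorm(-abs(z)),
              loglik = ev$loglik,
              loglik_null = loglik_null,
              aic = -2 * ev$loglik + 2 * length(beta),
              n_events = n_events,
              n_rows = nrow(dat),
              converged = converged,
              n_iterations = iter,
              score_max = max(abs(ev$score)),
              ties = ties,
              robust = robust,
              vcov = if (robust) vc_robust else vc_model,
              terms = terms)
  class(res) <- "td_hazard_fit"
  res
}

#' @export
print.td_hazard_fit <- function(x, ...) {
  cat(sprintf("Time-dependent hazard fit (%s ties%s): %d events, loglik %.4f, AIC %.2f%s\n",
              x$ties, if (x$robust) ", robust SE" else "",
              x$n_events, x$loglik, x$aic,
              if (!x$converged) "  [NOT CONVERGED]" else ""))
  tab <- data.frame(coef = x$coefficients, HR = x$hazard_ratio,
                    lower95 = x$ci_lower, upper95 = x$ci_upper,
                    se = x$se, p = x$p_value)
  print(round(tab, 4))
  invisible(x)
}

#' @export
coef.td_hazard_fit <- function(object, ...) object$coefficients

#' @export
vcov.td_hazard_fit <- function(object, ...) object$vcov

#' @export
logLik.td_hazard_fit <- function(object, ...) {
  structure(object$loglik, df = length(object$coefficients),
            class = "logLik")
}

#' Serialize a fit to JSON
#'
#' @param fit A `td_hazard_fit`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_fit_json <- function(fit, path) {
  out <- list(terms = fit$terms,
              coefficients = unname(fit$coefficients),
              se = unname(fit$se),
              hazard_ratio = unname(fit$hazard_ratio),
              ci_lower = unname(fit$ci_lower),
              ci_upper = unname(fit$ci_upper),
              p_value = unname(fit$p_value),
              loglik = fit$loglik,
              aic = fit$aic,
              n_events = fit$n_events,
              convergence = list(converged = fit$converged,
                                 n_iterations = fit$n_iterations,
                                 score_max = fit$score_max,
                                 ties = fit$ties,
                                 robust = fit$robust))
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Variance inflation factors over counting-process rows
#'
#' VIF_j = 1 / (1 - R^2_j) from the ordinary least-squares regression of
#' term j on all other terms (with intercept) over the expansion rows.
#' Exact collinearity yields `Inf` for the offending terms.
#'
#' @param expansion A `risk_expansion`.
#' @param terms Model columns (>= 2); default all exposure and covariate
#'   columns.
#' @return Named numeric vector of VIFs.
#' @export
compute_vif <- function(expansion, terms = NULL) {
  terms <- expansion_terms(expansion, terms)
  if (length(terms) < 2L) stop("need >= 2 terms for VIF", call. = FALSE)
  X <- as.matrix(expansion[terms])
  if (nrow(X) <= ncol(X))
    stop("need more rows than terms for VIF", call. = FALSE)
  vif <- setNames(numeric(length(terms)), terms)
  for (j in seq_along(terms)) {
    y <- X[, j]
    Z <- cbind(1, X[, -j, drop = FALSE])
    fitted <- Z %*% qr.coef(qr(Z), y)
    fitted[is.na(fitted)] <- 0
    sst <- sum((y - mean(y))^2)
    sse <- sum((y - fitted)^2)
    if (sst == 0) {
      vif[j] <- NA_real_
    } else {
      r2 <- 1 - sse / sst
      vif[j] <- if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
    }
  }
  vif
}
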