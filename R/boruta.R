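#' Build the patient-level feature matrix for shadow-feature selection
#'
#' Rows are patients; columns are binary exposure indicators (exposed to
#' the class in the interval at all = 1) plus encoded nonantibiotic
#' covariates.  The outcome is 1 if the primary event occurred by
#' `horizon`.  Patients who died without the primary event before the
#' horizon are excluded (the selector is not competing-risk aware);
#' patients censored before the horizon are kept with outcome 0.
#'
#' @param design An `exposure_design`.
#' @param covariates Optional baseline covariate table.
#' @param outcomes Outcome records.
#' @param horizon Day horizon (default 180, must be > 0).
#' @return List with `X` (numeric matrix) and `y` (0/1 integer vector).
#' @export
build_feature_matrix <- function(design, covariates = NULL, outcomes,
                                 horizon = 180L) {
  if (horizon <= 0) stop("horizon must be > 0", call. = FALSE)
  outcomes <- validate_outcomes(outcomes)
  oc <- outcomes[match(design$patients, outcomes$patient_id), ]
  excl <- oc$event_type == "death" & oc$event_day < horizon
  keep <- which(!excl)
  if (!length(keep))
    stop("all patients excluded (competing event before horizon)",
         call. = FALSE)
  y <- as.integer(oc$event_type[keep] == "agvhd" &
                    oc$event_day[keep] <= horizon)
  X <- (!is.na(design$first_day[keep, , drop = FALSE])) * 1
  if (!is.null(covariates)) {
    mm <- baseline_model_matrix(covariates)
    X <- cbind(X, mm[match(design$patients[keep], rownames(mm)), ,
                     drop = FALSE])
  }
  list(X = X, y = y, patients = design$patients[keep],
       n_excluded = sum(excl))
}

#' Append shuffled shadow copies of every feature
#'
#' @param X Numeric feature matrix.
#' @return Matrix with `2p` columns: the originals followed by
#'   `shadow_<name>` columns, each an independent row permutation of its
#'   source (uses the current RNG stream).
#' @export
shadow_augment <- function(X) {
  if (!is.matrix(X) || nrow(X) == 0L)
    stop("X must be a non-empty matrix", call. = FALSE)
  sh <- apply(X, 2L, function(col) col[sample.int(length(col))])
  colnames(sh) <- paste0("shadow_", colnames(X))
  cbind(X, sh)
}

#' Out-of-bag permutation importance (mean decrease accuracy)
#'
#' Trains a random-forest classifier and returns, per column, the mean
#' over trees of the drop in out-of-bag accuracy when that column is
#' permuted within the tree's OOB sample (unscaled).
#'
#' @param X_aug Feature matrix (typically shadow-augmented).
#' @param y Binary outcome (both classes present).
#' @param ntree Number of trees (default 500).
#' @param mtry Variables tried per split; default `ceiling(sqrt(p))`.
#' @return Named numeric vector of importances.
#' @export
mean_decrease_accuracy <- function(X_aug, y, ntree = 500L, mtry = NULL) {
  y <- factor(y)
  if (nlevels(y) < 2L)
    stop("outcome has a single class; importance undefined", call. = FALSE)
  if (is.null(mtry)) mtry <- ceiling(sqrt(ncol(X_aug)))
  rf <- randomForest::randomForest(x = X_aug, y = y, ntree = ntree,
                                   mtry = mtry, importance = TRUE)
  imp <- randomForest::importance(rf, type = 1L, scale = FALSE)
  setNames(imp[, 1L], rownames(imp))
}

#' Shadow-feature (Boruta-style) selection
#'
#' Each iteration re-shuffles the shadow copies, fits a random forest on
#' the augmented matrix and awards a "hit" to every original feature whose
#' permutation importance exceeds the maximum over the shadow features.
#' After each iteration a two-sided binomial test (p = 0.5) with Bonferroni
#' correction across still-unresolved features classifies features as
#' `important` (significantly more hits than expected) or `unimportant`
#' (significantly fewer); decisions are frozen once made.  Features
#' unresolved after `n_iter` iterations are `tentative` and can be resolved
#' by [extend_boruta()], which continues the same RNG stream (so
#' `run(n1)` then `extend(n2)` reproduces `run(n1 + n2)`).
#'
#' @param X Feature matrix (patients x features).
#' @param y Binary outcome vector.
#' @param n_iter Number of iterations (>= 1; default 100).
#' @param alpha Test level (default 0.05).
#' @param ntree,mtry Random-forest settings, see
#'   [mean_decrease_accuracy()].
#' @param seed Integer seed for reproducibility.
#' @return Object of class `boruta_result`: per-feature decision, hit
#'   counts, z-scores, importance history, and resumable state.
#' @export
run_boruta <- function(X, y, n_iter = 100L, alpha = 0.05, ntree = 500L,
                       mtry = NULL, seed = 1L) {
  if (n_iter < 1L) stop("n_iter must be >= 1", call. = FALSE)
  set.seed(seed)
  state <- list(X = X, y = y, alpha = alpha, ntree = ntree, mtry = mtry,
                seed = seed,
                hits = setNames(integer(ncol(X)), colnames(X)),
                decision = setNames(rep("tentative", ncol(X)), colnames(X)),
                n_done = 0L,
                history = matrix(NA_real_, nrow = 0L, ncol = 2L * ncol(X)))
  boruta_iterate(state, n_iter)
}

#' Continue a shadow-feature run for additional iterations
#'
#' @param result A `boruta_result`.
#' @param n_more Additional iterations (>= 1).
#' @return Updated `boruta_result`.
#' @export
extend_boruta <- function(result, n_more) {
  if (n_more < 1L) stop("n_more must be >= 1", call. = FALSE)
  state <- result$state
  assign(".Random.seed", state$rng, envir = globalenv())
  boruta_iterate(state, n_more)
}

boruta_iterate <- function(state, n_iter) {
  p <- ncol(state$X)
  feat <- colnames(state$X)
  for (it in seq_len(n_iter)) {
    X_aug <- shadow_augment(state$X)
    imp <- mean_decrease_accuracy(X_aug, state$y, ntree = state$ntree,
                                  mtry = state$mtry)
    shadow_max <- max(imp[(p + 1L):(2L * p)])
    state$hits <- state$hits + as.integer(imp[seq_len(p)] > shadow_max)
    state$n_done <- state$n_done + 1L
    state$history <- rbind(state$history, unname(imp))
    unresolved <- which(state$decision == "tentative")
    if (length(unresolved)) {
      pv <- vapply(unresolved, function(j)
        binom.test(state$hits[j], state$n_done, p = 0.5)$p.value,
        numeric(1))
      rej <- pv * length(unresolved) < state$alpha  # Bonferroni
      newly <- unresolved[rej]
      state$decision[newly] <- ifelse(
        state$hits[newly] > state$n_done / 2, "important", "unimportant")
    }
  }
  colnames(state$history) <- c(feat, paste0("shadow_", feat))
  state$rng <- get(".Random.seed", envir = globalenv())
  z <- (state$hits - state$n_done / 2) / sqrt(state$n_done / 4)
  structure(list(decision = state$decision,
                 hit_count = state$hits,
                 n_completed_iterations = state$n_done,
                 z_scores = z,
                 importance_history = state$history,
                 alpha = state$alpha,
                 state = state),
            class = "boruta_result")
}

#' @export
print.boruta_result <- function(x, ...) {
  tab <- table(factor(x$decision,
                      levels = c("important", "tentative", "unimportant")))
  cat(sprintf("Shadow-feature selection: %d iterations, alpha %.3g\n",
              x$n_completed_iterations, x$alpha))
  cat(sprintf("  important: %d, tentative: %d, unimportant: %d\n",
              tab[1], tab[2], tab[3]))
  imp <- names(x$decision)[x$decision == "important"]
  if (length(imp)) {
    ord <- order(-x$hit_count[imp])
    cat("  important features:", paste(imp[ord], collapse = ", "), "\n")
  }
  invisible(x)
}

#' Serialize a shadow-feature selection result to JSON
#' @param result A `boruta_result`.
#' @param path Output path.
#' @param history Include the full importance history (default FALSE).
#' @return Invisibly, `path`.
#' @export
write_boruta_json <- function(result, path, history = FALSE) {
  out <- list(features = names(result$decision),
              decision = unname(result$decision),
              hit_count = unname(result$hit_count),
              n_completed_iterations = result$n_completed_iterations,
              z_scores = unname(result$z_scores),
              alpha = result$alpha)
  if (history) out$importance_history <- result$importance_history
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
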