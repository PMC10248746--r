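#' Read competing-risk outcome records
#'
#' Expected header: `patient_id,event_day,event_type` with `event_type` in
#' `{agvhd, death, censored}` — `agvhd` is the primary event, `death` is
#' death without prior aGVHD (the competing event).
#'
#' @param path File path.
#' @return Validated data.frame of outcome records.
#' @export
read_outcomes <- function(path) {
  validate_outcomes(read.csv(path, stringsAsFactors = FALSE))
}

validate_outcomes <- function(x) {
  need <- c("patient_id", "event_day", "event_type")
  if (!is.data.frame(x) || !all(need %in% names(x)))
    stop("outcomes must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  x$patient_id <- as.character(x$patient_id)
  x$event_day <- as.integer(x$event_day)
  bad <- setdiff(unique(x$event_type), c("agvhd", "death", "censored"))
  if (length(bad))
    stop("unknown event_type value(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  if (anyDuplicated(x$patient_id))
    stop("outcomes must have exactly one record per patient", call. = FALSE)
  x
}

#' Read per-patient baseline covariates
#'
#' Expected columns: `patient_id`, `graft_source`, `conditioning_intensity`,
#' `atg_use`, `donor_type`, `gvhd_prophylaxis`, `age`, `engrafted`
#' (TRUE/FALSE), `engraftment_day` (empty when not engrafted).
#'
#' @param path File path.
#' @return data.frame of baseline covariates.
#' @export
read_covariates <- function(path) {
  x <- read.csv(path, stringsAsFactors = FALSE)
  validate_covariates(x)
}

validate_covariates <- function(x) {
  need <- c("patient_id", "graft_source", "conditioning_intensity",
            "atg_use", "donor_type", "gvhd_prophylaxis", "age",
            "engrafted", "engraftment_day")
  miss <- setdiff(need, names(x))
  if (length(miss))
    stop("covariate table missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  x$patient_id <- as.character(x$patient_id)
  x$engrafted <- as.logical(x$engrafted)
  x$engraftment_day <- as.integer(x$engraftment_day)
  if (any(x$engrafted & is.na(x$engraftment_day)))
    stop("engrafted patients must have an engraftment_day", call. = FALSE)
  if (any(!x$engrafted & !is.na(x$engraftment_day)))
    stop("non-engrafted patients must not have an engraftment_day",
         call. = FALSE)
  x
}

#' Engraftment model terms with median imputation
#'
#' Returns the two neutrophil-engraftment terms: an indicator for not
#' engrafting and a continuous days-to-engraftment.  Non-engrafters are
#' assigned the median engraftment day among engrafters, so the indicator's
#' coefficient compares them to a hypothetical patient engrafting at the
#' median.
#'
#' @param covariates Validated covariate table.
#' @return data.frame with `patient_id`, `non_engrafted` (0/1),
#'   `days_to_engraftment`.
#' @export
engraftment_covariates <- function(covariates) {
  covariates <- validate_covariates(covariates)
  eng <- covariates$engrafted
  if (!any(eng))
    stop("no engrafted patients: median engraftment day is undefined",
         call. = FALSE)
  med <- median(covariates$engraftment_day[eng])
  data.frame(patient_id = covariates$patient_id,
             non_engrafted = as.integer(!eng),
             days_to_engraftment = ifelse(eng, covariates$engraftment_day,
                                          med),
             stringsAsFactors = FALSE)
}

# Baseline covariate model matrix: categorical main effects, the donor-type
# by prophylaxis interaction, age, and the two engraftment terms.  Returns
# a numeric matrix with one row per patient (rownames = patient_id).
baseline_model_matrix <- function(covariates) {
  covariates <- validate_covariates(covariates)
  eg <- engraftment_covariates(covariates)
  df <- data.frame(
    graft_source = factor(covariates$graft_source),
    conditioning_intensity = factor(covariates$conditioning_intensity),
    atg_use = factor(covariates$atg_use),
    donor_type = factor(covariates$donor_type),
    gvhd_prophylaxis = factor(covariates$gvhd_prophylaxis),
    age = as.numeric(covariates$age),
    non_engrafted = eg$non_engrafted,
    days_to_engraftment = eg$days_to_engraftment)
  # drop constant factors (single level) so model.matrix does not error
  keep <- vapply(df, function(v) !is.factor(v) || nlevels(v) > 1L,
                 logical(1))
  df <- df[keep]
  fterms <- names(df)
  if (all(c("donor_type", "gvhd_prophylaxis") %in% fterms))
    fterms <- c(fterms, "donor_type:gvhd_prophylaxis")
  mm <- model.matrix(as.formula(paste("~", paste(fterms, collapse = " + "))),
                     data = df)
  mm <- mm[, colnames(mm) != "(Intercept)", drop = FALSE]
  rownames(mm) <- covariates$patient_id
  mm
}
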