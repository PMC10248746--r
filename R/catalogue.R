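#' Default antibiotic class catalogue
#'
#' The 17 antibiotic classes used to code peritransplant exposures.
#' Third-or-higher-generation cephalosporins and penicillins each split into
#' two groups by the presence of a beta-lactamase inhibitor, and vancomycin
#' splits by route (IV vs oral), which is the only route distinction kept.
#'
#' @return Character vector of 17 unique class names.
#' @export
#' @examples
#' default_antibiotic_classes()
default_antibiotic_classes <- function() {
  c("aminoglycosides",
    "aztreonam",
    "carbapenems",
    "cephalosporins_gen1_2",
    "cephalosporins_gen3plus",
    "cephalosporins_gen3plus_bli",
    "dalfopristin_quinupristin",
    "fluoroquinolones",
    "linezolid",
    "macrolides",
    "penicillins",
    "penicillins_bli",
    "rifaximin",
    "tetracyclines",
    "tmp_smx",
    "vancomycin_iv",
    "vancomycin_oral")
}

#' Nonantibiotic model-variable slots
#'
#' Names of the nine nonantibiotic covariate slots carried alongside the
#' antibiotic design columns: five baseline transplant characteristics, the
#' donor-type-by-prophylaxis interaction, recipient age, and the two
#' neutrophil-engraftment terms (engraftment indicator plus median-imputed
#' days to engraftment).
#'
#' @return Character vector of 9 slot names.
#' @export
nonantibiotic_slots <- function() {
  c("graft_source", "conditioning_intensity", "atg_use",
    "donor_type", "gvhd_prophylaxis", "donor_type:gvhd_prophylaxis",
    "age", "non_engrafted", "days_to_engraftment")
}

validate_catalogue <- function(catalogue) {
  if (!is.character(catalogue) || length(catalogue) == 0L)
    stop("catalogue must be a non-empty character vector of class names",
         call. = FALSE)
  if (anyDuplicated(catalogue))
    stop("catalogue names must be unique; duplicated: ",
         paste(unique(catalogue[duplicated(catalogue)]), collapse = ", "),
         call. = FALSE)
  invisible(catalogue)
}
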