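#' Encode administration records as interval-coded time-dependent exposures
#'
#' Converts long person-day administration records into one binary
#' time-dependent covariate per (antibiotic class, interval) pair.  Under
#' the default `"persistent"` coding a column switches from 0 to 1 at the
#' first administration day of that class within that interval and stays 1
#' for the rest of follow-up, so each class-by-interval term carries its own
#' hazard ratio from first in-interval exposure onward.  The `"transient"`
#' variant keeps the indicator active only from first exposure through the
#' end of its interval.
#'
#' Records outside the scheme window are dropped (their count is kept in the
#' design and reported via a message); duplicate administrations of the same
#' class on the same day collapse to one record.
#'
#' @param records data.frame with columns `patient_id`, `day`, `abx_class`.
#' @param scheme An [build_interval_scheme()] result.
#' @param catalogue Character vector of valid class names; defaults to the
#'   17-class catalogue.
#' @param coding `"persistent"` (default) or `"transient"`.
#' @param patients Optional character vector fixing the patient universe
#'   (patients with no records then contribute all-zero paths).
#' @return An `exposure_design` object.
#' @export
encode_exposures <- function(records, scheme,
                             catalogue = default_antibiotic_classes(),
                             coding = c("persistent", "transient"),
                             patients = NULL) {
  coding <- match.arg(coding)
  validate_catalogue(catalogue)
  stopifnot(is.data.frame(records))
  need <- c("patient_id", "day", "abx_class")
  if (!all(need %in% names(records)))
    stop("records must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)

  records$patient_id <- as.character(records$patient_id)
  records$abx_class <- as.character(records$abx_class)
  records$day <- as.integer(records$day)

  bad <- setdiff(unique(records$abx_class), catalogue)
  if (length(bad))
    stop("unknown antibiotic class name(s): ", paste(bad, collapse = ", "),
         call. = FALSE)

  win <- scheme_window(scheme)
  inwin <- records$day >= win[1] & records$day <= win[2]
  n_dropped <- sum(!inwin)
  if (n_dropped > 0)
    message(sprintf("encode_exposures: dropped %d record(s) outside window [%d, %d]",
                    n_dropped, win[1], win[2]))
  records <- records[inwin, , drop = FALSE]
  records <- unique(records[need])

  if (is.null(patients)) {
    patients <- sort(unique(records$patient_id))
  } else {
    patients <- as.character(patients)
    extra <- setdiff(unique(records$patient_id), patients)
    if (length(extra))
      stop("records contain patients outside the supplied universe: ",
           paste(head(extra, 5L), collapse = ", "), call. = FALSE)
  }

  k <- nrow(scheme)
  columns <- data.frame(
    abx_class = rep(catalogue, each = k),
    start_idx = rep(seq_len(k), times = length(catalogue)),
    end_idx = rep(seq_len(k), times = length(catalogue)),
    stringsAsFactors = FALSE)
  columns$name <- column_name(columns$abx_class, columns$start_idx,
                              columns$end_idx)

  first_day <- matrix(NA_integer_, nrow = length(patients),
                      ncol = nrow(columns),
                      dimnames = list(patients, columns$name))
  if (nrow(records)) {
    records$interval <- interval_of_day(scheme, records$day)
    key <- paste(records$abx_class, records$interval, sep = "\r")
    colkey <- paste(columns$abx_class, columns$start_idx, sep = "\r")
    j <- match(key, colkey)
    i <- match(records$patient_id, patients)
    ord <- order(records$day, decreasing = TRUE)  # earliest day written last
    for (idx in ord) first_day[i[idx], j[idx]] <- records$day[idx]
  }

  new_exposure_design(patients, catalogue, scheme, coding, columns,
                      first_day, n_dropped)
}

column_name <- function(abx_class, start_idx, end_idx) {
  ifelse(start_idx == end_idx,
         paste0(abx_class, "__i", start_idx),
         paste0(abx_class, "__i", start_idx, "_", end_idx))
}

new_exposure_design <- function(patients, catalogue, scheme, coding,
                                columns, first_day, n_dropped = 0L) {
  structure(list(patients = patients, catalogue = catalogue,
                 scheme = scheme, coding = coding, columns = columns,
                 first_day = first_day, n_dropped = as.integer(n_dropped)),
            class = "exposure_design")
}

#' @export
print.exposure_design <- function(x, ...) {
  cat(sprintf(paste0("Exposure design: %d patients, %d classes x %d ",
                     "intervals -> %d columns (%s coding)\n"),
              length(x$patients), length(x$catalogue),
              n_intervals(x$scheme), nrow(x$columns), x$coding))
  nz <- sum(!is.na(x$first_day))
  cat(sprintf("  %d patient-column exposures observed; %d record(s) dropped out of window\n",
              nz, x$n_dropped))
  invisible(x)
}

#' Number of exposure columns in a design
#' @param design An `exposure_design`.
#' @return Integer count of (class, interval-span) columns.
#' @export
n_design_columns <- function(design) nrow(design$columns)

#' Exposure path values on a given day
#'
#' Evaluates every exposure column for every patient at `day`.  Persistent
#' coding: 1 from the column's first exposure day onward.  Transient coding:
#' 1 from first exposure day through the end of the column's interval span.
#'
#' @param design An `exposure_design`.
#' @param day Integer scalar day.
#' @return Integer matrix patients x columns of 0/1.
#' @export
exposure_path_at <- function(design, day) {
  fd <- design$first_day
  on <- !is.na(fd) & fd <= day
  if (design$coding == "transient") {
    span_end <- design$scheme$end[design$columns$end_idx]
    on <- on & rep(day <= span_end, each = nrow(fd))
  }
  storage.mode(on) <- "integer"
  on
}

#' Days on which any exposure column changes value for each patient
#'
#' @param design An `exposure_design`.
#' @return Named list (by patient) of sorted integer day vectors.
#' @export
exposure_switch_days <- function(design) {
  fd <- design$first_day
  out <- vector("list", nrow(fd))
  names(out) <- rownames(fd)
  span_end <- design$scheme$end[design$columns$end_idx]
  for (i in seq_len(nrow(fd))) {
    d <- fd[i, ]
    d <- d[!is.na(d)]
    days <- as.integer(d)
    if (design$coding == "transient" && length(d)) {
      off <- span_end[match(names(d), design$columns$name)] + 1L
      days <- c(days, off)
    }
    out[[i]] <- sort(unique(days))
  }
  out
}

#' Merge adjacent interval columns of one antibiotic class
#'
#' Replaces the columns of `abx_class` covering `interval_indices` by a
#' single column whose switch-on day is the earliest first exposure day
#' among them (per patient).  Indices must form a contiguous run and every
#' index must be covered by a current column of the class.
#'
#' @param design An `exposure_design`.
#' @param abx_class Class name.
#' @param interval_indices Integer vector of >= 2 contiguous interval
#'   indices (in terms of the original scheme intervals).
#' @return A new `exposure_design` with the merged column in place.
#' @export
merge_columns <- function(design, abx_class, interval_indices) {
  interval_indices <- sort(unique(as.integer(interval_indices)))
  if (length(interval_indices) < 2L)
    stop("need at least 2 interval indices to merge", call. = FALSE)
  if (any(diff(interval_indices) != 1L))
    stop("interval_indices must be contiguous", call. = FALSE)
  cols <- design$columns
  sel <- which(cols$abx_class == abx_class &
               cols$start_idx >= interval_indices[1] &
               cols$end_idx <= interval_indices[length(interval_indices)])
  covered <- unlist(lapply(sel, function(j) cols$start_idx[j]:cols$end_idx[j]))
  if (!setequal(covered, interval_indices) || length(sel) < 2L)
    stop(sprintf("intervals {%s} of class '%s' are not covered by >= 2 existing columns",
                 paste(interval_indices, collapse = ","), abx_class),
         call. = FALSE)

  merged_first <- suppressWarnings(
    apply(design$first_day[, sel, drop = FALSE], 1L,
          function(v) if (all(is.na(v))) NA_integer_ else min(v, na.rm = TRUE)))
  newcol <- data.frame(abx_class = abx_class,
                       start_idx = interval_indices[1],
                       end_idx = interval_indices[length(interval_indices)],
                       stringsAsFactors = FALSE)
  newcol$name <- column_name(newcol$abx_class, newcol$start_idx, newcol$end_idx)

  keep <- setdiff(seq_len(nrow(cols)), sel)
  insert_at <- min(sel)
  before <- keep[keep < insert_at]
  after <- keep[keep >= insert_at]
  columns <- rbind(cols[before, ], newcol, cols[after, ])
  rownames(columns) <- NULL
  first_day <- cbind(design$first_day[, before, drop = FALSE],
                     matrix(as.integer(merged_first), ncol = 1,
                            dimnames = list(design$patients, newcol$name)),
                     design$first_day[, after, drop = FALSE])
  new_exposure_design(design$patients, design$catalogue, design$scheme,
                      design$coding, columns, first_day, design$n_dropped)
}

drop_design_column <- function(design, name) {
  j <- match(name, design$columns$name)
  if (is.na(j)) stop("no such design column: ", name, call. = FALSE)
  new_exposure_design(design$patients, design$catalogue, design$scheme,
                      design$coding, design$columns[-j, , drop = FALSE],
                      design$first_day[, -j, drop = FALSE], design$n_dropped)
}

#' Read administration records from CSV
#'
#' Expected header: `patient_id,day,abx_class`, one row per
#' administration-day.
#'
#' @param path File path.
#' @return data.frame of exposure records.
#' @export
read_exposure_records <- function(path) {
  x <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("patient_id", "day", "abx_class")
  if (!all(need %in% names(x)))
    stop("exposure CSV must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  x$patient_id <- as.character(x$patient_id)
  x$day <- as.integer(x$day)
  x
}

#' Write a design as a wide person-day CSV plus a JSON sidecar
#'
#' One row per patient-day over the scheme window with the 0/1 value of
#' every exposure column; the sidecar records the scheme, catalogue and
#' coding so the design can be reconstructed.
#'
#' @param design An `exposure_design`.
#' @param csv_path,json_path Output paths.
#' @return Invisibly, the CSV path.
#' @export
write_design_csv <- function(design, csv_path, json_path = NULL) {
  win <- scheme_window(design$scheme)
  days <- win[1]:win[2]
  blocks <- lapply(days, function(d) {
    m <- exposure_path_at(design, d)
    data.frame(patient_id = design$patients, day = d, m,
               check.names = FALSE, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, blocks)
  out <- out[order(out$patient_id, out$day), , drop = FALSE]
  write.csv(out, csv_path, row.names = FALSE)
  if (!is.null(json_path)) {
    sidecar <- list(
      window = list(start = win[1], end = win[2]),
      intervals = design$scheme[c("interval", "start", "end")],
      catalogue = design$catalogue,
      coding = design$coding,
      columns = design$columns[c("name", "abx_class", "start_idx", "end_idx")])
    jsonlite::write_json(sidecar, json_path, auto_unbox = TRUE, digits = NA)
  }
  invisible(csv_path)
}

#' Recover long administration records from a design
#'
#' Emits one record per (patient, column) at the column's first exposure
#' day.  Re-encoding these records with the same scheme and catalogue
#' reproduces the design's paths exactly (for an unmerged design).
#'
#' @param design An `exposure_design`.
#' @return data.frame with `patient_id`, `day`, `abx_class`.
#' @export
design_to_records <- function(design) {
  fd <- design$first_day
  idx <- which(!is.na(fd), arr.ind = TRUE)
  data.frame(patient_id = rownames(fd)[idx[, 1]],
             day = as.integer(fd[idx]),
             abx_class = design$columns$abx_class[idx[, 2]],
             stringsAsFactors = FALSE)
}
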