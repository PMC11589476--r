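#' Columns of a patient-level trial dataset
#'
#' @keywords internal
#' @noRd
.cohort_columns <- c("patient_id", "site_id", "arm", "death60", "t_discharge",
                     "discharge_event", "died_in_hospital", "sofa",
                     "creatinine", "bmi", "aki")

#' Construct a patient-level trial dataset
#'
#' Wraps a data frame of one-row-per-participant trial records and checks the
#' structural invariants the downstream models rely on. Columns:
#' `patient_id` (identifier), `site_id` (randomisation site), `arm`
#' (1 = high protein, 0 = usual protein), `death60` (death within 60 days of
#' randomisation, may be `NA`), `t_discharge` (days in (0, 60]; time of
#' discharge alive, or of in-hospital death, or 60 for patients still in
#' hospital), `discharge_event` (discharged alive within 60 days),
#' `died_in_hospital`, `sofa` (baseline SOFA score, integer 0-24),
#' `creatinine` (highest serum creatinine in the 24 h before randomisation,
#' umol/L, may be `NA`), `bmi` (kg/m^2), `aki` (acute kidney injury, KDIGO
#' stage >= 1 at randomisation).
#'
#' @param records A data frame with the columns above.
#' @return An object of class `trial_dataset` (also a `data.frame`).
#' @export
trial_dataset <- function(records) {
  stopifnot(is.data.frame(records))
  records <- as.data.frame(records)
  missing_cols <- setdiff(.cohort_columns, names(records))
  if (length(missing_cols))
    stop("missing required columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  records <- records[.cohort_columns]
  records$site_id <- as.character(records$site_id)
  if (!all(records$arm %in% c(0L, 1L)))
    stop("'arm' must be 0 (usual protein) or 1 (high protein)", call. = FALSE)
  ok_death <- records$death60 %in% c(0L, 1L) | is.na(records$death60)
  if (!all(ok_death))
    stop("'death60' must be 0, 1 or missing", call. = FALSE)
  if (any(!is.finite(records$t_discharge)) ||
      any(records$t_discharge <= 0 | records$t_discharge > 60))
    stop("'t_discharge' must lie in (0, 60]", call. = FALSE)
  bad <- records$discharge_event == 1 & records$died_in_hospital == 1
  if (any(bad))
    stop("a participant discharged alive cannot have died in hospital",
         call. = FALSE)
  if (any(records$creatinine <= 0, na.rm = TRUE))
    stop("'creatinine' must be positive", call. = FALSE)
  if (any(records$bmi <= 0, na.rm = TRUE))
    stop("'bmi' must be positive", call. = FALSE)
  class(records) <- c("trial_dataset", "data.frame")
  records
}

#' @export
print.trial_dataset <- function(x, ...) {
  n <- nrow(x)
  cat(sprintf("<trial_dataset> %d participants, %d sites (%d high / %d usual protein)\n",
              n, length(unique(x$site_id)), sum(x$arm == 1), sum(x$arm == 0)))
  cat(sprintf("  deaths by day 60: %d (%d missing outcome); discharged alive: %d\n",
              sum(x$death60 == 1, na.rm = TRUE), sum(is.na(x$death60)),
              sum(x$discharge_event == 1)))
  cat(sprintf("  reference (largest) site: %s (n = %d)\n",
              reference_site(x), max(site_sizes(x))))
  invisible(x)
}

#' Site sizes and the reference site of a trial dataset
#'
#' `site_sizes` tabulates participants per site. `reference_site` returns the
#' largest site, which all conditional treatment effects are evaluated at;
#' ties are broken deterministically towards the lexicographically lowest
#' site label.
#'
#' @param ds A [trial_dataset()].
#' @return `site_sizes`: named integer vector; `reference_site`: a site label.
#' @export
site_sizes <- function(ds) {
  stopifnot(inherits(ds, "trial_dataset"))
  tab <- table(ds$site_id)
  out <- as.integer(tab)
  names(out) <- names(tab)
  out
}

#' @rdname site_sizes
#' @export
reference_site <- function(ds) {
  sizes <- site_sizes(ds)
  labs <- names(sizes)[sizes == max(sizes)]
  sort(labs)[1L]
}

#' Read and write patient-level trial CSV files
#'
#' The on-disk format is a UTF-8 CSV with a header row naming the eleven
#' cohort columns; empty cells denote missing values. Writing then reading a
#' dataset reproduces every value and missingness flag. Unknown columns are
#' dropped with a warning; a file without `site_id` or `arm` columns, or with
#' a non-binary `arm`, is rejected.
#'
#' @param path Path to a CSV file.
#' @param ds A [trial_dataset()].
#' @return `read_cohort_csv`: a [trial_dataset()]. `write_cohort_csv`: `path`,
#'   invisibly.
#' @export
read_cohort_csv <- function(path) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         na.strings = "", check.names = FALSE)
  extra <- setdiff(names(raw), .cohort_columns)
  if (length(extra)) {
    warning("ignoring unknown columns: ", paste(extra, collapse = ", "),
            call. = FALSE)
    raw <- raw[setdiff(names(raw), extra)]
  }
  for (col in c("site_id", "arm"))
    if (!col %in% names(raw))
      stop("mandatory column '", col, "' not found in ", path, call. = FALSE)
  missing_cols <- setdiff(.cohort_columns, names(raw))
  if (length(missing_cols))
    stop("missing required columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  for (col in c("arm", "death60", "discharge_event", "died_in_hospital",
                "sofa", "aki"))
    raw[[col]] <- as.integer(raw[[col]])
  for (col in c("t_discharge", "creatinine", "bmi"))
    raw[[col]] <- as.numeric(raw[[col]])
  raw$patient_id <- as.character(raw$patient_id)
  trial_dataset(raw)
}

#' @rdname read_cohort_csv
#' @export
write_cohort_csv <- function(ds, path) {
  stopifnot(inherits(ds, "trial_dataset"))
  utils::write.csv(as.data.frame(ds), path, row.names = FALSE, na = "",
                   quote = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}
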