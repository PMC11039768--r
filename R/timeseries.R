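#' ROI time series container
#'
#' One subject's extracted ROI signals: a numeric T x p matrix whose columns
#' follow the atlas ROI order.
#'
#' @param subject_id subject identifier.
#' @param data numeric matrix, T rows (time points) by p ROIs; column names
#'   must equal the atlas ROI names in order.
#' @param atlas a [network_atlas()].
#' @param tr_seconds repetition time in seconds (default 0.72).
#' @return An object of class `roi_timeseries`.
#' @export
roi_timeseries <- function(subject_id, data, atlas, tr_seconds = 0.72) {
  data <- as.matrix(data)
  if (!is.numeric(data)) stop("time-series matrix must be numeric")
  if (anyNA(data)) stop("time-series matrix contains missing values")
  p <- length(atlas$roi_names)
  if (ncol(data) != p)
    stop("expected ", p, " ROI columns, found ", ncol(data))
  if (!is.null(colnames(data)) && !identical(colnames(data), atlas$roi_names))
    stop("time-series columns must match atlas ROI order")
  if (nrow(data) < 2L * p + 1L)
    stop("need at least ", 2L * p + 1L, " time points for ", p, " ROIs; got ",
         nrow(data))
  if (!is.numeric(tr_seconds) || tr_seconds <= 0)
    stop("tr_seconds must be a positive number")
  colnames(data) <- atlas$roi_names
  structure(list(subject_id = as.character(subject_id), data = data,
                 tr_seconds = tr_seconds),
            class = "roi_timeseries")
}

#' @export
print.roi_timeseries <- function(x, ...) {
  cat("roi_timeseries '", x$subject_id, "': ", nrow(x$data), " x ",
      ncol(x$data), " (TR = ", x$tr_seconds, " s)\n", sep = "")
  invisible(x)
}

#' Read one subject's ROI time series from a delimited file
#'
#' The file must be headered CSV or TSV (auto-detected) with one column per
#' atlas ROI. Columns may appear in any order in the file; they are reordered
#' to the atlas order.
#'
#' @param path file path; the filename stem is used as the subject id.
#' @param atlas a [network_atlas()].
#' @param tr_seconds repetition time in seconds.
#' @return An [roi_timeseries()].
#' @export
read_roi_timeseries <- function(path, atlas, tr_seconds = 0.72) {
  df <- read_delimited(path)
  miss <- setdiff(atlas$roi_names, names(df))
  if (length(miss))
    stop("time-series file ", basename(path), " missing ROI column(s): ",
         paste(miss, collapse = ", "))
  extra <- setdiff(names(df), atlas$roi_names)
  if (length(extra))
    stop("time-series file ", basename(path), " has unexpected column(s): ",
         paste(extra, collapse = ", "))
  df <- df[atlas$roi_names]
  for (nm in names(df)) {
    if (!is.numeric(df[[nm]])) {
      bad <- which(is.na(suppressWarnings(as.numeric(df[[nm]]))))[1L]
      stop("non-numeric value in column '", nm, "' at data row ", bad)
    }
  }
  subject_id <- sub("\\.[^.]*$", "", basename(path))
  roi_timeseries(subject_id, as.matrix(df), atlas, tr_seconds)
}

#' Write one subject's ROI time series as CSV
#'
#' @param ts an [roi_timeseries()].
#' @param path output file path.
#' @export
write_roi_timeseries <- function(ts, path) {
  utils::write.csv(as.data.frame(ts$data), path, row.names = FALSE)
  invisible(path)
}

#' Read a per-subject outcomes/covariates table
#'
#' Expected columns: `subject_id`, `slips` (non-negative integer count of
#' cigarettes smoked during the cessation attempt), `craving_treatment`
#' (mean daily craving, 0-10), `cue_craving` (post- minus pre-scan desire to
#' smoke, may be negative), `age`, `sex` (0/1), `ftnd` (Fagerstrom score,
#' 0-10), `treatment` (0/1 arm code) and optionally `baseline_cpd`.
#' Missing outcome cells are allowed and flagged, not dropped.
#'
#' @param path file path (headered CSV/TSV).
#' @return A data.frame of class `outcome_table` with logical columns
#'   `missing_slips`, `missing_craving`, `missing_cue`.
#' @export
read_outcomes <- function(path) {
  df <- read_delimited(path)
  need <- c("subject_id", "slips", "craving_treatment", "cue_craving",
            "age", "sex", "ftnd", "treatment")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("outcomes file missing column(s): ", paste(miss, collapse = ", "))
  as_outcome_table(df)
}

#' Validate and flag an outcomes data.frame
#'
#' @param df data.frame with the columns documented in [read_outcomes()].
#' @return The validated `outcome_table`.
#' @export
as_outcome_table <- function(df) {
  df$subject_id <- as.character(df$subject_id)
  if (anyDuplicated(df$subject_id))
    stop("duplicate subject_id in outcomes table")
  slips <- df$slips
  ok <- is.na(slips) | (slips >= 0 & slips == round(slips))
  if (!all(ok))
    stop("slips must be non-negative integer counts; offending subject(s): ",
         paste(df$subject_id[!ok], collapse = ", "))
  for (v in c("sex", "treatment")) {
    if (!all(df[[v]] %in% c(0, 1, NA)))
      stop(v, " must be coded 0/1")
  }
  df$missing_slips <- is.na(df$slips)
  df$missing_craving <- is.na(df$craving_treatment)
  df$missing_cue <- is.na(df$cue_craving)
  class(df) <- c("outcome_table", "data.frame")
  df
}
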