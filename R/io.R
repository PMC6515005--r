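#' Read a paired ECG/PCG recording
#'
#' Two on-disk layouts are supported:
#' \describe{
#'   \item{`csv`}{one file with header columns `ecg` and `pcg` (or columns
#'     named by `ecg_col`/`pcg_col`); the sampling rate is not stored in the
#'     file and is taken from `fs`.}
#'   \item{`wfdb`}{a WFDB-style plain-text record: `<record>.hea` header
#'     (first line `name nsignals fs nsamples`, one line per signal with its
#'     data file and description) plus the referenced sample CSV. The
#'     sampling rate comes from the header.}
#' }
#'
#' Sampling rates other than 1000 Hz are accepted but every rule constant of
#' the method is defined at 1-ms resolution; resampling is never performed
#' silently.
#'
#' @param path file path (for `wfdb`, the header path or its prefix).
#' @param format `"csv"` or `"wfdb"`.
#' @param fs sampling rate in Hz for `csv` input.
#' @param ecg_col,pcg_col column names for `csv` input.
#' @return A [recording()].
#' @export
read_recording <- function(path, format = c("csv", "wfdb"), fs = 1000,
                           ecg_col = "ecg", pcg_col = "pcg") {
  format <- match.arg(format)
  if (format == "csv") {
    if (!file.exists(path)) stop("input file not found: ", path)
    df <- utils::read.csv(path)
    if (ncol(df) < 2L) stop("expected 2 channels, found ", ncol(df))
    if (!all(c(ecg_col, pcg_col) %in% names(df))) {
      stop("missing channel column(s): expected '", ecg_col, "' and '",
           pcg_col, "'")
    }
    if (is.null(fs) || !is.finite(fs)) stop("sampling rate unknown: supply fs")
    return(recording(df[[ecg_col]], df[[pcg_col]], fs = fs))
  }
  hea <- if (grepl("\\.hea$", path)) path else paste0(path, ".hea")
  if (!file.exists(hea)) stop("header file not found: ", hea)
  lines <- readLines(hea)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  top <- strsplit(trimws(lines[1]), "\\s+")[[1]]
  if (length(top) < 4L) stop("malformed header: ", hea)
  nsig <- as.integer(top[2]); fs_h <- as.numeric(top[3])
  if (!is.finite(fs_h) || fs_h <= 0) stop("sampling rate unknown in header")
  if (is.na(nsig) || nsig != 2L) stop("expected 2 signals, header declares ", top[2])
  sig <- strsplit(trimws(lines[2:3]), "\\s+")
  datafile <- sig[[1]][1]
  roles <- vapply(sig, function(s) s[length(s)], character(1))
  df <- utils::read.csv(file.path(dirname(hea), datafile))
  if (!all(roles %in% names(df))) {
    stop("data file misses declared signal(s): ",
         paste(setdiff(roles, names(df)), collapse = ", "))
  }
  ecg_role <- roles[grepl("ecg", tolower(roles))]
  pcg_role <- roles[grepl("pcg", tolower(roles))]
  if (length(ecg_role) != 1L || length(pcg_role) != 1L) {
    stop("cannot resolve channel roles from header descriptions: ",
         paste(roles, collapse = ", "))
  }
  recording(df[[ecg_role]], df[[pcg_role]], fs = fs_h)
}

#' Write a recording to CSV or a WFDB-style text record
#'
#' Samples are written with full double precision so a write-read round trip
#' reproduces them exactly.
#'
#' @param rec a [recording()].
#' @param path output path; for `wfdb` the record prefix (writes
#'   `<path>.hea` and `<path>.csv`).
#' @param format `"csv"` or `"wfdb"`.
#' @return The main file written, invisibly.
#' @export
write_recording <- function(rec, path, format = c("csv", "wfdb")) {
  stopifnot(inherits(rec, "pcg_recording"))
  format <- match.arg(format)
  fmt_num <- function(v) sprintf("%.17g", v)
  if (format == "csv") {
    df <- data.frame(ecg = fmt_num(rec$ecg), pcg = fmt_num(rec$pcg))
    utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
    return(invisible(path))
  }
  prefix <- sub("\\.hea$", "", path)
  name <- basename(prefix)
  datafile <- paste0(name, ".csv")
  hea <- paste0(prefix, ".hea")
  writeLines(c(sprintf("%s 2 %.10g %d", name, rec$fs, length(rec$ecg)),
               sprintf("%s 16 1 0 0 ecg", datafile),
               sprintf("%s 16 1 0 0 pcg", datafile)),
             hea)
  df <- data.frame(ecg = fmt_num(rec$ecg), pcg = fmt_num(rec$pcg))
  utils::write.csv(df, file.path(dirname(hea), datafile),
                   row.names = FALSE, quote = FALSE)
  invisible(hea)
}

#' Export classified heart sounds as CSV
#'
#' One row per sound with all boundaries in ms at the record's resolution:
#' `ref_rpeak_ms`, `label`, `c1_ms`, `c2_ms`, `split_ms`, `start_ms`,
#' `end_ms`, `degenerate`.
#'
#' @param fit an `hs_segmentation` (or a `heart_sounds` table plus `fs`).
#' @param path output CSV path.
#' @param fs sampling rate when `fit` is a bare `heart_sounds` table.
#' @return `path`, invisibly.
#' @export
write_sounds_csv <- function(fit, path, fs = NULL) {
  if (inherits(fit, "hs_segmentation")) {
    s <- fit$sounds; fs <- fit$recording$fs
  } else {
    s <- fit
    if (is.null(fs)) stop("fs required for a bare heart_sounds table")
  }
  df <- data.frame(beat = s$beat,
                   ref_rpeak_ms = round(samples_to_ms(s$ref_rpeak, fs), 1),
                   label = s$label,
                   c1_ms = round(samples_to_ms(s$c1, fs), 1),
                   c2_ms = round(samples_to_ms(s$c2, fs), 1),
                   split_ms = round(samples_to_ms(s$split, fs), 1),
                   start_ms = round(samples_to_ms(s$start, fs), 1),
                   end_ms = round(samples_to_ms(s$end, fs), 1),
                   degenerate = s$degenerate)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read a heart-sounds CSV back into a `heart_sounds` table
#' @param path CSV written by [write_sounds_csv()].
#' @param fs sampling rate used to convert ms back to sample indices.
#' @return A `heart_sounds` data frame.
#' @export
read_sounds_csv <- function(path, fs = 1000) {
  df <- utils::read.csv(path)
  out <- data.frame(ref_rpeak = as.integer(round(ms_to_samples(df$ref_rpeak_ms, fs))),
                    beat = as.integer(df$beat),
                    label = as.character(df$label),
                    c1 = as.integer(round(ms_to_samples(df$c1_ms, fs))),
                    c2 = as.integer(round(ms_to_samples(df$c2_ms, fs))),
                    split = as.integer(round(ms_to_samples(df$split_ms, fs))),
                    start = as.integer(round(ms_to_samples(df$start_ms, fs))),
                    end = as.integer(round(ms_to_samples(df$end_ms, fs))),
                    degenerate = as.logical(df$degenerate),
                    env_c1 = NA_real_,
                    component_1 = ifelse(df$label == "S1", "mitral", "aortic"),
                    component_2 = ifelse(df$label == "S1", "tricuspid", "pulmonary"),
                    stringsAsFactors = FALSE)
  structure(out, class = c("heart_sounds", "data.frame"))
}

#' Serialize a timing summary as JSON and CSV
#' @param ts a `timing_summary` from [summarize_timings()].
#' @param json_path,csv_path output paths (either may be `NULL`).
#' @return Invisibly, the paths written.
#' @export
write_timing_summary <- function(ts, json_path = NULL, csv_path = NULL) {
  stopifnot(inherits(ts, "timing_summary"))
  df <- as.data.frame(ts)
  if (!is.null(csv_path)) utils::write.csv(df, csv_path, row.names = FALSE)
  if (!is.null(json_path)) {
    jsonlite::write_json(df, json_path, dataframe = "rows", digits = NA,
                         na = "null", auto_unbox = TRUE, pretty = TRUE)
  }
  invisible(c(json_path, csv_path))
}

#' Serialize a validation report as JSON
#' @param vr a `validation_report` from [detection_scores()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_validation_json <- function(vr, path) {
  stopifnot(inherits(vr, "validation_report"))
  jsonlite::write_json(unclass(vr), path, auto_unbox = TRUE, digits = NA,
                       na = "null", pretty = TRUE)
  invisible(path)
}

#' Write/read synthetic ground truth as JSON
#' @param truth a `ground_truth` from [generate_recording()].
#' @param path JSON path.
#' @return `path` invisibly for write; a `ground_truth` for read.
#' @export
write_truth_json <- function(truth, path) {
  stopifnot(inherits(truth, "ground_truth"))
  jsonlite::write_json(unclass(truth), path, dataframe = "columns",
                       digits = NA, auto_unbox = FALSE, pretty = TRUE)
  invisible(path)
}

#' @rdname write_truth_json
#' @export
read_truth_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(true_rpeaks = as.integer(x$true_rpeaks),
                 components = as.data.frame(x$components),
                 pvc_beats = as.integer(x$pvc_beats)),
            class = "ground_truth")
}
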