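# Delimited-text time-series I/O and (stub) dataset adapters.
#
# Native dialect: a header line "# fs=<value>", then one
# whitespace-delimited row per sample, one column per channel. An
# optional second header line "# labels=a,b,c" carries channel names.

#' Read a time series from disk
#'
#' @param path input file.
#' @param format `"delimited"` is the native dialect. `"eeglab_set"`
#'   and `"matlab_mat"` name adapters for common acquisition formats;
#'   reading those binary containers needs a MAT-file reader that is
#'   not bundled, so they error with instructions to convert to the
#'   delimited dialect first.
#' @return A `time_series`.
#' @export
read_timeseries <- function(path,
                            format = c("delimited", "eeglab_set",
                                       "matlab_mat")) {
  format <- match.arg(format)
  if (format != "delimited")
    stop(sprintf(paste0("format '%s' requires an external MAT-file reader; ",
                        "export the recording (and its sampling rate) to the ",
                        "delimited dialect ('# fs=<Hz>' header + one column ",
                        "per channel) and use format = \"delimited\""),
         format))
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, n = 2L)
  m <- regmatches(lines[1], regexec("^#\\s*fs\\s*=\\s*([0-9.eE+-]+)", lines[1]))[[1]]
  if (length(m) < 2)
    stop("missing sampling-rate header: first line must be '# fs=<value>'")
  fs <- as.numeric(m[2])
  if (!is.finite(fs) || fs <= 0) stop("invalid sampling rate in header")
  labels <- NULL
  skip <- 1L
  if (length(lines) > 1 && grepl("^#\\s*labels\\s*=", lines[2])) {
    labels <- strsplit(sub("^#\\s*labels\\s*=\\s*", "", lines[2]), ",")[[1]]
    skip <- 2L
  }
  dat <- utils::read.table(path, skip = skip, header = FALSE,
                           colClasses = "numeric")
  time_series(as.matrix(dat), fs, labels = labels)
}

#' Write a time series in the delimited dialect
#'
#' @param x a `time_series`.
#' @param path output file.
#' @param digits significant digits to print (default 17 round-trips
#'   doubles exactly).
#' @export
write_timeseries <- function(x, path, digits = 17) {
  stopifnot(is_time_series(x))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# fs=%.17g", x$fs), con)
  if (!is.null(x$labels))
    writeLines(paste0("# labels=", paste(x$labels, collapse = ",")), con)
  utils::write.table(format(x$samples, digits = digits, scientific = TRUE,
                            trim = TRUE),
                     con, sep = " ", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write a simulated cohort to a directory
#'
#' One delimited file per subject plus a `manifest.csv`
#' (`subject_id`, `seed`, `file`).
#'
#' @param specs a single sim spec applied to all subjects.
#' @param seeds integer seed per subject.
#' @param out_dir output directory (created if missing).
#' @param generator `generate_eeg_like` or `generate_imu_like`.
#' @return Invisibly, the manifest data frame.
#' @export
write_cohort <- function(specs, seeds, out_dir,
                         generator = generate_eeg_like) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  rows <- lapply(seq_along(seeds), function(i) {
    id <- sprintf("subject%03d", i)
    f <- file.path(out_dir, paste0(id, ".txt"))
    write_timeseries(generator(specs, seeds[i]), f, digits = 8)
    data.frame(subject_id = id, seed = seeds[i], file = basename(f))
  })
  manifest <- do.call(rbind, rows)
  utils::write.csv(manifest, file.path(out_dir, "manifest.csv"),
                   row.names = FALSE, quote = FALSE)
  invisible(manifest)
}
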