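# End-to-end benchmark: generate (or load) subjects, grand-average,
# apply the four filters, compute spectral outcomes, run the
# repeated-measures statistics, and write tables.

#' Benchmark configuration
#'
#' @param modality `"eeg"` (512 Hz, band 0.5-50 Hz) or `"imu"`
#'   (128 Hz, band 0.5-5 Hz); defaults follow the modality.
#' @param n_subjects number of simulated subjects (`>= 2`).
#' @param seed master seed; per-subject seeds are derived from it by a
#'   fixed counter scheme so earlier subjects are stable when more are
#'   added.
#' @param band analysis/filter pass band; `NULL` picks the modality
#'   default.
#' @param filters subset of
#'   `c("reza", "butterworth", "chebyshev1", "elliptic")`.
#' @param mode `"zero_phase"` (default; all reported statistics use
#'   forward-backward application) or `"causal"` for the classical
#'   filters. The exponential filter is zero-phase by construction.
#' @param snr_mode which SNR outcome(s) to record: band-ratio,
#'   residual, or both.
#' @param welch a [welch_spec()].
#' @param duration_s record length per subject; `NULL` picks 32 s (EEG)
#'   or 64 s (IMU).
#' @param sim_spec override the full simulation spec (must match the
#'   modality's generator); `NULL` builds one from the modality
#'   defaults.
#' @param reza a [reza_params()].
#' @return An object of class `benchmark_config`.
#' @export
benchmark_config <- function(modality = c("imu", "eeg"), n_subjects = 20,
                             seed = 1L, band = NULL,
                             filters = c("reza", "butterworth",
                                         "chebyshev1", "elliptic"),
                             mode = c("zero_phase", "causal"),
                             snr_mode = c("both", "band_ratio", "residual"),
                             welch = welch_spec(), duration_s = NULL,
                             sim_spec = NULL, reza = reza_params()) {
  modality <- match.arg(modality)
  mode <- match.arg(mode)
  snr_mode <- match.arg(snr_mode)
  filters <- match.arg(filters, several.ok = TRUE)
  if (n_subjects < 2) stop("`n_subjects` must be >= 2")
  if (is.null(band))
    band <- if (modality == "eeg") band_spec(0.5, 50) else band_spec(0.5, 5)
  if (is.null(duration_s))
    duration_s <- if (modality == "eeg") 32 else 64
  if (is.null(sim_spec))
    sim_spec <- if (modality == "eeg") eeg_sim_spec(duration_s = duration_s)
                else imu_sim_spec(duration_s = duration_s)
  fs <- sim_spec$fs
  check_band_vs_fs(band, fs)
  structure(list(modality = modality, n_subjects = as.integer(n_subjects),
                 seed = as.integer(seed), band = band, filters = filters,
                 mode = mode, snr_mode = snr_mode, welch = welch,
                 duration_s = duration_s, sim_spec = sim_spec, reza = reza),
            class = "benchmark_config")
}

# fixed counter scheme for per-subject seeds (kept below 2^31)
subject_seed <- function(master_seed, i) {
  (as.numeric(master_seed) * 1000 + i * 7919) %% 2147483647
}

# the classical comparator designs in the benchmark's configurations:
# Rp 0.5 dB for EEG Chebyshev, 1 dB for IMU Chebyshev and all elliptic,
# Rs 40 dB for elliptic
benchmark_designs <- function(config) {
  fs <- config$sim_spec$fs
  band <- config$band
  rp_cheb <- if (config$modality == "eeg") 0.5 else 1
  designs <- list()
  if ("butterworth" %in% config$filters)
    designs$butterworth <-
      design_iir(iir_design_spec("butterworth", 4, band, fs))
  if ("chebyshev1" %in% config$filters)
    designs$chebyshev1 <-
      design_iir(iir_design_spec("chebyshev1", 4, band, fs, rp_db = rp_cheb))
  if ("elliptic" %in% config$filters)
    designs$elliptic <-
      design_iir(iir_design_spec("elliptic", 4, band, fs, rp_db = 1,
                                 rs_db = 40))
  designs
}

apply_benchmark_filter <- function(name, designs, trace, config) {
  if (name == "reza") return(reza_filter(trace, config$band, config$reza))
  filt <- designs[[name]]
  if (config$mode == "zero_phase") apply_zero_phase(filt, trace)
  else apply_causal(filt, trace)
}

#' Run the filter benchmark
#'
#' For each subject: simulate a recording, grand-average it, apply each
#' requested filter, estimate the Welch PSD of the filtered trace, and
#' record band power plus SNR outcome(s). Each outcome's subject x
#' filter table is then analyzed with [rm_anova()] and
#' [bonferroni_posthoc()]. The whole report is a pure function of the
#' configuration.
#'
#' @param config a [benchmark_config()].
#' @param progress print per-subject progress to stderr.
#' @return An object of class `benchmark_report`: `metrics` (named list
#'   of [metrics_table()]s), `anova`, `posthoc` (parallel named lists),
#'   and `provenance`.
#' @export
run_benchmark <- function(config, progress = FALSE) {
  stopifnot(inherits(config, "benchmark_config"))
  generator <- if (config$modality == "eeg") generate_eeg_like
               else generate_imu_like
  designs <- benchmark_designs(config)
  outcomes <- c("band_power",
                if (config$snr_mode %in% c("both", "band_ratio")) "snr_band",
                if (config$snr_mode %in% c("both", "residual")) "snr_residual")
  rows <- list()
  failed <- character(0)
  for (i in seq_len(config$n_subjects)) {
    sid <- sprintf("subject%03d", i)
    res <- tryCatch({
      x <- generator(config$sim_spec, subject_seed(config$seed, i))
      trace <- grand_average(x)
      sub_rows <- list()
      for (fname in config$filters) {
        y <- apply_benchmark_filter(fname, designs, trace, config)
        psd <- welch_psd(y, config$welch)
        vals <- c(band_power = band_power(psd, config$band),
                  snr_band = suppressWarnings(band_snr(psd, config$band)),
                  snr_residual = suppressWarnings(residual_snr(trace, y)))
        for (oc in outcomes)
          sub_rows[[length(sub_rows) + 1L]] <-
            data.frame(subject_id = sid, filter_name = fname,
                       outcome = oc, value = unname(vals[oc]))
      }
      do.call(rbind, sub_rows)
    }, error = function(e) {
      message(sprintf("subject %s failed and is excluded: %s", sid,
                      conditionMessage(e)))
      NULL
    })
    if (is.null(res)) failed <- c(failed, sid) else
      rows[[length(rows) + 1L]] <- res
    if (progress) message(sprintf("  %s done", sid))
  }
  if (length(rows) < 2) stop("fewer than 2 subjects survived the pipeline")
  long <- do.call(rbind, rows)
  metrics <- anova <- posthoc <- list()
  for (oc in outcomes) {
    sub <- long[long$outcome == oc, ]
    tbl <- metrics_table(sub$subject_id, sub$filter_name, sub$value)
    metrics[[oc]] <- tbl
    if (length(config$filters) >= 2) {
      anova[[oc]] <- rm_anova(tbl)
      posthoc[[oc]] <- bonferroni_posthoc(tbl)
    }
  }
  structure(list(metrics = metrics, anova = anova, posthoc = posthoc,
                 provenance = list(config = config,
                                   excluded_subjects = failed,
                                   package_version =
                                     as.character(utils::packageVersion("rezabench")))),
            class = "benchmark_report")
}

#' @export
print.benchmark_report <- function(x, ...) {
  cfg <- x$provenance$config
  cat(sprintf("<benchmark_report> %s, %d subjects, filters: %s\n",
              cfg$modality, cfg$n_subjects,
              paste(cfg$filters, collapse = ", ")))
  for (oc in names(x$anova)) {
    cat(sprintf("  %-13s ", oc)); print(x$anova[[oc]])
  }
  invisible(x)
}

#' Write a benchmark report as delimited tables
#'
#' Emits `metrics.csv` (subject, filter, outcome, value), `anova.csv`,
#' `posthoc.csv` and a `config.json` provenance file; byte-stable given
#' an identical report.
#'
#' @param report a `benchmark_report`.
#' @param out_dir output directory (created if missing).
#' @return Invisibly, the paths written.
#' @export
write_report <- function(report, out_dir) {
  stopifnot(inherits(report, "benchmark_report"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  long <- do.call(rbind, lapply(names(report$metrics), function(oc) {
    df <- as.data.frame(report$metrics[[oc]])
    df$outcome <- oc
    df[, c("subject_id", "filter_name", "outcome", "value")]
  }))
  long <- long[order(long$subject_id, long$outcome, long$filter_name), ]
  p_metrics <- file.path(out_dir, "metrics.csv")
  utils::write.csv(format(long, digits = 17, trim = TRUE), p_metrics,
                   row.names = FALSE, quote = FALSE)
  an <- do.call(rbind, lapply(names(report$anova), function(oc) {
    a <- report$anova[[oc]]
    data.frame(outcome = oc, F = a$F, df1 = a$df1, df2 = a$df2, p = a$p,
               eta_p2 = a$eta_p2, ss_effect = a$ss_effect,
               ss_error = a$ss_error, ss_subject = a$ss_subject, n = a$n,
               k = a$k)
  }))
  p_anova <- file.path(out_dir, "anova.csv")
  utils::write.csv(an, p_anova, row.names = FALSE, quote = FALSE)
  ph <- do.call(rbind, lapply(names(report$posthoc), function(oc) {
    d <- as.data.frame(report$posthoc[[oc]])
    if (nrow(d)) d$outcome <- oc
    d
  }))
  p_posthoc <- file.path(out_dir, "posthoc.csv")
  if (is.null(ph) || !nrow(ph)) {
    writeLines("filter_a,filter_b,mean_diff,t,df,p,significant,outcome",
               p_posthoc)
  } else {
    utils::write.csv(ph, p_posthoc, row.names = FALSE, quote = FALSE)
  }
  cfg <- report$provenance$config
  prov <- list(modality = cfg$modality, n_subjects = cfg$n_subjects,
               seed = cfg$seed,
               band = c(cfg$band$f_lo, cfg$band$f_hi),
               filters = cfg$filters, mode = cfg$mode,
               snr_mode = cfg$snr_mode,
               welch = unclass(cfg$welch),
               duration_s = cfg$duration_s,
               excluded_subjects = report$provenance$excluded_subjects,
               package_version = report$provenance$package_version)
  p_cfg <- file.path(out_dir, "config.json")
  jsonlite::write_json(prov, p_cfg, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(c(p_metrics, p_anova, p_posthoc, p_cfg))
}

#' Read a metrics.csv back into per-outcome tables
#'
#' @param path a `metrics.csv` written by [write_report()].
#' @return Named list of [metrics_table()]s.
#' @export
read_metrics <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  out <- list()
  for (oc in unique(df$outcome)) {
    sub <- df[df$outcome == oc, ]
    out[[oc]] <- metrics_table(sub$subject_id, sub$filter_name,
                               as.numeric(sub$value))
  }
  out
}
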