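# One-way repeated-measures ANOVA across filter conditions, with
# partial eta-squared and Bonferroni-corrected paired post-hocs.

#' Subject x condition outcome table
#'
#' Long-format records of one outcome value per (subject, condition)
#' cell. Subjects missing any condition are dropped (complete-case
#' analysis) with a message.
#'
#' @param subject_id vector of subject identifiers.
#' @param filter_name vector of condition labels (the filter applied).
#' @param value numeric outcome values.
#' @return An object of class `metrics_table`: a data frame with
#'   columns `subject_id`, `filter_name`, `value`, complete cases only.
#' @export
metrics_table <- function(subject_id, filter_name, value) {
  df <- data.frame(subject_id = as.character(subject_id),
                   filter_name = as.character(filter_name),
                   value = as.numeric(value),
                   stringsAsFactors = FALSE)
  if (anyDuplicated(df[, c("subject_id", "filter_name")]))
    stop("duplicate (subject, condition) cells")
  levels_k <- unique(df$filter_name)
  counts <- table(df$subject_id)
  complete <- names(counts)[counts == length(levels_k)]
  dropped <- setdiff(unique(df$subject_id), complete)
  if (length(dropped))
    message(sprintf("dropping %d incomplete subject(s): %s",
                    length(dropped), paste(dropped, collapse = ", ")))
  df <- df[df$subject_id %in% complete, ]
  structure(df, class = c("metrics_table", "data.frame"))
}

# wide subject x condition matrix
mt_wide <- function(table) {
  subj <- unique(table$subject_id)
  cond <- unique(table$filter_name)
  m <- matrix(NA_real_, length(subj), length(cond),
              dimnames = list(subj, cond))
  m[cbind(match(table$subject_id, subj), match(table$filter_name, cond))] <-
    table$value
  m
}

#' One-way repeated-measures ANOVA
#'
#' Two-way additive decomposition without interaction:
#' `SS_total = SS_subject + SS_effect + SS_error`, with the condition
#' effect tested on `(k - 1, (k - 1)(n - 1))` degrees of freedom. No
#' sphericity correction is applied by default (set
#' `gg_correct = TRUE` for Greenhouse-Geisser-adjusted df and p).
#'
#' @param table a [metrics_table()] (or data frame with the same
#'   columns).
#' @param gg_correct apply the Greenhouse-Geisser epsilon to the df and
#'   p-value (the F statistic is unchanged).
#' @return An object of class `rm_anova_result`: `F`, `df1`, `df2`,
#'   `p`, `eta_p2`, `ss_effect`, `ss_error`, `ss_subject`, `n`, `k`
#'   (and `epsilon` when corrected).
#' @examples
#' tbl <- metrics_table(rep(c("A", "B", "C"), each = 2),
#'                      rep(c("f1", "f2"), 3), c(1, 2, 2, 3, 3, 5))
#' rm_anova(tbl)$F   # 16, the squared paired t of 4
#' @export
rm_anova <- function(table, gg_correct = FALSE) {
  if (!inherits(table, "metrics_table"))
    table <- metrics_table(table$subject_id, table$filter_name, table$value)
  m <- mt_wide(table)
  n <- nrow(m); k <- ncol(m)
  if (n < 2) stop("need at least 2 complete subjects")
  if (k < 2) stop("need at least 2 conditions")
  grand <- mean(m)
  ss_subject <- k * sum((rowMeans(m) - grand)^2)
  ss_effect <- n * sum((colMeans(m) - grand)^2)
  ss_total <- sum((m - grand)^2)
  ss_error <- max(ss_total - ss_subject - ss_effect, 0)
  df1 <- k - 1
  df2 <- (k - 1) * (n - 1)
  ms_error <- ss_error / df2
  F <- if (ms_error <= 0) {
    if (ss_effect <= 0) 0 else Inf
  } else (ss_effect / df1) / ms_error
  eta_p2 <- if (ss_effect == 0 && ss_error == 0) 0 else
    partial_eta_squared(ss_effect, ss_error)
  res <- list(F = F, df1 = df1, df2 = df2,
              p = if (is.infinite(F)) 0 else
                stats::pf(F, df1, df2, lower.tail = FALSE),
              eta_p2 = eta_p2, ss_effect = ss_effect, ss_error = ss_error,
              ss_subject = ss_subject, n = n, k = k)
  if (gg_correct) {
    eps <- gg_epsilon(m)
    res$epsilon <- eps
    res$df1 <- df1 * eps
    res$df2 <- df2 * eps
    res$p <- if (is.infinite(F)) 0 else
      stats::pf(F, res$df1, res$df2, lower.tail = FALSE)
  }
  structure(res, class = "rm_anova_result")
}

# Greenhouse-Geisser epsilon from the double-centered covariance
gg_epsilon <- function(m) {
  S <- stats::cov(m)
  k <- ncol(S)
  Sc <- S - outer(rowMeans(S), rep(1, k)) -
    outer(rep(1, k), colMeans(S)) + mean(S)
  sum(diag(Sc))^2 / ((k - 1) * sum(Sc^2))
}

#' @export
print.rm_anova_result <- function(x, ...) {
  cat(sprintf("RM-ANOVA: F(%g, %g) = %.4g, p = %.4g, partial eta^2 = %.4f (n = %d, k = %d)\n",
              x$df1, x$df2, x$F, x$p, x$eta_p2, x$n, x$k))
  invisible(x)
}

#' Partial eta-squared effect size
#'
#' `ss_effect / (ss_effect + ss_error)`: the proportion of
#' within-subject variance attributable to the condition factor.
#' Algebraically `F * df1 / (F * df1 + df2)`.
#'
#' @param ss_effect,ss_error sums of squares, `>= 0`, not both zero.
#' @return Value in `[0, 1]`.
#' @export
partial_eta_squared <- function(ss_effect, ss_error) {
  if (ss_effect < 0 || ss_error < 0) stop("sums of squares must be >= 0")
  if (ss_effect == 0 && ss_error == 0)
    stop("effect size undefined: both sums of squares are zero")
  ss_effect / (ss_effect + ss_error)
}

#' Bonferroni-corrected paired post-hoc comparisons
#'
#' Two-sided paired t-test for every unordered pair of conditions; each
#' raw p-value is compared against `alpha_fw / (k * (k - 1) / 2)`. For
#' four conditions at familywise 0.05 the adjusted alpha is 0.05 / 6 =
#' 0.0083.
#'
#' @param table a [metrics_table()].
#' @param alpha_fw familywise error level (default 0.05).
#' @return A data frame of class `pairwise_results` with one row per
#'   pair: `filter_a`, `filter_b`, `mean_diff`, `t`, `df`, `p`,
#'   `significant`; the adjusted alpha is attached as attribute
#'   `alpha_adj`.
#' @export
bonferroni_posthoc <- function(table, alpha_fw = 0.05) {
  if (!inherits(table, "metrics_table"))
    table <- metrics_table(table$subject_id, table$filter_name, table$value)
  m <- mt_wide(table)
  k <- ncol(m)
  if (nrow(m) < 2 || k < 2) stop("need >= 2 subjects and >= 2 conditions")
  pairs <- utils::combn(colnames(m), 2)
  alpha_adj <- alpha_fw / (k * (k - 1) / 2)
  rows <- apply(pairs, 2, function(pr) {
    d <- m[, pr[1]] - m[, pr[2]]
    n <- length(d)
    md <- mean(d)
    sd_d <- stats::sd(d)
    t <- if (sd_d == 0) {
      if (md == 0) 0 else sign(md) * Inf
    } else md / (sd_d / sqrt(n))
    p <- if (is.infinite(t)) 0 else
      2 * stats::pt(abs(t), n - 1, lower.tail = FALSE)
    data.frame(filter_a = pr[1], filter_b = pr[2], mean_diff = md,
               t = t, df = n - 1, p = p, significant = p < alpha_adj,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "alpha_adj") <- alpha_adj
  class(out) <- c("pairwise_results", "data.frame")
  out
}

#' Bonferroni-adjusted per-comparison alpha
#'
#' @param alpha_fw familywise level.
#' @param k number of conditions (comparisons are all `k(k-1)/2`
#'   unordered pairs).
#' @return The adjusted alpha.
#' @examples
#' bonferroni_alpha(0.05, 4)  # 0.008333...
#' @export
bonferroni_alpha <- function(alpha_fw = 0.05, k = 4) {
  alpha_fw / (k * (k - 1) / 2)
}
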