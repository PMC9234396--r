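#' @title Group-level statistics with effect sizes
#' @description
#' The classical layer used by every analysis: two-tailed one-sample and
#' paired t-tests reported with Cohen's dz, one-way repeated-measures
#' ANOVA reported with partial eta squared, and uncorrected post-hoc
#' pairwise comparisons. No multiple-comparison correction is applied:
#' post-hoc tests follow a significant omnibus F, and individual
#' comparisons are reported uncorrected with their effect sizes so that
#' the direction and size of each difference can be read directly.
#' @name group-stats
NULL

.stat_result <- function(test, statistic, df, p, effect, effect_name, n,
                         label = NA_character_) {
  data.frame(test = test, label = label, statistic = statistic,
             df1 = df[1], df2 = if (length(df) > 1) df[2] else NA_real_,
             p = p, effect = effect, effect_name = effect_name, n = n,
             stringsAsFactors = FALSE)
}

# run a test that may be degenerate (zero variance, e.g. a noise-free
# ceiling): report the row with NA statistics instead of aborting
.safe_stat <- function(expr, test, label, n) {
  tryCatch(expr, error = function(e)
    .stat_result(paste0(test, "_degenerate"), NA_real_, NA_real_,
                 NA_real_, NA_real_, "dz", n, label))
}

#' One-sample t-test with Cohen's dz
#'
#' Two-tailed t-test of the mean against `mu`; `dz = (mean - mu) / sd`.
#' Zero-variance input is a degenerate case and raises an error rather
#' than returning a meaningless p-value.
#'
#' @param values Numeric vector, length >= 2.
#' @param mu Null mean.
#' @param label Optional comparison label carried into the result.
#' @return One-row data frame: test, label, statistic, df, p, effect
#'   (dz), n.
#' @export
one_sample_t <- function(values, mu = 0, label = NA_character_) {
  stopifnot(is.numeric(values), length(values) >= 2L)
  if (stats::sd(values) == 0)
    stop("zero variance: one-sample t-test is degenerate", call. = FALSE)
  tt <- stats::t.test(values, mu = mu)
  dz <- (mean(values) - mu) / stats::sd(values)
  .stat_result("one_sample_t", unname(tt$statistic), unname(tt$parameter),
               tt$p.value, dz, "dz", length(values), label)
}

#' Paired t-test with Cohen's dz
#'
#' Equivalent to a one-sample t-test on the within-pair differences
#' against zero; `dz = mean(diff) / sd(diff)`.
#'
#' @param values_a,values_b Paired numeric vectors of equal length >= 2.
#' @param label Optional comparison label.
#' @return One-row data frame as [one_sample_t()].
#' @export
paired_t <- function(values_a, values_b, label = NA_character_) {
  stopifnot(length(values_a) == length(values_b), length(values_a) >= 2L)
  out <- one_sample_t(values_a - values_b, mu = 0, label = label)
  out$test <- "paired_t"
  out
}

#' One-way repeated-measures ANOVA with partial eta squared
#'
#' Univariate within-subject decomposition, fitted with [stats::aov()]
#' and a subject error stratum: `F = MS_condition / MS_error` with
#' `df1 = c - 1`, `df2 = (c - 1)(n - 1)`;
#' `partial eta^2 = SS_condition / (SS_condition + SS_error)`. No
#' sphericity correction is applied by default (matching reports of
#' uncorrected degrees of freedom); `gg = TRUE` applies the
#' Greenhouse-Geisser epsilon to the degrees of freedom and p-value.
#'
#' @param mat Complete numeric matrix, participants (rows) by conditions
#'   (columns), >= 2 of each.
#' @param gg Logical; apply the Greenhouse-Geisser correction.
#' @return One-row data frame: statistic (F), df1, df2, p, effect
#'   (partial eta squared), n (participants).
#' @export
rm_anova <- function(mat, gg = FALSE) {
  mat <- as.matrix(mat)
  if (anyNA(mat)) stop("rm_anova requires a complete matrix", call. = FALSE)
  if (nrow(mat) < 2L || ncol(mat) < 2L)
    stop("need >= 2 participants and >= 2 conditions", call. = FALSE)
  n <- nrow(mat); k <- ncol(mat)
  d <- data.frame(y = as.vector(mat),
                  subject = factor(rep(seq_len(n), times = k)),
                  cond = factor(rep(seq_len(k), each = n)))
  fit <- stats::aov(y ~ cond + Error(subject), data = d)
  tab <- summary(fit)[["Error: Within"]][[1L]]
  ss_cond <- tab["cond", "Sum Sq"]
  ss_err <- tab["Residuals", "Sum Sq"]
  df1 <- tab["cond", "Df"]; df2 <- tab["Residuals", "Df"]
  f <- tab["cond", "F value"]
  # no condition variation at all (identical columns): F is 0 by convention
  if (ss_cond <= 1e-12 * max(sum((mat - mean(mat))^2), 1)) {
    return(.stat_result("rm_anova", 0, c(df1, df2), 1, 0,
                        "partial_eta_sq", n))
  }
  eta_p2 <- ss_cond / (ss_cond + ss_err)
  if (gg) {
    eps <- .gg_epsilon(mat)
    p <- stats::pf(f, eps * df1, eps * df2, lower.tail = FALSE)
    return(.stat_result("rm_anova_gg", f, c(eps * df1, eps * df2), p,
                        eta_p2, "partial_eta_sq", n))
  }
  .stat_result("rm_anova", f, c(df1, df2),
               stats::pf(f, df1, df2, lower.tail = FALSE),
               eta_p2, "partial_eta_sq", n)
}

# Greenhouse-Geisser epsilon from the double-centred covariance matrix
.gg_epsilon <- function(mat) {
  S <- stats::cov(mat)
  k <- ncol(S)
  Sc <- S - outer(rowMeans(S), colMeans(S), "+") + mean(S)
  sum(diag(Sc))^2 / ((k - 1) * sum(Sc^2))
}

#' Uncorrected pairwise post-hoc comparisons
#'
#' All `c(c-1)/2` two-tailed paired t-tests between the columns of a
#' within-subject matrix, uncorrected, each with Cohen's dz. Comparisons
#' are flagged at two conventional levels: p < 0.05 and p < 0.10
#' (two-tailed, the latter equivalent to one-tailed 0.05).
#'
#' @param mat Complete numeric matrix, participants by conditions, with
#'   column names used as condition labels.
#' @return Data frame with one row per comparison: `condition_a`,
#'   `condition_b`, the [paired_t()] columns, `sig_05`, `sig_10`.
#' @export
posthoc_pairwise <- function(mat) {
  mat <- as.matrix(mat)
  labs <- colnames(mat)
  if (is.null(labs)) labs <- paste0("c", seq_len(ncol(mat)))
  pairs <- utils::combn(ncol(mat), 2L)
  rows <- lapply(seq_len(ncol(pairs)), function(j) {
    a <- pairs[1, j]; b <- pairs[2, j]
    lab <- paste(labs[a], "vs", labs[b])
    res <- .safe_stat(paired_t(mat[, a], mat[, b], label = lab),
                      "paired_t", lab, nrow(mat))
    cbind(data.frame(condition_a = labs[a], condition_b = labs[b],
                     stringsAsFactors = FALSE), res)
  })
  out <- do.call(rbind, rows)
  out$sig_05 <- out$p < 0.05
  out$sig_10 <- out$p < 0.10
  rownames(out) <- NULL
  out
}
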