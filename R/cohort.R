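# Cohort-level statistics: HR-deficiency sample exclusion, burden
# correlations, and the treated-vs-control replicate MMD comparison.

#' Exclude homologous-recombination-deficient samples
#'
#' Samples whose HRDetect probability is strictly greater than the cutoff
#' are removed: HR-deficient tumors rely more heavily on TMEJ, which would
#' confound APOBEC3-driven MMD signal. Samples with a missing score are
#' retained with a warning.
#'
#' @param samples Data.frame with a `hrdetect_prob` column (fraction in
#'   \[0, 1\] or NA).
#' @param cutoff Exclusion cutoff (default 0.70; "over 70%" is read as a
#'   strict inequality, so exactly 0.70 is retained).
#' @return List with `retained`, `excluded` (both data.frames) and
#'   `n_missing`.
#' @export
filter_hrdetect <- function(samples, cutoff = 0.70) {
  if (cutoff <= 0 || cutoff >= 1) stop("cutoff must lie in (0, 1)")
  prob <- samples$hrdetect_prob
  if (is.null(prob)) prob <- rep(NA_real_, nrow(samples))
  if (any(!is.na(prob) & (prob < 0 | prob > 1))) {
    stop("hrdetect_prob values must lie in [0, 1]")
  }
  n_missing <- sum(is.na(prob))
  if (n_missing > 0L) {
    warning(n_missing, " sample(s) without an HRDetect score were retained")
  }
  drop <- !is.na(prob) & prob > cutoff
  list(retained = samples[!drop, , drop = FALSE],
       excluded = samples[drop, , drop = FALSE],
       n_missing = n_missing)
}

#' Pearson or Spearman correlation with p-value
#'
#' Pairwise-complete observations; rank ties are mid-ranked; the p-value is
#' two-sided. Zero variance in either vector is an error (the coefficient is
#' undefined).
#'
#' @param x,y Numeric vectors of equal length.
#' @param method `"pearson"` or `"spearman"`.
#' @return List: method, r, p, n (complete pairs used; must be >= 3).
#' @export
correlate <- function(x, y, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  if (length(x) != length(y)) stop("x and y must have equal length")
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3L) stop("need at least 3 complete pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("correlation undefined: zero variance in x or y")
  }
  ct <- suppressWarnings(
    stats::cor.test(x, y, method = method, exact = FALSE))
  list(method = method, r = unname(ct$estimate), p = ct$p.value, n = n)
}

#' Compare replicate MMD counts between treated and control groups
#'
#' One-sided Welch t-test of the alternative that treated replicates carry
#' more MMDs than controls.
#'
#' @param treated,control Numeric vectors of per-replicate MMD counts
#'   (each of length >= 2).
#' @return List: mean_treated, mean_control, t_statistic, p_one_sided.
#' @export
compare_replicate_mmds <- function(treated, control) {
  if (length(treated) < 2L || length(control) < 2L) {
    stop("each group needs at least 2 replicates")
  }
  m_t <- mean(treated); m_c <- mean(control)
  if (stats::sd(treated) == 0 && stats::sd(control) == 0) {
    # degenerate constant groups: symmetric p for equal means, extreme
    # otherwise
    t_stat <- if (m_t == m_c) 0 else sign(m_t - m_c) * Inf
    p <- if (m_t == m_c) 0.5 else if (m_t > m_c) 0 else 1
  } else {
    tt <- stats::t.test(treated, control, alternative = "greater",
                        var.equal = FALSE)
    t_stat <- unname(tt$statistic); p <- tt$p.value
  }
  list(mean_treated = m_t, mean_control = m_c,
       t_statistic = t_stat, p_one_sided = p)
}
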