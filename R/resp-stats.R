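#' Detect apneas among interbreath intervals
#'
#' An apnea is an interbreath interval strictly longer than the threshold
#' (default 1.5 s); an IBI exactly at the threshold does not qualify.
#'
#' @param ibis_s numeric vector of interbreath intervals in seconds.
#' @param threshold_s apnea threshold in seconds.
#' @return List with `count` and `mean_length_s` (NA when count is 0).
#' @export
detect_apneas <- function(ibis_s, threshold_s = 1.5) {
  if (!is.numeric(ibis_s) || length(ibis_s) == 0L)
    stop_input("`ibis_s` must be a non-empty numeric vector")
  check_scalar_num(threshold_s, "threshold_s", 0, strict_lower = TRUE)
  q <- ibis_s[ibis_s > threshold_s]
  list(count = length(q),
       mean_length_s = if (length(q)) mean(q) else NA_real_)
}

#' Coefficient of variation of a breathing measure
#'
#' The instability measure used for interbreath intervals and breath
#' amplitudes. The default follows the standard-error convention,
#' `CV = (SD / sqrt(n)) / mean`; the conventional `SD / mean` form is
#' available via `type = "sd"`.
#'
#' @param values numeric vector (length >= 2, nonzero mean).
#' @param type `"se"` (default) or `"sd"`.
#' @return The coefficient of variation (dimensionless).
#' @export
variability_cv <- function(values, type = c("se", "sd")) {
  type <- match.arg(type)
  if (!is.numeric(values) || length(values) < 2L)
    stop_input("`values` must have at least 2 elements")
  m <- mean(values)
  if (abs(m) < .Machine$double.eps)
    stop_input("mean of `values` must be nonzero")
  s <- sd(values)
  if (type == "se") s <- s / sqrt(length(values))
  s / m
}

#' Lag-1 Poincare pairs of interbreath intervals
#'
#' @param ibis_s numeric vector of IBIs.
#' @return A two-column matrix (`ibi_n`, `ibi_n1`) of consecutive pairs;
#'   `n` IBIs yield `n - 1` rows (empty for fewer than 2 IBIs).
#' @export
poincare_pairs <- function(ibis_s) {
  n <- length(ibis_s)
  if (n < 2L)
    return(matrix(numeric(0), ncol = 2,
                  dimnames = list(NULL, c("ibi_n", "ibi_n1"))))
  cbind(ibi_n = ibis_s[-n], ibi_n1 = ibis_s[-1L])
}

#' Poincare plot of interbreath intervals
#'
#' Scatter of consecutive IBI pairs with the identity line, the standard
#' visualization of breath-to-breath variability.
#'
#' @param ibis_s numeric vector of IBIs in seconds.
#' @param ... further arguments to [graphics::plot()].
#' @return The pair matrix, invisibly.
#' @export
plot_poincare <- function(ibis_s, ...) {
  p <- poincare_pairs(ibis_s)
  plot(p[, 1L], p[, 2L], xlab = expression(IBI[n] ~ "(s)"),
       ylab = expression(IBI[n + 1] ~ "(s)"), ...)
  abline(0, 1, lty = 2)
  invisible(p)
}

#' Relative ventilatory response of a challenge condition to baseline
#'
#' Each component of the ventilation summary is expressed as the ratio
#' challenge / baseline; `ve_ratio == vf_ratio * vt_ratio` by construction.
#'
#' @param baseline,challenge `respiratory_summary` objects (or lists with
#'   fields `vf`, `vt`, `ve`).
#' @return List with `vf_ratio`, `vt_ratio`, `ve_ratio`.
#' @export
relative_response <- function(baseline, challenge) {
  for (f in c("vf", "vt", "ve"))
    if (!is.numeric(baseline[[f]]) || baseline[[f]] <= 0)
      stop_input("baseline %s must be > 0", f)
  list(vf_ratio = challenge$vf / baseline$vf,
       vt_ratio = challenge$vt / baseline$vt,
       ve_ratio = challenge$ve / baseline$ve)
}

#' Unpaired two-sample t-test (pooled variance)
#'
#' The group comparison used throughout: pooled-variance t statistic with
#' `df = nA + nB - 2` and a two-sided p-value. When both groups have zero
#' variance the comparison degenerates: equal means give `t = 0, p = 1`,
#' unequal means give an infinite statistic and `p = 0`.
#'
#' @param a,b numeric vectors, each of length >= 2.
#' @return Object of class `group_comparison`: `t_stat`, `df`,
#'   `p_two_sided`, `mean_a`, `mean_b`.
#' @export
compare_groups <- function(a, b) {
  if (length(a) < 2L || length(b) < 2L)
    stop_input("each group needs at least 2 values")
  na <- length(a); nb <- length(b)
  df <- na + nb - 2
  sp2 <- ((na - 1) * var(a) + (nb - 1) * var(b)) / df
  d <- mean(a) - mean(b)
  if (sp2 <= 0) {
    t <- if (d == 0) 0 else sign(d) * Inf
    p <- if (d == 0) 1 else 0
  } else {
    t <- d / sqrt(sp2 * (1 / na + 1 / nb))
    p <- 2 * pt(-abs(t), df)
  }
  structure(list(t_stat = t, df = df, p_two_sided = p,
                 mean_a = mean(a), mean_b = mean(b)),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("<group_comparison> t = %.4g, df = %d, p = %.4g (means %.4g vs %.4g)\n",
              x$t_stat, x$df, x$p_two_sided, x$mean_a, x$mean_b))
  invisible(x)
}

#' Chi-square goodness-of-fit test for genotype counts from timed matings
#'
#' Tests observed genotype counts against expected Mendelian fractions:
#' `chi2 = sum((obs - exp)^2 / exp)` with `df = k - 1`.
#'
#' @param observed integer vector of observed counts per genotype class.
#' @param expected_fraction expected probabilities, summing to 1.
#' @return List with `chi2`, `df`, `p`.
#' @export
mendelian_chi_square <- function(observed, expected_fraction) {
  if (length(observed) != length(expected_fraction))
    stop_input("observed and expected_fraction must have equal length")
  if (any(observed < 0)) stop_input("observed counts must be >= 0")
  if (abs(sum(expected_fraction) - 1) > 1e-8)
    stop_input("expected_fraction must sum to 1")
  expected <- sum(observed) * expected_fraction
  if (any(expected <= 0)) stop_input("zero expected count")
  ct <- suppressWarnings(chisq.test(observed, p = expected_fraction))
  list(chi2 = unname(ct$statistic), df = unname(ct$parameter),
       p = ct$p.value)
}

#' Expected Mendelian carrier fractions for a two-parent cross
#'
#' For each independently segregating locus, a parent carrying `c` copies of
#' the allele transmits it with probability `c / 2`; an offspring carries
#' the allele if it receives it from either parent. The joint
#' all-loci-carrier fraction is the product across loci (e.g. a homozygous
#' knock-in parent crossed to a hemizygous cre parent yields double carriers
#' at the expected 50% frequency).
#'
#' @param parent1_copies,parent2_copies integer vectors (0, 1 or 2 copies)
#'   of the tracked allele at each locus.
#' @return List with `per_locus` carrier fractions and `all_loci`, the
#'   expected fraction of offspring carrying every tracked allele.
#' @export
mendelian_expected <- function(parent1_copies, parent2_copies) {
  if (length(parent1_copies) != length(parent2_copies))
    stop_input("parental copy vectors must have equal length")
  if (any(!parent1_copies %in% 0:2) || any(!parent2_copies %in% 0:2))
    stop_input("allele copies must be 0, 1 or 2")
  p <- 1 - (1 - parent1_copies / 2) * (1 - parent2_copies / 2)
  list(per_locus = p, all_loci = prod(p))
}
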