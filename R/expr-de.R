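#' Quantile-normalize a log2 expression matrix
#'
#' Forces every sample column onto the identical distribution (the
#' column-wise mean of order statistics) while preserving within-column
#' ranks. Used here as the normalization step ahead of differential
#' expression testing.
#'
#' @param mat numeric matrix, genes in rows, samples in columns (>= 2),
#'   log2-scale values; row names are gene ids.
#' @return The normalized matrix, same dimensions and dimnames.
#' @export
normalize_quantile <- function(mat) {
  mat <- as.matrix(mat)
  if (ncol(mat) < 2L) stop_input("need at least 2 samples to normalize")
  if (any(!is.finite(mat))) stop_input("expression values must be finite")
  out <- limma::normalizeQuantiles(mat)
  dimnames(out) <- dimnames(mat)
  out
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjustment with monotonicity enforcement; each adjusted value is
#' the estimated FDR when the corresponding raw p-value is used as the
#' significance cutoff.
#'
#' @param p_values numeric vector of p-values in \[0, 1\].
#' @return Adjusted values, same length and order.
#' @export
bh_fdr <- function(p_values) {
  if (!is.numeric(p_values) || length(p_values) == 0L)
    stop_input("`p_values` must be a non-empty numeric vector")
  if (any(!is.finite(p_values)) || any(p_values < 0) || any(p_values > 1))
    stop_input("p-values must lie in [0, 1]")
  p.adjust(p_values, method = "BH")
}

#' Signed fold change from a log2 fold change
#'
#' The signed linear-scale convention used for reporting thresholds such as
#' "fold-change >= 1.2 and <= -1.2": `2^log2fc` when `log2fc >= 0`, else
#' `-2^(-log2fc)`. Values never fall in the open interval (-1, 1).
#'
#' @param log2fc numeric vector of log2 fold changes.
#' @return Signed fold changes.
#' @export
signed_fold_change <- function(log2fc) {
  ifelse(log2fc >= 0, 2^log2fc, -(2^(-log2fc)))
}

#' Per-gene differential expression by pooled two-sample t-test
#'
#' For every gene, a pooled-variance unpaired t-test of case against control
#' samples (identical to [compare_groups()] applied row-wise), a log2 fold
#' change `mean_case - mean_control`, its signed linear fold change, and a
#' Benjamini-Hochberg FDR across all genes. Genes with zero variance in both
#' groups and equal means are reported as `t = 0, p = 1` so that gene counts
#' stay stable.
#'
#' @param mat numeric matrix of log2 expression (genes x samples) with gene
#'   ids as row names; normalize first (see [normalize_quantile()]).
#' @param groups character/factor of `"case"` / `"control"` per column.
#' @return A `data.frame` of class `de_result` with columns `gene_id`,
#'   `mean_case`, `mean_control`, `log2fc`, `signed_fc`, `t_stat`, `p`,
#'   `fdr`.
#' @export
de_test <- function(mat, groups) {
  mat <- as.matrix(mat)
  groups <- as.character(groups)
  if (length(groups) != ncol(mat))
    stop_input("`groups` must label every sample column")
  if (!all(groups %in% c("case", "control")))
    stop_input("groups must be 'case' or 'control'")
  ic <- which(groups == "case"); ik <- which(groups == "control")
  if (length(ic) < 2L || length(ik) < 2L)
    stop_input("need at least 2 samples per group")
  if (is.null(rownames(mat))) rownames(mat) <- paste0("g", seq_len(nrow(mat)))

  xc <- mat[, ic, drop = FALSE]; xk <- mat[, ik, drop = FALSE]
  nc <- length(ic); nk <- length(ik)
  mc <- rowMeans(xc); mk <- rowMeans(xk)
  vc <- rowSums((xc - mc)^2) / (nc - 1)
  vk <- rowSums((xk - mk)^2) / (nk - 1)
  df <- nc + nk - 2
  sp2 <- ((nc - 1) * vc + (nk - 1) * vk) / df
  d <- mc - mk
  se <- sqrt(sp2 * (1 / nc + 1 / nk))
  t <- ifelse(se > 0, d / se, ifelse(d == 0, 0, sign(d) * Inf))
  p <- ifelse(is.finite(t), 2 * pt(-abs(t), df), 0)
  p[t == 0 & se == 0] <- 1
  res <- data.frame(gene_id = rownames(mat), mean_case = mc,
                    mean_control = mk, log2fc = d,
                    signed_fc = signed_fold_change(d),
                    t_stat = t, p = p, fdr = bh_fdr(p),
                    row.names = NULL, stringsAsFactors = FALSE)
  class(res) <- c("de_result", "data.frame")
  res
}

#' @export
print.de_result <- function(x, ...) {
  cat(sprintf("<de_result> %d genes; %d at FDR < 0.05\n",
              nrow(x), sum(x$fdr < 0.05)))
  NextMethod()
}

#' Threshold a DE result into up- and down-regulated gene sets
#'
#' A gene is called up when `fdr < fdr_threshold` and
#' `signed_fc >= fc_threshold`, down when `fdr < fdr_threshold` and
#' `signed_fc <= -fc_threshold` (boundary fold changes included).
#'
#' @param records a `de_result` from [de_test()].
#' @param fdr_threshold FDR cutoff (default 0.05, strict).
#' @param fc_threshold signed fold-change magnitude cutoff (default 1.2,
#'   inclusive).
#' @return Object of class `deregulated_sets`: character vectors `up` and
#'   `down`, the thresholds, and `directions`, a named `"up"`/`"down"`
#'   vector over the union.
#' @export
threshold_filter <- function(records, fdr_threshold = 0.05,
                             fc_threshold = 1.2) {
  check_scalar_num(fdr_threshold, "fdr_threshold", 0, strict_lower = TRUE)
  check_scalar_num(fc_threshold, "fc_threshold", 1)
  sig <- records$fdr < fdr_threshold
  up <- records$gene_id[sig & records$signed_fc >= fc_threshold]
  down <- records$gene_id[sig & records$signed_fc <= -fc_threshold]
  dirs <- c(stats::setNames(rep("up", length(up)), up),
            stats::setNames(rep("down", length(down)), down))
  structure(list(up = up, down = down, fdr_threshold = fdr_threshold,
                 fc_threshold = fc_threshold, directions = dirs),
            class = "deregulated_sets")
}

#' @export
print.deregulated_sets <- function(x, ...) {
  n <- length(x$up) + length(x$down)
  cat(sprintf("<deregulated_sets> %d genes (FDR < %g, |FC| >= %g)\n",
              n, x$fdr_threshold, x$fc_threshold))
  if (n > 0) {
    pc <- deregulation_percentages(length(x$up), length(x$down))
    cat(sprintf("  up   %d (%.2f%%)\n  down %d (%.2f%%)\n",
                length(x$up), pc["pct_up"], length(x$down), pc["pct_down"]))
  }
  invisible(x)
}

#' Percentage breakdown of a deregulated gene set
#'
#' @param n_up,n_down counts of up- and down-regulated genes.
#' @return Named vector `pct_up`, `pct_down` (percent of all deregulated).
#' @export
deregulation_percentages <- function(n_up, n_down) {
  tot <- n_up + n_down
  if (tot <= 0) stop_input("no deregulated genes")
  c(pct_up = 100 * n_up / tot, pct_down = 100 * n_down / tot)
}

#' Relative qPCR quantification by the delta-delta-Ct method
#'
#' `dCt_test = Ct_target,test - Ct_reference,test`, analogously for the
#' control condition; `ddCt = dCt_test - dCt_control`; fold change is
#' `2^(-ddCt)`. Vectorized over measurements.
#'
#' @param ct_target_test,ct_reference_test Ct of target and reference gene
#'   in the test condition (cycles, > 0).
#' @param ct_target_control,ct_reference_control same for the control
#'   condition.
#' @return Fold change(s) of the target relative to control, reference-gene
#'   normalized.
#' @export
delta_delta_ct <- function(ct_target_test, ct_reference_test,
                           ct_target_control, ct_reference_control) {
  cts <- c(ct_target_test, ct_reference_test,
           ct_target_control, ct_reference_control)
  if (any(!is.finite(cts)) || any(cts <= 0))
    stop_input("all Ct values must be positive")
  ddct <- (ct_target_test - ct_reference_test) -
          (ct_target_control - ct_reference_control)
  2^(-ddct)
}
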