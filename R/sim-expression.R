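#' Parameters for the paired expression-study simulator
#'
#' Defaults mirror the design of a gain-of-function versus loss-of-function
#' microarray comparison: a 2000-gene universe, 200 deregulated genes per
#' study with 100 shared, three quarters of the shared genes reciprocal
#' (opposite directions between studies), a planted effect of 2 log2 units
#' against sample noise of 0.5 log2 units, and 3 samples per group as in a
#' typical small array study.
#'
#' @param n_genes_universe number of genes in the shared universe.
#' @param n_dereg_a,n_dereg_b planted deregulated genes per study.
#' @param n_overlap planted shared deregulated genes
#'   (`<= min(n_dereg_a, n_dereg_b)`).
#' @param reciprocal_fraction fraction of the shared genes given opposite
#'   directions in the two studies.
#' @param effect_log2 planted shift in log2 units.
#' @param noise_sd per-sample Gaussian noise SD, log2 units.
#' @param samples_per_group samples per case/control group (>= 2).
#' @param seed integer seed.
#' @return List of class `expr_pair_sim_params`.
#' @export
expr_pair_sim_params <- function(n_genes_universe = 2000, n_dereg_a = 200,
                                 n_dereg_b = 200, n_overlap = 100,
                                 reciprocal_fraction = 0.75,
                                 effect_log2 = 2, noise_sd = 0.5,
                                 samples_per_group = 3, seed = 1L) {
  check_scalar_num(n_genes_universe, "n_genes_universe", 1)
  check_scalar_num(n_dereg_a, "n_dereg_a", 0, upper = n_genes_universe)
  check_scalar_num(n_dereg_b, "n_dereg_b", 0, upper = n_genes_universe)
  if (n_overlap > min(n_dereg_a, n_dereg_b))
    stop_input("n_overlap exceeds a deregulated-set size")
  if (n_dereg_a + n_dereg_b - n_overlap > n_genes_universe)
    stop_input("deregulated sets do not fit in the universe")
  check_scalar_num(reciprocal_fraction, "reciprocal_fraction", 0, upper = 1)
  check_scalar_num(effect_log2, "effect_log2", 0)
  check_scalar_num(noise_sd, "noise_sd", 0, strict_lower = TRUE)
  check_scalar_num(samples_per_group, "samples_per_group", 2)
  structure(list(n_genes_universe = as.integer(n_genes_universe),
                 n_dereg_a = as.integer(n_dereg_a),
                 n_dereg_b = as.integer(n_dereg_b),
                 n_overlap = as.integer(n_overlap),
                 reciprocal_fraction = reciprocal_fraction,
                 effect_log2 = effect_log2, noise_sd = noise_sd,
                 samples_per_group = as.integer(samples_per_group),
                 seed = as.integer(seed)),
            class = "expr_pair_sim_params")
}

#' Simulate a pair of expression studies with planted deregulation
#'
#' Generates log2-scale expression matrices for two case/control studies
#' over a shared gene universe. Planted deregulated genes are shifted by
#' `+/- effect_log2` in their study's case group; of the shared genes,
#' `round(reciprocal_fraction * n_overlap)` receive opposite signs in the
#' two studies and the rest the same sign. All other genes are null, with
#' every sample value drawn `N(baseline, noise_sd)` around a gene-specific
#' baseline.
#'
#' @param params an [expr_pair_sim_params()].
#' @return List with `study_a` and `study_b` (each `values`: genes x
#'   samples log2 matrix, `groups`: case/control labels) and `truth`:
#'   named direction vectors `dereg_a`, `dereg_b` (`"up"`/`"down"`),
#'   `overlap_genes`, `reciprocal_genes`, and the gene `universe`.
#' @export
sim_expression_pair <- function(params) {
  stopifnot(inherits(params, "expr_pair_sim_params"))
  with_seed(params$seed, {
    p <- params
    universe <- sprintf("g%05d", seq_len(p$n_genes_universe))
    ov <- sample(universe, p$n_overlap)
    rest <- setdiff(universe, ov)
    only_a <- sample(rest, p$n_dereg_a - p$n_overlap)
    only_b <- sample(setdiff(rest, only_a), p$n_dereg_b - p$n_overlap)
    genes_a <- c(ov, only_a); genes_b <- c(ov, only_b)

    sgn_a <- stats::setNames(sample(c(1, -1), p$n_dereg_a, replace = TRUE),
                             genes_a)
    n_rec <- round(p$reciprocal_fraction * p$n_overlap)
    rec_genes <- if (n_rec > 0) sample(ov, n_rec) else character(0)
    sgn_b <- stats::setNames(sample(c(1, -1), p$n_dereg_b, replace = TRUE),
                             genes_b)
    sgn_b[ov] <- sgn_a[ov]
    sgn_b[rec_genes] <- -sgn_a[rec_genes]

    mk_study <- function(sgn) {
      k <- p$samples_per_group
      base <- rnorm(p$n_genes_universe, 8, 1)
      shift <- stats::setNames(numeric(p$n_genes_universe), universe)
      shift[names(sgn)] <- sgn * p$effect_log2
      vals <- matrix(rnorm(p$n_genes_universe * 2 * k,
                           mean = rep(base, 2 * k), sd = p$noise_sd),
                     nrow = p$n_genes_universe)
      vals[, seq_len(k)] <- vals[, seq_len(k)] + shift
      rownames(vals) <- universe
      colnames(vals) <- c(paste0("case_", seq_len(k)),
                          paste0("control_", seq_len(k)))
      list(values = vals,
           groups = rep(c("case", "control"), each = k))
    }
    dir_of <- function(sgn) stats::setNames(
      ifelse(sgn > 0, "up", "down"), names(sgn))
    list(study_a = mk_study(sgn_a), study_b = mk_study(sgn_b),
         truth = list(dereg_a = dir_of(sgn_a), dereg_b = dir_of(sgn_b),
                      overlap_genes = ov, reciprocal_genes = sort(rec_genes),
                      universe = universe))
  })
}
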