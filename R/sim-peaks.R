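#' Parameters for the ChIP-seq peak / gene-annotation simulator
#'
#' Genes are placed with at least 10 kb between TSSs inside a gene
#' territory at the start of the (single-chromosome) genome, leaving the
#' remainder as gene desert so that out-of-domain peaks can be placed
#' beyond any capped regulatory domain.
#'
#' @param genome_length_bp total chromosome length (must exceed
#'   `n_genes * 10000`).
#' @param n_genes number of genes to place.
#' @param n_peaks number of peaks to emit.
#' @param fraction_in_domains fraction of peaks planted inside a gene's
#'   basal regulatory domain; the remainder go to gene deserts.
#' @param peak_width_bp width of each emitted peak.
#' @param seed integer seed.
#' @return List of class `peak_sim_params`.
#' @export
peak_sim_params <- function(genome_length_bp = 1e8, n_genes = 200,
                            n_peaks = 100, fraction_in_domains = 0.8,
                            peak_width_bp = 300, seed = 1L) {
  check_scalar_num(genome_length_bp, "genome_length_bp", 0,
                   strict_lower = TRUE)
  check_scalar_num(n_genes, "n_genes", 1)
  if (n_genes * 10000 >= genome_length_bp)
    stop_input("genome too short: need n_genes * 10000 < genome_length_bp")
  check_scalar_num(n_peaks, "n_peaks", 0)
  check_scalar_num(fraction_in_domains, "fraction_in_domains", 0, upper = 1)
  check_scalar_num(peak_width_bp, "peak_width_bp", 10)
  structure(list(genome_length_bp = genome_length_bp,
                 n_genes = as.integer(n_genes),
                 n_peaks = as.integer(n_peaks),
                 fraction_in_domains = fraction_in_domains,
                 peak_width_bp = as.integer(peak_width_bp),
                 seed = as.integer(seed)),
            class = "peak_sim_params")
}

#' Simulate ChIP-seq peaks and a gene annotation with planted targets
#'
#' Places `n_genes` TSSs (random position within the gene territory,
#' random strand, >= 10 kb apart), then emits
#' `round(fraction_in_domains * n_peaks)` peaks whose midpoints lie strictly
#' inside the basal regulatory domain of a planted target gene and the
#' remaining peaks in gene deserts, farther than `max_ext` plus the basal
#' span from every TSS so that no capped regulatory domain can reach them.
#' Placement is by bounded rejection sampling; if the genome leaves no
#' desert space a generation error is raised.
#'
#' @param params a [peak_sim_params()].
#' @param gene_ids optional character vector of gene ids to use (length
#'   `n_genes`); defaults to `g00001...`.
#' @param target_gene_ids optional gene ids to receive the in-domain peaks
#'   (cycled over); defaults to a random sample of genes.
#' @param basal_up,basal_down,max_ext regulatory-domain geometry used to
#'   define basal interiors and desert clearance (bp).
#' @param chrom chromosome name for all features.
#' @return List with `peaks` (BED-style `data.frame`: chrom, start, end),
#'   `genes` (`gene_id`, `chrom`, `strand`, `tss`), and `truth`:
#'   `target_genes` (planted, unique), `peak_target` (per-peak gene id or
#'   NA for desert peaks).
#' @export
sim_peaks_genes <- function(params, gene_ids = NULL, target_gene_ids = NULL,
                            basal_up = 5000, basal_down = 1000,
                            max_ext = 1e6, chrom = "chr1") {
  stopifnot(inherits(params, "peak_sim_params"))
  with_seed(params$seed, {
    p <- params
    gap <- 10000
    if (is.null(gene_ids)) gene_ids <- sprintf("g%05d", seq_len(p$n_genes))
    if (length(gene_ids) != p$n_genes)
      stop_input("gene_ids must have length n_genes")
    # gene territory: genes confined to the left part of the chromosome
    territory <- min(p$genome_length_bp,
                     max(2 * p$n_genes * gap, 0.4 * p$genome_length_bp))
    # stick-breaking placement guarantees >= gap between consecutive TSSs
    slack <- territory - p$n_genes * gap
    tss <- sort(runif(p$n_genes, 0, slack)) +
      (seq_len(p$n_genes) - 1L) * gap + gap / 2
    tss <- floor(tss)
    genes <- data.frame(gene_id = gene_ids, chrom = chrom,
                        strand = sample(c("+", "-"), p$n_genes,
                                        replace = TRUE),
                        tss = tss, stringsAsFactors = FALSE)

    n_in <- round(p$fraction_in_domains * p$n_peaks)
    n_out <- p$n_peaks - n_in
    targets <- if (n_in == 0) character(0)
      else if (!is.null(target_gene_ids)) {
        if (!all(target_gene_ids %in% gene_ids))
          stop_input("target_gene_ids must be placed genes")
        rep_len(target_gene_ids, n_in)
      } else sample(gene_ids, n_in, replace = TRUE)

    half <- floor(p$peak_width_bp / 2)
    mk_peak <- function(mid) data.frame(chrom = chrom, start = mid - half,
                                        end = mid - half + p$peak_width_bp,
                                        stringsAsFactors = FALSE)
    peaks <- NULL; peak_target <- character(0)
    if (n_in > 0) {
      gi <- match(targets, genes$gene_id)
      plus <- genes$strand[gi] == "+"
      b_start <- ifelse(plus, genes$tss[gi] - basal_up,
                        genes$tss[gi] - basal_down + 1)
      b_end <- ifelse(plus, genes$tss[gi] + basal_down,
                      genes$tss[gi] + basal_up + 1)
      mids <- floor(runif(n_in, b_start + 100, b_end - 100))
      peaks <- mk_peak(mids)
      peak_target <- targets
    }
    if (n_out > 0) {
      clearance <- max_ext + basal_up + basal_down + gap
      lo <- territory + clearance
      hi <- p$genome_length_bp - p$peak_width_bp
      if (lo >= hi)
        stop_input(paste("generation error: no desert space for",
                         "out-of-domain peaks; increase genome_length_bp"))
      mids <- floor(runif(n_out, lo + half, hi - half))
      peaks <- rbind(peaks, mk_peak(mids))
      peak_target <- c(peak_target, rep(NA_character_, n_out))
    }
    if (is.null(peaks))
      peaks <- data.frame(chrom = character(0), start = numeric(0),
                          end = numeric(0), stringsAsFactors = FALSE)
    list(peaks = peaks, genes = genes,
         truth = list(target_genes = sort(unique(peak_target[
                        !is.na(peak_target)])),
                      peak_target = peak_target))
  })
}
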