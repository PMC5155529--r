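#' Hypergeometric test for the overlap of two gene sets
#'
#' One-sided enrichment test: with a universe of `N` genes and sets of sizes
#' `nA`, `nB`, the p-value is `P(X >= m)` for
#' `X ~ Hypergeometric(N, nA, nB)`, where `m` is the observed overlap.
#'
#' @param set_a,set_b character vectors of gene ids, subsets of `universe`.
#' @param universe character vector of all testable gene ids.
#' @return Object of class `overlap_result`: `universe_size`, `set_a_size`,
#'   `set_b_size`, `overlap_genes`, `overlap_size`, `p_hypergeometric`.
#' @export
overlap_test <- function(set_a, set_b, universe) {
  universe <- unique(as.character(universe))
  set_a <- unique(as.character(set_a)); set_b <- unique(as.character(set_b))
  if (!all(set_a %in% universe) || !all(set_b %in% universe))
    stop_input("gene sets must be subsets of the universe")
  ov <- intersect(set_a, set_b)
  m <- length(ov)
  p <- phyper(m - 1, length(set_a), length(universe) - length(set_a),
              length(set_b), lower.tail = FALSE)
  structure(list(universe_size = length(universe),
                 set_a_size = length(set_a), set_b_size = length(set_b),
                 overlap_genes = ov, overlap_size = m,
                 p_hypergeometric = p),
            class = "overlap_result")
}

#' @export
print.overlap_result <- function(x, ...) {
  cat(sprintf(
    "<overlap_result> |A|=%d, |B|=%d, overlap %d of universe %d; p = %.3g\n",
    x$set_a_size, x$set_b_size, x$overlap_size, x$universe_size,
    x$p_hypergeometric))
  invisible(x)
}

#' Classify direction concordance of genes deregulated in two studies
#'
#' Tallies the overlap genes by their deregulation direction in each study:
#' `uu` (up in both), `dd` (down in both), `ud` (up in A, down in B), `du`
#' (down in A, up in B). Reciprocal genes -- the dosage-responsive signature
#' -- are `ud + du`.
#'
#' @param overlap_genes character vector of shared deregulated genes.
#' @param directions_a,directions_b named character vectors giving
#'   `"up"`/`"down"` per gene in studies A and B; every overlap gene must be
#'   present in both.
#' @return Object of class `reciprocity_result`: counts `uu`, `dd`, `ud`,
#'   `du`, plus `reciprocal`, `concordant`, and `m = uu+dd+ud+du`.
#' @export
classify_reciprocity <- function(overlap_genes, directions_a, directions_b) {
  overlap_genes <- as.character(overlap_genes)
  miss <- setdiff(overlap_genes,
                  intersect(names(directions_a), names(directions_b)))
  if (length(miss))
    stop_input("missing direction for gene(s): %s",
               paste(head(miss, 5), collapse = ", "))
  da <- directions_a[overlap_genes]; db <- directions_b[overlap_genes]
  if (!all(c(da, db) %in% c("up", "down")))
    stop_input("directions must be 'up' or 'down'")
  uu <- sum(da == "up" & db == "up")
  dd <- sum(da == "down" & db == "down")
  ud <- sum(da == "up" & db == "down")
  du <- sum(da == "down" & db == "up")
  structure(list(uu = uu, dd = dd, ud = ud, du = du,
                 reciprocal = ud + du, concordant = uu + dd,
                 m = length(overlap_genes)),
            class = "reciprocity_result")
}

#' @export
print.reciprocity_result <- function(x, ...) {
  cat(sprintf(
    "<reciprocity_result> %d/%d reciprocal (ud %d, du %d; uu %d, dd %d)\n",
    x$reciprocal, x$m, x$ud, x$du, x$uu, x$dd))
  invisible(x)
}

#' Exact binomial test for an excess of reciprocal expression trends
#'
#' Under the null that each overlap gene is reciprocal or concordant with
#' equal probability, the p-value for observing `k` reciprocal genes out of
#' `m` is the exact upper tail `P(X >= k)`, `X ~ Binomial(m, 1/2)`.
#'
#' @param reciprocal observed number of reciprocal genes, `0 <= k <= m`.
#' @param m total overlap size.
#' @return One-sided p-value.
#' @export
reciprocity_test <- function(reciprocal, m) {
  check_scalar_num(m, "m", 0)
  check_scalar_num(reciprocal, "reciprocal", 0, upper = m)
  pbinom(reciprocal - 1, m, 0.5, lower.tail = FALSE)
}

#' Basal-plus-extension regulatory domains for a gene annotation
#'
#' Each gene receives a strand-aware basal domain (`basal_up` bp upstream
#' and `basal_down` bp downstream of its TSS) that is then extended in both
#' directions up to the nearest neighboring basal domain on the same
#' chromosome, capped at `max_ext` bp beyond the basal edge (the GREAT
#' association rule). Basal domains are always retained even when neighbors
#' are close. Coordinates are 0-based half-open.
#'
#' @param genes `data.frame` with columns `gene_id`, `chrom`, `strand`
#'   (`"+"`/`"-"`), `tss` (0-based bp).
#' @param basal_up,basal_down basal domain extent upstream/downstream of the
#'   TSS in bp.
#' @param max_ext maximum extension beyond the basal domain in bp.
#' @return `data.frame` with `gene_id`, `chrom`, `strand`, `tss`,
#'   `basal_start`, `basal_end`, `dom_start`, `dom_end`.
#' @export
regulatory_domains <- function(genes, basal_up = 5000, basal_down = 1000,
                               max_ext = 1e6) {
  genes <- as.data.frame(genes)
  need <- c("gene_id", "chrom", "strand", "tss")
  if (!all(need %in% names(genes)))
    stop_input("genes need columns %s", paste(need, collapse = ", "))
  if (anyDuplicated(genes$gene_id)) stop_input("gene_id must be unique")
  if (!all(genes$strand %in% c("+", "-")))
    stop_input("strand must be '+' or '-'")
  plus <- genes$strand == "+"
  genes$basal_start <- ifelse(plus, genes$tss - basal_up,
                              genes$tss - basal_down + 1)
  genes$basal_end <- ifelse(plus, genes$tss + basal_down,
                            genes$tss + basal_up + 1)
  genes$basal_start <- pmax(genes$basal_start, 0)
  out <- lapply(split(genes, genes$chrom), function(g) {
    g <- g[order(g$basal_start), , drop = FALSE]
    n <- nrow(g)
    left_nb <- c(-Inf, g$basal_end[-n])   # nearest basal edge to the left
    right_nb <- c(g$basal_start[-1L], Inf)
    g$dom_start <- pmin(g$basal_start,
                        pmax(g$basal_start - max_ext,
                             cummax_finite(left_nb)))
    g$dom_end <- pmax(g$basal_end,
                      pmin(g$basal_end + max_ext, right_nb))
    g$dom_start <- pmax(g$dom_start, 0)
    g
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

# running max so a short gene nested between long neighbors still stops at
# the rightmost basal edge seen so far
cummax_finite <- function(x) {
  y <- cummax(ifelse(is.finite(x), x, -Inf))
  y
}

#' Assign ChIP-seq peaks to genes via regulatory domains
#'
#' A peak is anchored at its midpoint `floor((start + end) / 2)` and
#' associated with every gene whose regulatory domain (see
#' [regulatory_domains()]) contains the midpoint. The signed distance is
#' midpoint minus TSS, with the sign flipped on minus-strand genes so that
#' negative always means upstream of the gene.
#'
#' @param peaks `data.frame` with columns `chrom`, `start`, `end` (BED,
#'   0-based half-open, `start < end`).
#' @param genes gene annotation as in [regulatory_domains()].
#' @param basal_up,basal_down,max_ext domain parameters in bp.
#' @return `data.frame` of class `peak_gene_assoc` with columns `chrom`,
#'   `start`, `end`, `gene_id`, `signed_distance_bp`.
#' @export
assign_peaks <- function(peaks, genes, basal_up = 5000, basal_down = 1000,
                         max_ext = 1e6) {
  peaks <- as.data.frame(peaks)
  empty <- data.frame(chrom = character(0), start = numeric(0),
                      end = numeric(0), gene_id = character(0),
                      signed_distance_bp = numeric(0))
  class(empty) <- c("peak_gene_assoc", "data.frame")
  if (nrow(peaks) == 0L) return(empty)
  if (!all(c("chrom", "start", "end") %in% names(peaks)))
    stop_input("peaks need columns chrom, start, end")
  if (any(peaks$start >= peaks$end))
    stop_input("malformed peak interval: start >= end")
  dom <- regulatory_domains(genes, basal_up, basal_down, max_ext)
  peaks$midpoint <- floor((peaks$start + peaks$end) / 2)
  res <- lapply(intersect(unique(peaks$chrom), unique(dom$chrom)),
                function(chr) {
    p <- peaks[peaks$chrom == chr, , drop = FALSE]
    d <- dom[dom$chrom == chr, , drop = FALSE]
    # 0-based half-open [s, e) as 1-based closed [s+1, e]
    hits <- IRanges::findOverlaps(
      IRanges::IRanges(p$midpoint + 1L, p$midpoint + 1L),
      IRanges::IRanges(d$dom_start + 1L, d$dom_end))
    qi <- S4Vectors::queryHits(hits); si <- S4Vectors::subjectHits(hits)
    if (!length(qi)) return(NULL)
    dist <- p$midpoint[qi] - d$tss[si]
    dist <- ifelse(d$strand[si] == "-", -dist, dist)
    data.frame(chrom = chr, start = p$start[qi], end = p$end[qi],
               gene_id = d$gene_id[si], signed_distance_bp = dist,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, res)
  if (is.null(res)) return(empty)
  rownames(res) <- NULL
  class(res) <- c("peak_gene_assoc", "data.frame")
  res
}

#' Signed distance-to-TSS histogram of peak-gene associations
#'
#' Bins the absolute TSS distances (kb) into half-open bins given by
#' `bin_edges_kb`, split by side (negative distances upstream, non-negative
#' downstream; an exact 0 counts as downstream). Fractions sum to 1 over all
#' associations.
#'
#' @param assocs output of [assign_peaks()], non-empty.
#' @param bin_edges_kb increasing bin edges in kb; the last may be `Inf`.
#' @return `data.frame` with `side`, `bin`, `count`, `fraction`.
#' @export
tss_distance_histogram <- function(assocs,
                                   bin_edges_kb = c(0, 5, 50, 500, Inf)) {
  if (NROW(assocs) == 0L) stop_input("no associations to histogram")
  d <- assocs$signed_distance_bp
  side <- factor(ifelse(d >= 0, "downstream", "upstream"),
                 levels = c("upstream", "downstream"))
  bin <- cut(abs(d) / 1000, breaks = bin_edges_kb, right = FALSE)
  tab <- as.data.frame(table(side = side, bin = bin))
  names(tab)[3] <- "count"
  tab$fraction <- tab$count / length(d)
  tab
}

#' Three-way intersection of ChIP targets with two deregulated gene sets
#'
#' Returns the genes bound in the ChIP experiment (associated with at least
#' one peak) that are deregulated in both expression studies; with
#' `require_reciprocal = TRUE` the directions must be opposite between the
#' studies (the direct dosage-target signature).
#'
#' @param chip_genes character vector of peak-associated gene ids.
#' @param dereg_a,dereg_b `deregulated_sets` from [threshold_filter()] (or
#'   lists with `up`/`down` character vectors).
#' @param require_reciprocal demand opposite directions (default FALSE).
#' @return Sorted character vector of gene ids.
#' @export
three_way_intersect <- function(chip_genes, dereg_a, dereg_b,
                                require_reciprocal = FALSE) {
  chip_genes <- unique(as.character(chip_genes))
  a_all <- c(dereg_a$up, dereg_a$down)
  b_all <- c(dereg_b$up, dereg_b$down)
  g <- intersect(chip_genes, intersect(a_all, b_all))
  if (require_reciprocal) {
    rec <- (g %in% dereg_a$up & g %in% dereg_b$down) |
           (g %in% dereg_a$down & g %in% dereg_b$up)
    g <- g[rec]
  }
  sort(g)
}
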