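test_that("hypergeometric overlap test matches the exact tail sum", {
  universe <- paste0("g", 1:20)
  a <- universe[1:5]
  b <- c(universe[1:4], universe[10:11])  # overlap 4, |B| = 6
  r <- overlap_test(a, b, universe)
  expect_equal(r$overlap_size, 4)
  # exact: (C(5,4) C(15,2) + C(5,5) C(15,1)) / C(20,6) = 540/38760
  expect_equal(r$p_hypergeometric, 540 / 38760, tolerance = 1e-12)

  # zero overlap where 0 is attainable: p = 1
  r0 <- overlap_test(universe[1:3], universe[10:12], universe)
  expect_equal(r0$overlap_size, 0)
  expect_equal(r0$p_hypergeometric, 1)

  expect_error(overlap_test(c(a, "zzz"), b, universe), "subsets")
})

test_that("overlap p is monotone non-increasing in the overlap size", {
  N <- 100; nA <- 20; nB <- 30
  universe <- paste0("g", 1:N)
  ps <- vapply(5:15, function(m) {
    a <- universe[1:nA]
    b <- c(universe[1:m], universe[(nA + 1):(nA + nB - m)])
    overlap_test(a, b, universe)$p_hypergeometric
  }, numeric(1))
  expect_true(all(diff(ps) < 0))
})

test_that("overlap p agrees with a label-permutation Monte-Carlo oracle", {
  set.seed(61)
  universe <- paste0("g", 1:30)
  a <- sample(universe, 8)
  b <- sample(universe, 10)
  r <- overlap_test(a, b, universe)
  ndraw <- 1e5
  draws <- replicate(ndraw,
    length(intersect(a, sample(universe, 10))) >= r$overlap_size)
  p_mc <- mean(draws)
  se <- sqrt(p_mc * (1 - p_mc) / ndraw)
  expect_lt(abs(r$p_hypergeometric - p_mc), 3 * se + 1e-8)
})

test_that("reciprocity classification tallies direction combinations", {
  dirs_a <- c(g1 = "up", g2 = "down", g3 = "up", g4 = "down")
  dirs_b <- c(g1 = "down", g2 = "up", g3 = "up", g4 = "up")
  r <- classify_reciprocity(names(dirs_a), dirs_a, dirs_b)
  expect_equal(r$ud, 1)
  expect_equal(r$du, 2)
  expect_equal(r$uu, 1)
  expect_equal(r$dd, 0)
  expect_equal(r$reciprocal, 3)
  expect_equal(r$uu + r$dd + r$ud + r$du, r$m)

  # swapping the studies swaps ud and du, reciprocal total unchanged
  rs <- classify_reciprocity(names(dirs_a), dirs_b, dirs_a)
  expect_equal(rs$ud, r$du)
  expect_equal(rs$du, r$ud)
  expect_equal(rs$reciprocal, r$reciprocal)

  expect_error(classify_reciprocity(c("g1", "gX"), dirs_a, dirs_b),
               "missing direction")
})

test_that("reciprocity binomial tail is exact and matches simulation", {
  expect_equal(reciprocity_test(10, 10), 2^-10)
  expect_equal(reciprocity_test(0, 10), 1)
  expect_error(reciprocity_test(11, 10), "out of range")

  p <- reciprocity_test(15, 20)
  set.seed(67)
  ndraw <- 1e6
  # independent oracle: per-gene fair coin flips for the direction pattern
  k <- rbinom(ndraw, 20, 0.5)
  p_mc <- mean(k >= 15)
  se <- sqrt(p_mc * (1 - p_mc) / ndraw)
  expect_lt(abs(p - p_mc), 3 * se)
})

test_that("regulatory domains follow the basal-plus-extension rule", {
  genes <- data.frame(gene_id = c("gA", "gB"), chrom = "chr1",
                      strand = "+", tss = c(100000, 400000))
  d <- regulatory_domains(genes)
  # basal: 5 kb upstream, 1 kb downstream on + strand
  expect_equal(d$basal_start[1], 95000)
  expect_equal(d$basal_end[1], 101000)
  # extension stops at the neighbor's basal domain
  expect_equal(d$dom_end[1], 395000)
  expect_equal(d$dom_start[2], 101000)
  # and is capped at max_ext elsewhere
  expect_equal(d$dom_start[1], 0)  # 95000 - 1e6 clipped at chromosome start
  expect_equal(d$dom_end[2], 401000 + 1e6)

  # minus-strand basal is mirrored
  dm <- regulatory_domains(data.frame(gene_id = "gC", chrom = "chr1",
                                      strand = "-", tss = 50000))
  expect_equal(dm$basal_start, 50000 - 1000 + 1)
  expect_equal(dm$basal_end, 50000 + 5000 + 1)

  # adjacent same-chromosome extended domains only share the gap
  set.seed(71)
  g <- data.frame(gene_id = paste0("g", 1:30), chrom = "chr1",
                  strand = sample(c("+", "-"), 30, TRUE),
                  tss = sort(sample.int(5e6, 30)) * 3)
  dd <- regulatory_domains(g)
  dd <- dd[order(dd$basal_start), ]
  expect_true(all(dd$dom_start <= dd$basal_start))
  expect_true(all(dd$dom_end >= dd$basal_end))
  # extension (beyond a gene's own basal domain) never reaches inside a
  # neighbor's basal domain
  for (i in 2:nrow(dd))
    expect_gte(dd$dom_start[i],
               min(dd$basal_start[i], max(dd$basal_end[seq_len(i - 1)])))
})

test_that("peak assignment matches the worked domain examples", {
  gene <- data.frame(gene_id = "gA", chrom = "chr1", strand = "+",
                     tss = 100000)
  peak <- data.frame(chrom = "chr1", start = 96000, end = 96500)
  a <- assign_peaks(peak, gene)
  expect_equal(nrow(a), 1)
  expect_equal(a$gene_id, "gA")
  expect_equal(a$signed_distance_bp, -3750)

  # beyond the 1 Mb cap: no association
  far <- data.frame(chrom = "chr1", start = 2200000, end = 2200400)
  expect_equal(nrow(assign_peaks(far, gene)), 0)

  # midpoint between two extended domains is associated with both
  genes2 <- data.frame(gene_id = c("gA", "gB"), chrom = "chr1",
                       strand = "+", tss = c(100000, 400000))
  mid <- data.frame(chrom = "chr1", start = 249800, end = 250200)
  a2 <- assign_peaks(mid, genes2)
  expect_setequal(a2$gene_id, c("gA", "gB"))
  expect_equal(sort(a2$signed_distance_bp), c(-150000, 150000))

  # strand-aware sign: same peak is downstream of a minus-strand gene
  gm <- data.frame(gene_id = "gM", chrom = "chr1", strand = "-",
                   tss = 100000)
  am <- assign_peaks(peak, gm)
  expect_equal(am$signed_distance_bp, 3750)

  expect_error(assign_peaks(data.frame(chrom = "chr1", start = 5,
                                       end = 5), gene), "malformed")
})

test_that("association distances never exceed cap plus basal span", {
  p <- peak_sim_params(genome_length_bp = 5e7, n_genes = 40, n_peaks = 60,
                       fraction_in_domains = 0.7, seed = 73)
  s <- sim_peaks_genes(p)
  a <- assign_peaks(s$peaks, s$genes)
  expect_true(all(abs(a$signed_distance_bp) <= 1e6 + 6000))
})

test_that("TSS distance histogram bins signed distances", {
  assocs <- data.frame(signed_distance_bp = c(0, -60000, 2000, -3000,
                                              600000, -700))
  h <- tss_distance_histogram(assocs)
  expect_equal(sum(h$fraction), 1)
  # distance 0 counts as downstream [0,5) kb
  expect_equal(h$count[h$side == "downstream" & h$bin == "[0,5)"], 2)
  # -60 kb falls in upstream [50,500)
  expect_equal(h$count[h$side == "upstream" & h$bin == "[50,500)"], 1)
  expect_equal(h$count[h$side == "downstream" & h$bin == "[500,Inf)"], 1)
  expect_error(tss_distance_histogram(assocs[0, , drop = FALSE]), "no assoc")

  set.seed(79)
  r <- data.frame(signed_distance_bp = rnorm(500, 0, 2e5))
  expect_equal(sum(tss_distance_histogram(r)$fraction), 1)
})

test_that("three-way intersection filters by presence and direction", {
  a <- list(up = c("g1", "g3"), down = c("g2"))
  b <- list(up = c("g2", "g4"), down = c("g1", "g3"))
  expect_equal(three_way_intersect(character(0), a, b), character(0))
  expect_equal(three_way_intersect(c("g1", "g9"), a, b), "g1")
  # g1: up in A, down in B -> reciprocal; g3 same; g2 reciprocal too
  expect_equal(three_way_intersect(c("g1", "g2", "g3"), a, b,
                                   require_reciprocal = TRUE),
               c("g1", "g2", "g3"))
  # concordant gene excluded under the reciprocal requirement
  b2 <- list(up = c("g1"), down = character(0))
  expect_equal(three_way_intersect("g1", a, b2, require_reciprocal = TRUE),
               character(0))
  expect_equal(three_way_intersect("g1", a, b2), "g1")
})
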