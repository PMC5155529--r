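# shared fixtures, all built in code

# noiseless, perfectly regular breathing: 180/min for 10 s
noiseless_sim <- function(seed = 7) {
  sim_breath_trace(breath_sim_params(
    duration_s = 10, vf_mean = 180, ibi_cv = 0, amp_cv = 0, p_apnea = 0,
    noise_sd = 0, seed = seed))
}

# a pressure trace with given epochs/mask but trivial signal, for window
# selection tests
dummy_trace <- function(duration_s, epochs, mask = NULL, fs = 10) {
  pressure_trace(numeric(duration_s * fs), fs, epochs = epochs,
                 artifact_mask = mask)
}

room_air_epoch <- function(end_s, start_s = 0)
  data.frame(label = "room_air", start_s = start_s, end_s = end_s)

# independent brute-force BH step-up: sort, multiply by m/rank, cumulative
# min from the largest, clip to 1, restore order
bh_brute <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  pmin(adj, 1)[order(o)]
}

# planted-target end-to-end fixture: paired expression studies plus peaks
# in the basal domains of a few reciprocal genes
triangulation_fixture <- function(seed, n_targets = 8) {
  ep <- expr_pair_sim_params(samples_per_group = 10, seed = seed)
  sim <- sim_expression_pair(ep)
  targets <- sim$truth$reciprocal_genes[seq_len(n_targets)]
  pk <- peak_sim_params(genome_length_bp = 1e8, n_genes = 2000,
                        n_peaks = 40, fraction_in_domains = 0.5,
                        seed = seed + 1000L)
  pg <- sim_peaks_genes(pk, gene_ids = sim$truth$universe,
                        target_gene_ids = targets)
  list(sim = sim, peaks = pg, targets = sort(targets))
}
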