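# Shared fixture builders; everything is generated in code under fixed
# seeds so no binary data ships with the package.

# small simulated two-condition study (trisomic chr21 block at 1.5x)
small_study <- function(seed = 1, n_genes = 2000, replicates = 3,
                        a = 0.01, b = 1, trisomy_a = a, trisomy_b = b,
                        chr21_fraction = 0.05, depth_scale = 1,
                        dosage_override = NULL, zero_fraction = 0.2) {
  gen <- generate_mean_profile(n_genes = n_genes,
                               chr21_fraction = chr21_fraction,
                               zero_fraction = zero_fraction, seed = seed)
  cfg <- simulation_config(a = a, b = b, trisomy_a = trisomy_a,
                           trisomy_b = trisomy_b, replicates = replicates,
                           depth_scale = depth_scale,
                           seed = derive_seed(seed, 7))
  ds <- simulate_experiment(gen$profile, gen$annotation, cfg,
                            dosage_override = dosage_override)
  list(gen = gen, config = cfg, ds = ds)
}

# single-gene NB draws through the simulator machinery: a profile with one
# expressed gene and many replicates of one condition
draws_for <- function(mu, a, b, n_draws, seed = 1, depth_scale = 1,
                      trisomic = FALSE) {
  profile <- data.frame(gene_id = c("target", "filler"), mu = c(mu, 5))
  annotation <- data.frame(gene_id = c("target", "filler"),
                           chromosome = c(if (trisomic) "chr21" else "chr1",
                                          "chr2"),
                           ploidy_X = c(if (trisomic) 3L else 2L, 2L),
                           repeat_flag = FALSE)
  cfg <- simulation_config(a = a, b = b, replicates = n_draws,
                           depth_scale = depth_scale, seed = seed)
  counts <- simulate_counts(profile, annotation, cfg, "X")
  counts["target", ]
}

# brute-force BH step-up, straight from the definition
bh_bruteforce <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  out <- numeric(m)
  out[o] <- pmin(1, adj)
  out
}
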