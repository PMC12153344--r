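# synthetic_data: genome generation, site planting, count simulation,
# titrations, and the packaged fixture.

test_that("simulate_genome is deterministic and honours GC bounds", {
  cfg <- simulation_config(genome_length = 1000, gc_fraction = 0.5,
                           rng_seed = 1)
  expect_identical(simulate_genome(cfg), simulate_genome(cfg))

  only_gc <- simulate_genome(simulation_config(genome_length = 500,
                                               gc_fraction = 1, rng_seed = 2))
  expect_true(grepl("^[GC]+$", only_gc[[1]]))
  only_at <- simulate_genome(simulation_config(genome_length = 500,
                                               gc_fraction = 0, rng_seed = 2))
  expect_true(grepl("^[AT]+$", only_at[[1]]))

  g <- simulate_genome(simulation_config(genome_length = 50000,
                                         gc_fraction = 0.4, rng_seed = 7))
  bases <- strsplit(g[[1]], "")[[1]]
  gc <- mean(bases %in% c("G", "C"))
  expect_gte(gc, 0.37)
  expect_lte(gc, 0.43)
})

test_that("simulation_config validates its invariants", {
  expect_error(simulation_config(genome_length = 50), "genome_length")
  expect_error(simulation_config(gc_fraction = 1.2), "gc_fraction")
  expect_error(simulation_config(seq_error_rate = -0.1), "seq_error_rate")
  expect_error(simulation_config(editing_fractions = c(0.5, 0.5)),
               "one value per planted site")
  expect_error(simulation_config(rng_seed = NA), "seed")
  expect_error(simulation_config(depth_dispersion = 0), "depth_dispersion")
})

test_that("plant_sites writes perfect and fully-deviated cis-elements", {
  fac <- synthetic_factor()
  tab <- synthetic_scoring_table()
  rng <- factor_score_range(fac, tab)
  cfg <- simulation_config(genome_length = 400, rng_seed = 5)
  g <- simulate_genome(cfg)

  perfect <- planted_sites(100, "+", 0.5, 0L)
  gp <- plant_sites(g, fac, tab, perfect, seed = 3)
  expect_equal(score_site(fac, tab, gp, 100, "+")$total, rng$max)

  worst <- planted_sites(100, "+", 0.5, 14L)  # all scored motifs deviate
  gw <- plant_sites(g, fac, tab, worst, seed = 3)
  expect_equal(score_site(fac, tab, gw, 100, "+")$total, rng$min)

  minus <- planted_sites(200, "-", 0.5, 0L)
  gm <- plant_sites(g, fac, tab, minus, seed = 3)
  expect_identical(substr(gm[[1]], 200, 200), "G")  # complement of edited C
  expect_equal(score_site(fac, tab, gm, 200, "-")$total, rng$max)
})

test_that("plant_sites rejects overlapping windows and out-of-bounds sites", {
  fac <- synthetic_factor()
  tab <- synthetic_scoring_table()
  g <- simulate_genome(simulation_config(genome_length = 300, rng_seed = 1))
  expect_error(
    plant_sites(g, fac, tab, planted_sites(c(100, 120), "+", 0.5, 0L)),
    "overlap")
  expect_error(
    plant_sites(g, fac, tab, planted_sites(10, "+", 0.5, 0L)),
    "bounds")
  expect_error(
    plant_sites(g, fac, tab, planted_sites(100, "+", 0.5, 15L)),
    "deviations")
})

test_that("simulate_counts: clean recovery, determinism, conservation", {
  fac <- synthetic_factor()
  tab <- synthetic_scoring_table()
  cfg <- simulation_config(genome_length = 300, depth_mean = 10000,
                           depth_dispersion = Inf, seq_error_rate = 0,
                           n_target_sites = 1, n_decoy_sites = 0,
                           editing_fractions = 0.5, rng_seed = 4)
  sites <- planted_sites(150, "+", 0.5, 0L)
  g <- plant_sites(simulate_genome(cfg), fac, tab, sites, seed = 4)

  counts <- simulate_counts(g, sites, cfg, "rna", "s1", seed = 8)
  expect_identical(counts, simulate_counts(g, sites, cfg, "rna", "s1",
                                           seed = 8))

  # with no error, only the planted site carries alternate reads
  alt_plus <- counts$fT + counts$rA
  expect_true(all(alt_plus[-150][counts$ref[-150] == "C"] == 0))
  f_hat <- alt_plus[150] / (counts$fC[150] + counts$rG[150] + alt_plus[150])
  expect_gte(f_hat, 0.47)  # binomial 99% interval at depth 10000
  expect_lte(f_hat, 0.53)

  # fraction forced to zero for control roles
  dna <- simulate_counts(g, sites, cfg, "dna_control", "dna", seed = 9)
  expect_identical(sum(dna$fT[150], dna$rA[150]), 0L)
})

test_that("dna_control mismatch fraction matches the stated error rate", {
  cfg <- simulation_config(genome_length = 10000, depth_mean = 300,
                           seq_error_rate = 0.001, n_target_sites = 0,
                           n_decoy_sites = 0, editing_fractions = numeric(0),
                           rng_seed = 6)
  g <- simulate_genome(cfg)
  none <- planted_sites(integer(0), character(0), numeric(0))
  dna <- simulate_counts(g, none, cfg, "dna_control", "dna", seed = 10)
  tot <- cbind(A = dna$fA + dna$rT, C = dna$fC + dna$rG,
               G = dna$fG + dna$rC, T = dna$fT + dna$rA)
  depth <- rowSums(tot)
  ref_n <- tot[cbind(seq_len(nrow(tot)), match(dna$ref, colnames(tot)))]
  mism <- sum(depth - ref_n) / sum(depth)
  expect_gt(mism, 0.0009)
  expect_lt(mism, 0.0011)
})

test_that("planted fractions are recovered within 3 binomial SD (error = 0)", {
  w <- planted_world(seed = 21, depth_mean = 1000, seq_error_rate = 0)
  cand <- w$candidates
  for (i in seq_len(nrow(w$sites))) {
    j <- match(w$sites$position[i], cand$pos)
    expect_false(is.na(j))
    tf <- w$sites$true_fraction[i]
    sd3 <- 3 * sqrt(tf * (1 - tf) / cand$depth[j])
    expect_lt(abs(cand$f_rna[j] - tf), sd3)
  }
})

test_that("simulate_titration follows the closed-form isotherm", {
  half <- simulate_titration(0.7, 1, 0.7, noise_sd = 0)
  expect_equal(half$fraction_bound, 0.5)
  zero <- simulate_titration(0.7, 1, 0, noise_sd = 0)
  expect_equal(zero$fraction_bound, 0)

  conc <- seq(0.1, 4, length.out = 12)
  curve <- simulate_titration(0.5, 0.9, conc, noise_sd = 0)
  expect_equal(curve$fraction_bound, 0.9 * conc / (0.5 + conc),
               tolerance = 1e-12)
  expect_error(simulate_titration(-1, 1, conc), "kd")
  expect_error(simulate_titration(0.5, 1, c(-1, 1, 2)), "non-negative")
})

test_that("packaged cross-sample fixture matches its printed summaries", {
  m <- transcribe_table2_fixture()
  expect_s3_class(m, "cross_sample_matrix")
  expect_identical(sum(!m$sites$is_target), 34L)
  expect_equal(m$extent["rpoA", "sample14"], 4.5)
  expect_identical(m$n_samples[m$sites$site_id == "1838803"], 8)
  # every declared n_samples equals the per-row flag count by construction
  expect_identical(unname(rowSums(m$flag)), as.numeric(m$n_samples))
})
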