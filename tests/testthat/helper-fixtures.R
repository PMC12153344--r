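# Shared fixtures: an independent G-test oracle, small hand-built objects,
# and the simulation worlds used by the property and acceptance suites.

# Independent brute-force G-statistic for a 2x2 table, written cell by cell
# from the definition (margins -> expected counts -> 2 * sum O ln(O/E)).
# Deliberately structured differently from the package implementation.
oracle_g2x2 <- function(tab) {
  stopifnot(is.matrix(tab), all(dim(tab) == c(2L, 2L)))
  n <- sum(tab)
  g <- 0
  for (i in 1:2) {
    for (j in 1:2) {
      o <- tab[i, j]
      if (o > 0) {
        e <- sum(tab[i, ]) * sum(tab[, j]) / n
        g <- g + o * log(o / e)
      }
    }
  }
  2 * g
}

oriented <- function(ref, alt, other = 0, strand = "+") {
  # build an oriented_counts via the public constructor path
  if (strand == "+") {
    site <- list(ref = "C", fA = 0, fC = ref, fG = other, fT = alt,
                 rA = 0, rC = 0, rG = 0, rT = 0)
  } else {
    site <- list(ref = "G", fA = alt, fC = other, fG = ref, fT = 0,
                 rA = 0, rC = 0, rG = 0, rT = 0)
  }
  orient_counts(site, strand)
}

make_candidates <- function(pos, f_rna = 0.2, f_dna = 0, depth = 500,
                            score = NULL, strand = "+", sample = "s1",
                            chrom = "sim_chr") {
  n <- length(pos)
  if (is.null(score)) score <- 10 * f_rna * depth + 1
  data.frame(chrom = chrom, pos = as.integer(pos),
             strand = rep_len(strand, n), f_rna = rep_len(f_rna, n),
             f_dna = rep_len(f_dna, n), depth = rep_len(depth, n),
             score = rep_len(score, n), sample = sample,
             stringsAsFactors = FALSE)
}

# Property/acceptance world: no editing anywhere, error only.
null_world <- function(seed, genome_length = 2000, depth_mean = 300,
                       seq_error_rate = 0.001, n_rna = 3, n_neg = 2) {
  cfg <- simulation_config(genome_length = genome_length,
                           depth_mean = depth_mean,
                           seq_error_rate = seq_error_rate,
                           n_target_sites = 0, n_decoy_sites = 0,
                           editing_fractions = numeric(0), rng_seed = seed)
  g <- simulate_genome(cfg)
  none <- planted_sites(integer(0), character(0), numeric(0))
  dna <- simulate_counts(g, none, cfg, "dna_control", "dna",
                         seed = seed * 101 + 1)
  cands <- lapply(seq_len(n_rna), function(i) {
    rna <- simulate_counts(g, none, cfg, "rna", paste0("s", i),
                           seed = seed * 101 + 1 + i)
    suppressMessages(call_candidates(g, rna, dna))
  })
  names(cands) <- paste0("s", seq_len(n_rna))
  ctrl <- lapply(seq_len(n_neg), function(i) {
    nc <- simulate_counts(g, none, cfg, "negative_control", paste0("n", i),
                          seed = seed * 101 + 10 + i)
    suppressMessages(call_candidates(g, nc, dna))
  })
  list(config = cfg, genome = g, candidates = cands, controls = ctrl)
}

# Property/acceptance world: 5 planted zero-deviation sites, one RNA sample.
planted_world <- function(seed, genome_length = 2000, depth_mean = 500,
                          seq_error_rate = 0.001,
                          fractions = c(0.05, 0.1, 0.2, 0.4, 0.8)) {
  fac <- synthetic_factor()
  tab <- synthetic_scoring_table()
  cfg <- simulation_config(genome_length = genome_length,
                           depth_mean = depth_mean,
                           seq_error_rate = seq_error_rate,
                           n_target_sites = 1,
                           n_decoy_sites = length(fractions) - 1L,
                           editing_fractions = fractions, rng_seed = seed)
  g <- simulate_genome(cfg)
  sites <- place_sites(cfg, deviations = rep(0L, length(fractions)))
  g <- plant_sites(g, fac, tab, sites, seed = seed)
  dna <- simulate_counts(g, sites, cfg, "dna_control", "dna",
                         seed = seed * 101 + 1)
  rna <- simulate_counts(g, sites, cfg, "rna", "s1", seed = seed * 101 + 2)
  cand <- suppressMessages(call_candidates(g, rna, dna))
  list(config = cfg, genome = g, sites = sites, factor = fac, table = tab,
       candidates = cand)
}

# Maximum / minimum attainable total score of the synthetic factor under
# the synthetic table, computed directly from the table rows.
factor_score_range <- function(fac = synthetic_factor(),
                               tab = synthetic_scoring_table()) {
  al <- align_offsets(fac)
  entries <- tab$entries
  pairs <- paste0(al$aa5, al$aa_last)
  scored <- pairs %in% rownames(entries)
  rows <- entries[pairs[scored], , drop = FALSE]
  list(max = sum(apply(rows, 1, max)), min = sum(apply(rows, 1, min)))
}

write_counts_tsv <- function(df, dir = tempdir(),
                             name = paste0(df$sample[1] %||% "t", ".tsv")) {
  path <- file.path(dir, name)
  write_site_counts(df, path)
  path
}

`%||%` <- function(a, b) if (is.null(a) || length(a) == 0L) b else a
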