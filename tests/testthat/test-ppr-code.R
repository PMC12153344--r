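# ppr_code: scoring tables, factor alignment, site profiles, genome scan.

test_that("scoring table I/O validates and round-trips", {
  tab <- synthetic_scoring_table()
  nd <- tab$entries["ND", ]
  expect_length(nd, 4L)
  expect_true(all(is.finite(nd)))

  # wrong number of nucleotide columns
  bad <- tempfile(fileext = ".tsv")
  writeLines(c("pair\tA\tC\tG", "ND\t1\t0\t0"), bad)
  expect_error(read_scoring_table(bad), "4 nucleotide columns")

  dup <- tempfile(fileext = ".tsv")
  writeLines(c("pair\tA\tC\tG\tU", "ND\t1\t0\t0\t0", "ND\t0\t1\t0\t0"), dup)
  expect_error(read_scoring_table(dup), "duplicate")

  nonnum <- tempfile(fileext = ".tsv")
  writeLines(c("pair\tA\tC\tG\tU", "ND\t1\tx\t0\t0"), nonnum)
  expect_error(read_scoring_table(nonnum), "non-numeric")

  rt <- tempfile(fileext = ".tsv")
  write_scoring_table(tab, rt)
  expect_identical(read_scoring_table(rt)$entries, tab$entries)
})

test_that("ppr_factor validates architecture", {
  expect_error(ppr_factor("x", data.frame(motif_class = "Q", aa5 = "N",
                                          aa_last = "D")), "unknown motif")
  # binding motifs interrupted by a terminal domain are rejected
  bad <- data.frame(motif_class = c("P", "E1", "P"),
                    aa5 = c("T", "G", "T"), aa_last = c("N", "D", "N"))
  expect_error(ppr_factor("x", bad), "contiguous")
  expect_error(ppr_factor("x", data.frame(motif_class = "P", aa5 = "Nx",
                                          aa_last = "D")), "one-letter")
})

test_that("align_offsets lays out the motif ladder", {
  al <- align_offsets(synthetic_factor())
  binding <- al[!al$motif_class %in% c("E1", "E2"), ]
  expect_identical(range(binding$offset), c(-15L, -4L))
  expect_identical(nrow(binding), 12L)
  expect_identical(al$offset[al$motif_class == "E1"], -3L)
  expect_identical(al$offset[al$motif_class == "E2"], -2L)

  solo <- ppr_factor("solo", data.frame(motif_class = "P", aa5 = "T",
                                        aa_last = "N"))
  expect_identical(align_offsets(solo)$offset, -4L)
})

test_that("score_site profiles planted sites exactly", {
  fac <- synthetic_factor()
  tab <- synthetic_scoring_table()
  rng <- factor_score_range(fac, tab)
  g <- simulate_genome(simulation_config(genome_length = 300, rng_seed = 2))
  g <- plant_sites(g, fac, tab, planted_sites(150, "+", 0.5, 0L), seed = 1)

  p <- score_site(fac, tab, g, 150, "+")
  expect_equal(p$total, rng$max)
  expect_equal(p$total, sum(p$scores))  # additivity
  expect_length(p$offsets, 14L)

  # an all-zero table gives a zero, all-neutral profile
  zero <- scoring_table(matrix(0, nrow = nrow(tab$entries), ncol = 4,
                               dimnames = list(rownames(tab$entries),
                                               c("A", "C", "G", "U"))))
  pz <- score_site(fac, zero, g, 150, "+")
  expect_equal(pz$total, 0)
  expect_true(all(pz$classes == "neutral"))

  # mutating one window position drops the total by exactly that motif's
  # score difference
  bases <- strsplit(g[[1]], "")[[1]]
  for (k in c(1, 7, 14)) {
    off <- p$offsets[k]
    pair <- align_offsets(fac)
    row <- tab$entries[paste0(pair$aa5[pair$offset == off],
                              pair$aa_last[pair$offset == off]), ]
    old_nt <- p$nucleotides[k]
    new_nt <- setdiff(c("A", "C", "G", "U"), old_nt)[1]
    mutated <- bases
    mutated[150 + off] <- sub("U", "T", new_nt)
    gm <- stats::setNames(paste(mutated, collapse = ""), names(g))
    pm <- score_site(fac, tab, gm, 150, "+")
    expect_equal(p$total - pm$total, row[[old_nt]] - row[[new_nt]])
  }

  expect_error(score_site(fac, tab, g, 5, "+"), "bounds")
  not_c <- which(bases != "C")
  not_c <- not_c[not_c > 16][1]
  expect_error(score_site(fac, tab, g, not_c, "+"), "not C")
})

test_that("score_site is invariant under reverse complement", {
  fac <- synthetic_factor()
  tab <- synthetic_scoring_table()
  revcomp_chr <- function(s) {
    comp <- c(A = "T", C = "G", G = "C", T = "A")
    paste(rev(comp[strsplit(s, "")[[1]]]), collapse = "")
  }
  set.seed(7)
  for (i in 1:10) {
    g <- simulate_genome(simulation_config(genome_length = 200,
                                           rng_seed = 100 + i))
    bases <- strsplit(g[[1]], "")[[1]]
    pos <- which(bases == "C" & seq_along(bases) > 16)
    if (length(pos) == 0) next
    pos <- pos[1]
    p_fwd <- score_site(fac, tab, g, pos, "+")
    g_rc <- stats::setNames(revcomp_chr(g[[1]]), names(g))
    p_rev <- score_site(fac, tab, g_rc, 200 - pos + 1, "-")
    expect_equal(p_fwd$total, p_rev$total)
    expect_identical(p_fwd$nucleotides, p_rev$nucleotides)
  }
})

test_that("scan_genome ranks planted perfect matches first", {
  fac <- synthetic_factor()
  tab <- synthetic_scoring_table()
  rng <- factor_score_range(fac, tab)
  cfg <- simulation_config(genome_length = 3000, n_target_sites = 3,
                           n_decoy_sites = 0,
                           editing_fractions = rep(0.5, 3), rng_seed = 12)
  sites <- place_sites(cfg, deviations = rep(0L, 3))
  g <- plant_sites(simulate_genome(cfg), fac, tab, sites, seed = 12)
  hits <- scan_genome(fac, tab, g)
  expect_identical(sort(hits$pos[1:3]), sort(sites$position))
  expect_true(all(hits$total[1:3] == rng$max))
  expect_true(all(diff(hits$total) <= 0))  # sorted descending

  # no C on either strand -> nothing to score
  polyA <- c(chr = strrep("A", 100))
  expect_identical(nrow(scan_genome(fac, tab, polyA)), 0L)

  # unreachable threshold -> empty
  expect_identical(nrow(scan_genome(fac, tab, g, min_total = Inf)), 0L)
})
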