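# editing_detection: TSV ingest, strand collapse, fractions, the
# G-statistic score, and candidate calling.

counts_header <- paste(c("chrom", "pos", "ref", "fA", "fC", "fG", "fT",
                         "rA", "rC", "rG", "rT", "sample"), collapse = "\t")

write_lines_tsv <- function(lines) {
  path <- tempfile(fileext = ".tsv")
  writeLines(lines, path)
  path
}

test_that("read_site_counts parses valid tables and rejects malformed ones", {
  empty <- write_lines_tsv(counts_header)
  expect_identical(nrow(read_site_counts(empty)), 0L)

  three <- write_lines_tsv(c(
    counts_header,
    "chr1\t5\tC\t0\t90\t0\t10\t0\t0\t0\t0\ts1",
    "chr1\t7\tG\t5\t0\t80\t0\t0\t0\t0\t0\ts1",
    "chr1\t9\tA\t50\t0\t0\t0\t0\t0\t0\t0\ts1"))
  df <- read_site_counts(three)
  expect_identical(nrow(df), 3L)
  expect_identical(df$pos, c(5L, 7L, 9L))

  bad_ref <- write_lines_tsv(c(counts_header,
                               "chr1\t5\tN\t0\t1\t0\t0\t0\t0\t0\t0\ts1"))
  expect_error(read_site_counts(bad_ref), "ref base 'N'.*line 2")

  neg <- write_lines_tsv(c(counts_header,
                           "chr1\t5\tC\t0\t-3\t0\t0\t0\t0\t0\t0\ts1"))
  expect_error(read_site_counts(neg), "negative count.*line 2")

  wrong_header <- write_lines_tsv("chrom\tpos\tref")
  expect_error(read_site_counts(wrong_header), "header")
})

test_that("orient_counts collapses orientation and checks the ref base", {
  plus <- orient_counts(list(ref = "C", fA = 0, fC = 90, fG = 0, fT = 10,
                             rA = 0, rC = 0, rG = 0, rT = 0), "+")
  expect_equal(plus$ref_count, 90)
  expect_equal(plus$alt_count, 10)
  expect_equal(plus$other_count, 0)

  minus <- orient_counts(list(ref = "G", fA = 20, fC = 0, fG = 80, fT = 0,
                              rA = 0, rC = 0, rG = 0, rT = 0), "-")
  expect_equal(minus$ref_count, 80)
  expect_equal(minus$alt_count, 20)

  with_other <- orient_counts(list(ref = "C", fA = 0, fC = 50, fG = 20,
                                   fT = 30, rA = 0, rC = 0, rG = 0, rT = 0),
                              "+")
  expect_equal(with_other$other_count, 20)
  expect_equal(with_other$depth, 100)

  expect_error(orient_counts(list(ref = "C", fA = 0, fC = 1, fG = 0, fT = 0,
                                  rA = 0, rC = 0, rG = 0, rT = 0), "-"),
               "inconsistent")
})

test_that("orientation collapse: reads may move between orientations", {
  # a forward read of base b is equivalent to a reverse read reporting
  # comp(b); shuffling reads between the two maps never changes the result
  base_site <- list(ref = "C", fA = 1, fC = 73, fG = 2, fT = 24,
                    rA = 0, rC = 0, rG = 0, rT = 0)
  f0 <- editing_fraction(orient_counts(base_site, "+"))
  set.seed(42)
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  for (rep in 1:25) {
    moved <- list(ref = "C", fA = 0, fC = 0, fG = 0, fT = 0,
                  rA = 0, rC = 0, rG = 0, rT = 0)
    for (b in c("A", "C", "G", "T")) {
      n <- base_site[[paste0("f", b)]]
      k <- if (n > 0) sample(0:n, 1) else 0
      moved[[paste0("f", b)]] <- n - k
      moved[[paste0("r", comp[[b]])]] <- moved[[paste0("r", comp[[b]])]] + k
    }
    o <- orient_counts(moved, "+")
    expect_equal(editing_fraction(o), f0)
    expect_equal(o$depth, 100)
  }
})

test_that("editing_fraction matches the printed two-peak ratio", {
  expect_equal(editing_fraction(oriented(100, 0)), 0)
  expect_equal(editing_fraction(oriented(50, 50)), 0.5)
  # ref 181, alt 819: the 81.9% target extent printed for sample 6
  expect_equal(editing_fraction(oriented(181, 819)), 0.819)
  expect_error(editing_fraction(oriented(0, 0, other = 10)), "undefined")
})

test_that("site_score equals the brute-force G oracle", {
  # proportionally identical compositions score zero
  expect_equal(site_score(oriented(90, 10), oriented(900, 100)), 0)

  # one worked example against the cell-by-cell oracle
  expect_equal(site_score(oriented(50, 50), oriented(100, 0)),
               oracle_g2x2(matrix(c(50, 100, 50, 0), 2)), tolerance = 1e-12)

  # monotonicity in the RNA editing fraction at equal depths
  expect_lt(site_score(oriented(90, 10), oriented(100, 0)),
            site_score(oriented(50, 50), oriented(100, 0)))

  # label symmetry
  expect_equal(site_score(oriented(70, 30), oriented(95, 5)),
               site_score(oriented(95, 5), oriented(70, 30)))

  expect_error(site_score(oriented(0, 0, other = 5), oriented(10, 0)),
               "depth")
})

test_that("site_score matches the oracle on 1000 random tables to 1e-9", {
  set.seed(123)
  for (i in 1:1000) {
    tab <- matrix(sample(0:200, 4, replace = TRUE), 2)
    if (sum(tab[1, ]) == 0 || sum(tab[2, ]) == 0) next
    got <- site_score(oriented(tab[1, 1], tab[1, 2]),
                      oriented(tab[2, 1], tab[2, 2]))
    expect_equal(got, max(oracle_g2x2(tab), 0), tolerance = 1e-9)
  }
})

test_that("call_candidates selects C(+) and G(-) sites covered in both tables", {
  g <- c(chr = "ACGT")
  mk <- function(sample) data.frame(
    chrom = "chr", pos = 1:4, ref = c("A", "C", "G", "T"),
    fA = c(50, 0, 0, 0), fC = c(0, 50, 0, 0), fG = c(0, 0, 50, 0),
    fT = c(0, 0, 0, 50), rA = 0, rC = 0, rG = 0, rT = 0,
    sample = sample, stringsAsFactors = FALSE)
  cand <- call_candidates(g, mk("rna"), mk("dna"))
  expect_identical(cand$pos, 2:3)
  expect_identical(cand$strand, c("+", "-"))
  expect_equal(cand$f_rna, c(0, 0))
  expect_equal(cand$score, c(0, 0))

  # site absent from the DNA table is skipped
  dna_partial <- mk("dna")[-2, ]
  expect_message(cand2 <- call_candidates(g, mk("rna"), dna_partial),
                 "skipped 1")
  expect_identical(cand2$pos, 3L)
})

test_that("with no error exactly the planted sites show editing", {
  w <- planted_world(seed = 31, seq_error_rate = 0)
  cand <- w$candidates
  expect_identical(sort(cand$pos[cand$f_rna > 0]),
                   sort(w$sites$position))
  expect_true(all(cand$f_dna == 0))
})

test_that("null simulations centre f_RNA - f_DNA at zero", {
  w <- null_world(seed = 77, genome_length = 5000, n_rna = 1, n_neg = 0)
  d <- w$candidates$s1$f_rna - w$candidates$s1$f_dna
  se <- stats::sd(d) / sqrt(length(d))
  expect_lt(abs(mean(d)), 2 * se + 1e-12)
})
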