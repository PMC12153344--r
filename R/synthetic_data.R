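# Synthetic-data generation: genome, planted cis-elements, stranded count
# tables, binding titrations, and the packaged cross-sample fixture.
#
# The generator emulates the statistical structure the downstream filters
# assume: per-site depths from a negative-binomial law, binomially edited
# read counts at planted sites, and strand-symmetric uniform sequencing
# error.  It does not simulate reads, alignment artifacts, or library-prep
# biases.

#' Simulation configuration
#'
#' Bundles the generative parameters for [simulate_genome()] and
#' [simulate_counts()] and validates their invariants.
#'
#' @param genome_length Genome length in bp (>= 100).
#' @param gc_fraction Target GC content, in `[0, 1]`.
#' @param n_target_sites Number of engineered (zero-deviation) target sites.
#' @param n_decoy_sites Number of decoy (off-target-like) sites with
#'   recognition-code deviations.
#' @param editing_fractions True editing fraction per planted site, one value
#'   per site (`n_target_sites + n_decoy_sites` in total).
#' @param depth_mean Mean per-position read depth.
#' @param depth_dispersion Negative-binomial dispersion (`size`); `Inf` gives
#'   Poisson depths.
#' @param seq_error_rate Per-base substitution error rate, spread uniformly
#'   over the three alternative bases and symmetric in read orientation.
#' @param rng_seed Integer seed; all randomness in the simulation flows from
#'   explicit seeds (no hidden global state).
#' @return An object of class `simulation_config` (a validated list).
#' @examples
#' cfg <- simulation_config(genome_length = 1000, rng_seed = 1)
#' @export
simulation_config <- function(genome_length = 10000,
                              gc_fraction = 0.51,
                              n_target_sites = 1,
                              n_decoy_sites = 4,
                              editing_fractions = c(0.8, 0.05, 0.1, 0.2, 0.4),
                              depth_mean = 300,
                              depth_dispersion = 20,
                              seq_error_rate = 0.001,
                              rng_seed = 1) {
  if (!is.numeric(genome_length) || length(genome_length) != 1L ||
      genome_length < 100) {
    stop("`genome_length` must be a single number >= 100", call. = FALSE)
  }
  assert_proportion(gc_fraction, "gc_fraction")
  assert_proportion(editing_fractions, "editing_fractions")
  assert_proportion(seq_error_rate, "seq_error_rate")
  if (n_target_sites < 0 || n_decoy_sites < 0) {
    stop("site counts must be non-negative", call. = FALSE)
  }
  n_sites <- n_target_sites + n_decoy_sites
  if (n_sites > 0 && length(editing_fractions) != n_sites) {
    stop("`editing_fractions` must have one value per planted site",
         call. = FALSE)
  }
  if (!is.numeric(depth_mean) || depth_mean <= 0) {
    stop("`depth_mean` must be positive", call. = FALSE)
  }
  if (!is.numeric(depth_dispersion) || depth_dispersion <= 0) {
    stop("`depth_dispersion` must be positive (Inf allowed)", call. = FALSE)
  }
  if (!is.numeric(rng_seed) || length(rng_seed) != 1L || is.na(rng_seed)) {
    stop("`rng_seed` is required and must be a single integer", call. = FALSE)
  }
  structure(
    list(genome_length = as.integer(genome_length),
         gc_fraction = gc_fraction,
         n_target_sites = as.integer(n_target_sites),
         n_decoy_sites = as.integer(n_decoy_sites),
         editing_fractions = editing_fractions,
         depth_mean = depth_mean,
         depth_dispersion = depth_dispersion,
         seq_error_rate = seq_error_rate,
         rng_seed = as.integer(rng_seed)),
    class = "simulation_config"
  )
}

#' Simulate a random genome sequence
#'
#' Draws an i.i.d. sequence over `{A, C, G, T}` with `P(G) = P(C) =
#' gc_fraction / 2` and `P(A) = P(T) = (1 - gc_fraction) / 2`.
#'
#' @param config A [simulation_config()].
#' @param name Sequence name used as the chromosome id.
#' @return A named character vector of length 1 (the genome).
#' @examples
#' g <- simulate_genome(simulation_config(genome_length = 200, rng_seed = 1))
#' nchar(g)
#' @export
simulate_genome <- function(config, name = "sim_chr") {
  stopifnot(inherits(config, "simulation_config"))
  p <- c(A = (1 - config$gc_fraction) / 2,
         C = config$gc_fraction / 2,
         G = config$gc_fraction / 2,
         T = (1 - config$gc_fraction) / 2)
  bases <- with_seed(config$rng_seed, {
    sample(DNA_BASES, config$genome_length, replace = TRUE, prob = p)
  })
  stats::setNames(paste(bases, collapse = ""), name)
}

#' Describe planted editing sites
#'
#' @param position 1-based genome coordinate of the edited C (transcript
#'   strand); on the `-` strand the genome forward strand carries a G there.
#' @param strand `"+"` or `"-"`, the transcript strand.
#' @param true_fraction True editing fraction per site.
#' @param n_code_deviations Number of cis-element positions deliberately
#'   mutated away from the factor's top-scoring nucleotide.
#' @return A `data.frame` with one row per site (class `planted_sites`).
#' @export
planted_sites <- function(position, strand, true_fraction,
                          n_code_deviations = 0L) {
  n <- length(position)
  strand <- rep_len(strand, n)
  true_fraction <- rep_len(true_fraction, n)
  n_code_deviations <- rep_len(as.integer(n_code_deviations), n)
  if (!all(strand %in% c("+", "-"))) {
    stop("`strand` must be '+' or '-'", call. = FALSE)
  }
  assert_proportion(true_fraction, "true_fraction")
  if (any(n_code_deviations < 0L)) {
    stop("`n_code_deviations` must be non-negative", call. = FALSE)
  }
  structure(
    data.frame(position = as.integer(position), strand = strand,
               true_fraction = true_fraction,
               n_code_deviations = n_code_deviations,
               stringsAsFactors = FALSE),
    class = c("planted_sites", "data.frame")
  )
}

# Engineered target fragment: 33 nt upstream and 5 nt downstream of the
# edited C.  Only used to keep planted windows in bounds and disjoint.
SITE_WINDOW_UP <- 33L
SITE_WINDOW_DOWN <- 5L

#' Randomly place planted sites on a genome
#'
#' Convenience helper used by the simulate subcommand: draws site positions
#' whose -33..+5 windows are in bounds and pairwise separated by at least
#' `min_separation` bp, with random strands.
#'
#' @param config A [simulation_config()].
#' @param seed Integer seed.
#' @param deviations Integer vector of recognition-code deviations per site;
#'   defaults to 0 for target sites and 2 for decoys.
#' @return A [planted_sites()] data frame.
#' @export
place_sites <- function(config, seed = config$rng_seed, deviations = NULL) {
  stopifnot(inherits(config, "simulation_config"))
  n <- config$n_target_sites + config$n_decoy_sites
  if (n == 0L) {
    return(planted_sites(integer(0), character(0), numeric(0), integer(0)))
  }
  if (is.null(deviations)) {
    deviations <- c(rep(0L, config$n_target_sites),
                    rep(2L, config$n_decoy_sites))
  }
  # safe for either strand: the engineered fragment reaches 33 bp both ways
  lo <- SITE_WINDOW_UP + 1L
  hi <- config$genome_length - SITE_WINDOW_UP
  if (hi - lo < (n - 1L) * 40L) {
    stop("genome too short to place sites >= 40 bp apart", call. = FALSE)
  }
  with_seed(seed, {
    repeat {
      pos <- sort(sample(lo:hi, n))
      strand <- sample(c("+", "-"), n, replace = TRUE)
      # engineered -33..+5 fragments must not overlap (strand-aware extents)
      ext_lo <- ifelse(strand == "+", pos - SITE_WINDOW_UP,
                       pos - SITE_WINDOW_DOWN)
      ext_hi <- ifelse(strand == "+", pos + SITE_WINDOW_DOWN,
                       pos + SITE_WINDOW_UP)
      if (n == 1L ||
          (all(diff(pos) >= 40L) && all(ext_lo[-1L] > ext_hi[-n]))) break
    }
    planted_sites(pos, strand, config$editing_fractions, deviations)
  })
}

#' Overwrite cis-elements at planted sites
#'
#' For every site, the scored window positions on the transcript strand are
#' overwritten with the factor's top-scoring nucleotide per aligned motif,
#' the edited position itself is set to C, and then `n_code_deviations`
#' randomly chosen window positions are mutated to that motif's
#' minimum-scoring nucleotide (the worst legal deviation, making score drops
#' deterministic).  Sites on the `-` strand are stored reverse-complemented
#' on the genome forward strand.
#'
#' @param genome Named character vector of length 1 (see
#'   [simulate_genome()]).
#' @param factor A [ppr_factor()].
#' @param table A [scoring_table()].
#' @param sites A [planted_sites()] data frame.
#' @param seed Integer seed governing which window positions deviate.
#' @return The modified genome (same shape as `genome`).
#' @export
plant_sites <- function(genome, factor, table, sites, seed = 1L) {
  stopifnot(is.character(genome), length(genome) == 1L)
  prefs <- motif_preferences(factor, table)
  offsets <- prefs$offset
  bases <- seq_to_bases(genome[[1L]])
  L <- length(bases)

  # windows in bounds and pairwise disjoint over the engineered fragment
  win_lo <- ifelse(sites$strand == "+",
                   sites$position - SITE_WINDOW_UP,
                   sites$position - SITE_WINDOW_DOWN)
  win_hi <- ifelse(sites$strand == "+",
                   sites$position + SITE_WINDOW_DOWN,
                   sites$position + SITE_WINDOW_UP)
  if (any(win_lo < 1L) || any(win_hi > L)) {
    stop("site window out of genome bounds", call. = FALSE)
  }
  if (nrow(sites) > 1L) {
    ord <- order(win_lo)
    if (any(win_lo[ord][-1L] <= win_hi[ord][-length(ord)])) {
      stop("planted site windows overlap", call. = FALSE)
    }
  }

  with_seed(seed, {
    for (i in seq_len(nrow(sites))) {
      pos <- sites$position[i]
      strand <- sites$strand[i]
      ndev <- sites$n_code_deviations[i]
      if (ndev > length(offsets)) {
        stop("n_code_deviations exceeds the number of scored motifs",
             call. = FALSE)
      }
      dev_idx <- if (ndev > 0L) sample(seq_along(offsets), ndev) else integer(0)
      written <- ifelse(seq_along(offsets) %in% dev_idx,
                        prefs$min_base_dna, prefs$top_base_dna)
      if (strand == "+") {
        bases[pos + offsets] <- written
        bases[pos] <- "C"
      } else {
        bases[pos - offsets] <- complement_base(written)
        bases[pos] <- "G"
      }
    }
  })
  stats::setNames(paste(bases, collapse = ""), names(genome))
}

#' Simulate a stranded per-site base-count table
#'
#' Per genome position, a depth is drawn from a negative-binomial law (mean
#' `depth_mean`, dispersion `depth_dispersion`; Poisson when the dispersion
#' is infinite).  At planted sites, in the `rna` role, the edited-base count
#' is Binomial(depth, `true_fraction`) on the transcript strand (C->T seen
#' forward, G->A seen on the genome strand for `-` sites).  Every read then
#' suffers a substitution error with probability `seq_error_rate`, uniform
#' over the three alternative bases, and is finally assigned a read
#' orientation (forward/reverse, each with probability 1/2); reverse-oriented
#' reads report the complement base, as in an RF-first-strand library.
#'
#' @inheritParams plant_sites
#' @param config A [simulation_config()].
#' @param role One of `"rna"`, `"dna_control"`, `"negative_control"`;
#'   control roles force all true fractions to zero.
#' @param sample_id Sample label written into the table.
#' @param seed Integer seed (defaults to `config$rng_seed`).
#' @return A site-count `data.frame` with columns `chrom, pos, ref, fA, fC,
#'   fG, fT, rA, rC, rG, rT, sample` (the on-disk TSV schema).
#' @export
simulate_counts <- function(genome, sites, config,
                            role = c("rna", "dna_control", "negative_control"),
                            sample_id = role, seed = config$rng_seed) {
  stopifnot(inherits(config, "simulation_config"))
  role <- match.arg(role)
  bases <- seq_to_bases(genome[[1L]])
  L <- length(bases)

  frac <- numeric(L)
  alt_base <- character(L)
  if (!is.null(sites) && nrow(sites) > 0L && role == "rna") {
    frac[sites$position] <- sites$true_fraction
    alt_base[sites$position] <- ifelse(sites$strand == "+", "T", "A")
  }

  e <- config$seq_error_rate
  counts <- with_seed(seed, {
    depth <- if (is.infinite(config$depth_dispersion)) {
      rpois(L, config$depth_mean)
    } else {
      rnbinom(L, mu = config$depth_mean, size = config$depth_dispersion)
    }
    n_alt <- rbinom(L, depth, frac)
    n_ref <- depth - n_alt

    # true (pre-error) counts per genome-forward base identity
    M <- matrix(0L, nrow = L, ncol = 4L, dimnames = list(NULL, DNA_BASES))
    for (b in DNA_BASES) {
      idx <- bases == b
      M[idx, b] <- M[idx, b] + n_ref[idx]
    }
    for (b in c("T", "A")) {
      idx <- alt_base == b
      M[idx, b] <- M[idx, b] + n_alt[idx]
    }

    # strand-symmetric substitution error, uniform over the 3 other bases
    if (e > 0) {
      for (b in DNA_BASES) {
        n_err <- rbinom(L, M[, b], e)
        M[, b] <- M[, b] - n_err
        others <- setdiff(DNA_BASES, b)
        x1 <- rbinom(L, n_err, 1 / 3)
        x2 <- rbinom(L, n_err - x1, 1 / 2)
        M[, others[1L]] <- M[, others[1L]] + x1
        M[, others[2L]] <- M[, others[2L]] + x2
        M[, others[3L]] <- M[, others[3L]] + (n_err - x1 - x2)
      }
    }

    # orientation split; reverse reads report the complement base
    fwd <- matrix(0L, nrow = L, ncol = 4L, dimnames = list(NULL, DNA_BASES))
    rev <- fwd
    for (b in DNA_BASES) {
      f <- rbinom(L, M[, b], 0.5)
      fwd[, b] <- f
      rev[, complement_base(b)] <- rev[, complement_base(b)] + (M[, b] - f)
    }
    list(fwd = fwd, rev = rev)
  })

  data.frame(
    chrom = names(genome)[1L], pos = seq_len(L), ref = bases,
    fA = counts$fwd[, "A"], fC = counts$fwd[, "C"],
    fG = counts$fwd[, "G"], fT = counts$fwd[, "T"],
    rA = counts$rev[, "A"], rC = counts$rev[, "C"],
    rG = counts$rev[, "G"], rT = counts$rev[, "T"],
    sample = sample_id, stringsAsFactors = FALSE
  )
}

#' Simulate a 1:1 binding titration
#'
#' `fraction_i = fmax * c_i / (kd + c_i) + N(0, noise_sd)`, clipped to
#' `[0, 1]`.
#'
#' @param kd Dissociation constant, in the units of `concentrations`
#'   (conventionally uM); must be positive.
#' @param fmax Saturating bound fraction.
#' @param concentrations Protein concentrations (>= 0).
#' @param noise_sd Gaussian noise standard deviation on the bound fraction.
#' @param seed Integer seed.
#' @param replicate_id Label carried through to the output.
#' @return A `data.frame` (class `titration_curve`) with columns
#'   `concentration`, `fraction_bound`, `replicate_id`.
#' @examples
#' simulate_titration(0.5, 1, c(0, 0.5, 2), noise_sd = 0, seed = 1)
#' @export
simulate_titration <- function(kd, fmax = 1, concentrations,
                               noise_sd = 0, seed = 1L,
                               replicate_id = "rep1") {
  if (!is.numeric(kd) || length(kd) != 1L || kd <= 0) {
    stop("`kd` must be a single positive number", call. = FALSE)
  }
  if (any(concentrations < 0)) {
    stop("`concentrations` must be non-negative", call. = FALSE)
  }
  fb <- fmax * concentrations / (kd + concentrations)
  if (noise_sd > 0) {
    fb <- with_seed(seed, fb + rnorm(length(fb), 0, noise_sd))
  }
  fb <- pmin(pmax(fb, 0), 1)
  structure(
    data.frame(concentration = concentrations, fraction_bound = fb,
               replicate_id = replicate_id, stringsAsFactors = FALSE),
    class = c("titration_curve", "data.frame")
  )
}

#' Load the packaged cross-sample editing-extent fixture
#'
#' Parses the TSV shipped under `inst/extdata` that transcribes the
#' cross-sample editing-extent table of the study system: the engineered
#' rpoA target row plus 34 off-target sites over 12 samples, with per-cell
#' significance flags and a per-site detection count.
#'
#' @param dest Optional path; when given, the raw fixture TSV is also copied
#'   there.
#' @return A [cross_sample_matrix] object.
#' @examples
#' m <- transcribe_table2_fixture()
#' nrow(m$sites)
#' @export
transcribe_table2_fixture <- function(dest = NULL) {
  path <- system.file("extdata", "table2_editing_extents.tsv",
                      package = "PPRedit", mustWork = TRUE)
  if (!is.null(dest)) file.copy(path, dest, overwrite = TRUE)
  read_cross_sample_matrix(path)
}
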