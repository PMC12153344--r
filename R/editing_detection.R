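# Candidate C-to-U event detection from stranded per-site base counts.
#
# Count tables are read from TSV, collapsed to the transcript strand
# (RF-first-strand convention: forward-read counts plus complemented
# reverse-read counts), and every genomic C (+ strand) / G (- strand)
# covered in both the RNA and the DNA control table becomes a candidate
# with an editing fraction and a 2x2 G-statistic confidence score.  The
# G-statistic is a deliberate, transparent stand-in for the original
# pipeline's Dirichlet-multinomial score: all downstream thresholds are
# rank-based percentiles, so any monotone per-site RNA-vs-DNA contrast is
# equivalent.

SITE_COUNT_COLUMNS <- c("chrom", "pos", "ref",
                        "fA", "fC", "fG", "fT", "rA", "rC", "rG", "rT",
                        "sample")

#' Read a stranded site-count table
#'
#' @param path TSV file with header
#'   `chrom pos ref fA fC fG fT rA rC rG rT sample`: per-position base
#'   counts split by read orientation (`f*` forward-oriented reads, `r*`
#'   reverse-oriented reads reporting their own base).
#' @return A validated `data.frame`, one row per site; positions need not
#'   be contiguous.
#' @export
read_site_counts <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!identical(names(df), SITE_COUNT_COLUMNS)) {
    stop("site-count table header must be: ",
         paste(SITE_COUNT_COLUMNS, collapse = ", "), call. = FALSE)
  }
  for (col in c("chrom", "ref", "sample")) df[[col]] <- as.character(df[[col]])
  if (nrow(df) == 0L) {
    for (col in setdiff(SITE_COUNT_COLUMNS, c("chrom", "ref", "sample"))) {
      df[[col]] <- integer(0)
    }
    return(df)
  }
  validate_site_counts(df, path)
  df
}

#' @keywords internal
validate_site_counts <- function(df, origin = "site-count table") {
  count_cols <- c("fA", "fC", "fG", "fT", "rA", "rC", "rG", "rT")
  for (col in c("pos", count_cols)) {
    if (!is.numeric(df[[col]])) {
      bad <- which(!grepl("^\\s*-?\\d+\\s*$", as.character(df[[col]])))[1L]
      stop(sprintf("%s: non-numeric '%s' at line %d", origin, col,
                   bad + 1L), call. = FALSE)
    }
  }
  bad_ref <- which(!df$ref %in% DNA_BASES)
  if (length(bad_ref)) {
    stop(sprintf("%s: ref base '%s' outside {A,C,G,T} at line %d", origin,
                 df$ref[bad_ref[1L]], bad_ref[1L] + 1L), call. = FALSE)
  }
  for (col in count_cols) {
    bad <- which(df[[col]] < 0)
    if (length(bad)) {
      stop(sprintf("%s: negative count in '%s' at line %d", origin, col,
                   bad[1L] + 1L), call. = FALSE)
    }
  }
  bad_pos <- which(df$pos < 1)
  if (length(bad_pos)) {
    stop(sprintf("%s: non-positive position at line %d", origin,
                 bad_pos[1L] + 1L), call. = FALSE)
  }
  invisible(df)
}

#' Write a site-count table
#' @param df A site-count `data.frame` (see [read_site_counts()]).
#' @param path Output TSV path.
#' @export
write_site_counts <- function(df, path) {
  stopifnot(identical(names(df), SITE_COUNT_COLUMNS))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Collapse stranded counts onto the transcript strand
#'
#' Sums forward-read counts with complemented reverse-read counts (the
#' RF-first-strand collapse), then orients the result: on strand `+` the
#' unedited base is C and the edited base T; on strand `-` (genome forward
#' view) they are G and A.
#'
#' @param site One site-count record: a one-row `data.frame` or named list
#'   with the fields of [read_site_counts()].
#' @param strand Transcript strand, `"+"` or `"-"`.
#' @return An object of class `oriented_counts`: list with
#'   `transcript_strand`, `ref_count`, `alt_count`, `other_count`, `depth`.
#' @examples
#' s <- list(ref = "C", fA = 0, fC = 90, fG = 0, fT = 10,
#'           rA = 0, rC = 0, rG = 0, rT = 0)
#' orient_counts(s, "+")
#' @export
orient_counts <- function(site, strand) {
  stopifnot(strand %in% c("+", "-"))
  expected_ref <- if (strand == "+") "C" else "G"
  if (!identical(as.character(site$ref), expected_ref)) {
    stop(sprintf("ref base '%s' inconsistent with strand %s (expected %s)",
                 site$ref, strand, expected_ref), call. = FALSE)
  }
  # genome-forward totals: forward reads report the base itself, reverse
  # reads report its complement
  tot <- c(A = site$fA + site$rT, C = site$fC + site$rG,
           G = site$fG + site$rC, T = site$fT + site$rA)
  if (strand == "+") {
    ref_count <- tot[["C"]]; alt_count <- tot[["T"]]
  } else {
    ref_count <- tot[["G"]]; alt_count <- tot[["A"]]
  }
  depth <- sum(tot)
  structure(list(transcript_strand = strand, ref_count = ref_count,
                 alt_count = alt_count,
                 other_count = depth - ref_count - alt_count, depth = depth),
            class = "oriented_counts")
}

#' Editing fraction of an oriented site
#'
#' `alt / (ref + alt)`; reads supporting neither the edited nor the
#' unedited base are excluded, mirroring the two-peak ratio used for
#' Sanger-trace quantification.
#'
#' @param oriented An [orient_counts()] result.
#' @return A proportion in `[0, 1]`.
#' @export
editing_fraction <- function(oriented) {
  stopifnot(inherits(oriented, "oriented_counts"))
  den <- oriented$ref_count + oriented$alt_count
  if (den <= 0) {
    stop("editing fraction undefined: no ref or alt reads", call. = FALSE)
  }
  oriented$alt_count / den
}

# Vectorised G-statistic of the 2x2 table [ref, alt] x [RNA, DNA]:
# 2 * sum O * log(O / E), zero cells contributing zero.
#' @keywords internal
g2x2 <- function(rna_ref, rna_alt, dna_ref, dna_alt) {
  n <- rna_ref + rna_alt + dna_ref + dna_alt
  row_rna <- rna_ref + rna_alt
  row_dna <- dna_ref + dna_alt
  col_ref <- rna_ref + dna_ref
  col_alt <- rna_alt + dna_alt
  term <- function(o, e) ifelse(o > 0, o * log(o / e), 0)
  g <- 2 * (term(rna_ref, row_rna * col_ref / n) +
              term(rna_alt, row_rna * col_alt / n) +
              term(dna_ref, row_dna * col_ref / n) +
              term(dna_alt, row_dna * col_alt / n))
  pmax(g, 0)  # clamp tiny negative round-off
}

#' Per-site RNA-vs-DNA confidence score
#'
#' The G-statistic (likelihood-ratio chi-square) of the 2x2 contingency
#' table `[ref, alt] x [RNA, DNA]`.  It is 0 when the two samples have
#' proportionally identical compositions and is invariant to which sample
#' is labelled RNA.
#'
#' @param rna,dna [orient_counts()] results for the RNA sample and the DNA
#'   control at the same site.
#' @return A non-negative real.
#' @export
site_score <- function(rna, dna) {
  stopifnot(inherits(rna, "oriented_counts"), inherits(dna, "oriented_counts"))
  if (rna$ref_count + rna$alt_count <= 0 ||
      dna$ref_count + dna$alt_count <= 0) {
    stop("site_score requires positive ref+alt depth in both samples",
         call. = FALSE)
  }
  g2x2(rna$ref_count, rna$alt_count, dna$ref_count, dna$alt_count)
}

# Vectorised transcript-strand collapse for a whole table subset.
#' @keywords internal
oriented_totals <- function(df, strand) {
  if (strand == "+") {
    list(ref = df$fC + df$rG, alt = df$fT + df$rA)
  } else {
    list(ref = df$fG + df$rC, alt = df$fA + df$rT)
  }
}

#' Call candidate C-to-U events
#'
#' Emits one candidate per genomic C (strand `+`) and G (strand `-`)
#' present in both the RNA and the DNA control table with positive
#' ref+alt depth in each; sites absent from the DNA table (or with no
#' usable depth) are skipped and counted in the `skipped` attribute.
#'
#' @param genome Named character vector of length 1.
#' @param rna_table,dna_table Site-count `data.frame`s
#'   (see [read_site_counts()]).
#' @param sample_id Sample label for the output; defaults to the RNA
#'   table's `sample` value.
#' @return A `data.frame` of candidates: `chrom, pos, strand, f_rna, f_dna,
#'   depth, score, sample`.
#' @export
call_candidates <- function(genome, rna_table, dna_table, sample_id = NULL) {
  stopifnot(is.character(genome), length(genome) == 1L)
  if (is.null(sample_id)) {
    sample_id <- if (nrow(rna_table) > 0L) rna_table$sample[1L] else "sample"
  }
  chrom <- names(genome)[1L]
  bases <- seq_to_bases(genome[[1L]])
  editable <- data.frame(
    pos = c(which(bases == "C"), which(bases == "G")),
    strand = rep(c("+", "-"), c(sum(bases == "C"), sum(bases == "G"))),
    stringsAsFactors = FALSE)
  if (nrow(editable) == 0L) {
    return(empty_candidates(sample_id))
  }

  rna <- rna_table[rna_table$chrom == chrom, , drop = FALSE]
  dna <- dna_table[dna_table$chrom == chrom, , drop = FALSE]
  ir <- match(editable$pos, rna$pos)
  id <- match(editable$pos, dna$pos)
  covered <- !is.na(ir) & !is.na(id)
  skipped_uncovered <- sum(!is.na(ir) & is.na(id))  # in RNA but not DNA

  ed <- editable[covered, , drop = FALSE]
  rna <- rna[ir[covered], , drop = FALSE]
  dna <- dna[id[covered], , drop = FALSE]

  f_rna <- f_dna <- score <- numeric(nrow(ed))
  depth <- integer(nrow(ed))
  usable <- logical(nrow(ed))
  for (strand in c("+", "-")) {
    sel <- ed$strand == strand
    if (!any(sel)) next
    r <- oriented_totals(rna[sel, , drop = FALSE], strand)
    d <- oriented_totals(dna[sel, , drop = FALSE], strand)
    ok <- (r$ref + r$alt) > 0 & (d$ref + d$alt) > 0
    usable[sel] <- ok
    f_rna[sel] <- ifelse(ok, r$alt / (r$ref + r$alt), NA_real_)
    f_dna[sel] <- ifelse(ok, d$alt / (d$ref + d$alt), NA_real_)
    score[sel] <- ifelse(ok, g2x2(r$ref, r$alt, d$ref, d$alt), NA_real_)
    cnt <- rna[sel, c("fA", "fC", "fG", "fT", "rA", "rC", "rG", "rT")]
    depth[sel] <- as.integer(rowSums(cnt))
  }
  skipped_nodepth <- sum(!usable)
  n_out <- sum(usable)
  out <- data.frame(chrom = rep_len(chrom, n_out), pos = ed$pos[usable],
                    strand = ed$strand[usable], f_rna = f_rna[usable],
                    f_dna = f_dna[usable], depth = depth[usable],
                    score = score[usable],
                    sample = rep_len(sample_id, n_out),
                    stringsAsFactors = FALSE)
  out <- out[order(out$pos, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  if (skipped_uncovered + skipped_nodepth > 0L) {
    message(sprintf("call_candidates [%s]: skipped %d site(s) without DNA %s",
                    sample_id, skipped_uncovered + skipped_nodepth,
                    "coverage or usable depth"))
  }
  attr(out, "skipped") <- c(no_dna = skipped_uncovered,
                            no_depth = skipped_nodepth)
  out
}

#' @keywords internal
empty_candidates <- function(sample_id = "sample") {
  data.frame(chrom = character(0), pos = integer(0), strand = character(0),
             f_rna = numeric(0), f_dna = numeric(0), depth = integer(0),
             score = numeric(0), sample = character(0),
             stringsAsFactors = FALSE)
}
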