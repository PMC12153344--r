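# PPR recognition-code model: factor definitions, scoring tables,
# motif-to-offset alignment, per-site score profiles, and genome scans.
#
# Each PPR motif binds a single ribonucleotide; specificity is carried by
# the residues at positions 5 and 35 ("last") of the motif.  A scoring
# table maps each (aa5, aa_last) pair to a score per ribonucleotide; the
# total score of a candidate cis-element is the sum of per-motif scores at
# the aligned offsets upstream of the edited C.

PPR_MOTIF_CLASSES <- c("P", "L", "S", "P2", "L2", "S2", "E1", "E2", "DYW")
NONBINDING_CLASSES <- c("E1", "E2", "DYW")

#' Construct a PPR factor
#'
#' @param name Factor name.
#' @param motifs A `data.frame` with columns `motif_class`, `aa5`,
#'   `aa_last`, ordered N-terminus to C-terminus.
#' @return An object of class `ppr_factor`.
#' @details Motifs of class E1/E2/DYW are not nucleotide-binding; E1/E2 are
#'   nevertheless assigned offsets -3/-2 and are scored whenever their
#'   residue pair is present in the scoring table.  The nucleotide-binding
#'   motifs must form one contiguous N-terminal block.
#' @export
ppr_factor <- function(name, motifs) {
  req <- c("motif_class", "aa5", "aa_last")
  if (!all(req %in% names(motifs))) {
    stop("`motifs` needs columns motif_class, aa5, aa_last", call. = FALSE)
  }
  motifs <- as.data.frame(motifs, stringsAsFactors = FALSE)[, req]
  if (!all(motifs$motif_class %in% PPR_MOTIF_CLASSES)) {
    stop("unknown motif class: ",
         paste(setdiff(motifs$motif_class, PPR_MOTIF_CLASSES), collapse = ", "),
         call. = FALSE)
  }
  bad_aa <- !grepl("^[A-Z*-]$", c(motifs$aa5, motifs$aa_last))
  if (any(bad_aa)) {
    stop("specificity residues must be one-letter amino-acid codes",
         call. = FALSE)
  }
  motifs$binds_nucleotide <- !(motifs$motif_class %in% NONBINDING_CLASSES)
  if (sum(motifs$binds_nucleotide) < 1L) {
    stop("factor needs at least one nucleotide-binding motif", call. = FALSE)
  }
  idx <- which(motifs$binds_nucleotide)
  if (!identical(idx, seq(min(idx), max(idx)))) {
    stop("nucleotide-binding motifs must be contiguous", call. = FALSE)
  }
  structure(list(name = name, motifs = motifs), class = "ppr_factor")
}

#' @export
print.ppr_factor <- function(x, ...) {
  cat(sprintf("<ppr_factor> %s: %d motifs (%d nucleotide-binding)\n",
              x$name, nrow(x$motifs), sum(x$motifs$binds_nucleotide)))
  invisible(x)
}

#' Read a PPR factor definition file
#'
#' The file is a TSV with columns `motif_class`, `aa5`, `aa_last`, one row
#' per motif, N-terminus first.
#'
#' @param path Path to the TSV file.
#' @param name Factor name; defaults to the file name.
#' @return A [ppr_factor()].
#' @export
read_ppr_factor <- function(path, name = sub("\\.tsv$", "", basename(path))) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  ppr_factor(name, df)
}

#' A packaged synthetic example factor
#'
#' A 15-motif PLS-architecture designer factor (3 x PLS triplets, P2-L2-S2,
#' then E1, E2, DYW) whose residue pairs are all covered by the packaged
#' synthetic scoring table.  It is a synthetic stand-in, not the published
#' protein.
#'
#' @return A [ppr_factor()].
#' @export
synthetic_factor <- function() {
  read_ppr_factor(system.file("extdata", "synthetic_factor.tsv",
                              package = "PPRedit", mustWork = TRUE),
                  name = "synthetic_PLS_factor")
}

#' Construct a recognition-code scoring table
#'
#' @param entries A numeric matrix with one row per residue pair (rownames
#'   are two-letter strings, `aa5` then `aa_last`) and columns `A, C, G, U`.
#' @return An object of class `scoring_table`.
#' @export
scoring_table <- function(entries) {
  entries <- as.matrix(entries)
  if (!identical(colnames(entries), RNA_BASES)) {
    stop("scoring table must have exactly the nucleotide columns A, C, G, U",
         call. = FALSE)
  }
  if (is.null(rownames(entries)) || anyDuplicated(rownames(entries))) {
    stop("scoring table rows must be uniquely keyed by residue pair",
         call. = FALSE)
  }
  storage.mode(entries) <- "double"
  if (any(!is.finite(entries))) {
    stop("scoring table contains non-finite scores", call. = FALSE)
  }
  structure(list(entries = entries), class = "scoring_table")
}

#' Read a recognition-code scoring table
#'
#' Expects a TSV in the PPRmatcher table dialect: a residue-pair key column
#' followed by exactly four nucleotide columns `A, C, G, U`.
#'
#' @param path Path to the TSV file.
#' @return A [scoring_table()].
#' @export
read_scoring_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (ncol(df) != 5L) {
    stop("scoring table must have a key column plus 4 nucleotide columns, ",
         "got ", ncol(df), call. = FALSE)
  }
  keys <- as.character(df[[1L]])
  if (anyDuplicated(keys)) {
    stop("duplicate residue-pair keys in scoring table: ",
         paste(unique(keys[duplicated(keys)]), collapse = ", "),
         call. = FALSE)
  }
  vals <- df[, -1L, drop = FALSE]
  num <- vapply(vals, is.numeric, logical(1))
  if (!all(num)) {
    stop("non-numeric scores in scoring table column(s): ",
         paste(names(vals)[!num], collapse = ", "), call. = FALSE)
  }
  m <- as.matrix(vals)
  rownames(m) <- keys
  colnames(m) <- sub("^T$", "U", colnames(m))
  scoring_table(m[, RNA_BASES, drop = FALSE])
}

#' Write a scoring table back to TSV
#' @param table A [scoring_table()].
#' @param path Output path.
#' @export
write_scoring_table <- function(table, path) {
  stopifnot(inherits(table, "scoring_table"))
  df <- data.frame(pair = rownames(table$entries), table$entries,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' The packaged synthetic scoring table
#'
#' A small neutral table covering the residue pairs of
#' [synthetic_factor()].  Scores are synthetic values in `[-0.5, 1]` with a
#' unique top and bottom nucleotide per pair; they are not the published
#' recognition-code statistics, which users supply as an external TSV.
#'
#' @return A [scoring_table()].
#' @export
synthetic_scoring_table <- function() {
  read_scoring_table(system.file("extdata", "synthetic_scoring_table.tsv",
                                 package = "PPRedit", mustWork = TRUE))
}

#' Look up the score row for one residue pair
#' @keywords internal
lookup_pair <- function(table, aa5, aa_last) {
  key <- paste0(aa5, aa_last)
  if (!key %in% rownames(table$entries)) {
    stop(sprintf("residue pair '%s' missing from scoring table", key),
         call. = FALSE)
  }
  table$entries[key, ]
}

#' Align factor motifs to cis-element offsets
#'
#' The last nucleotide-binding motif aligns to offset -4 (relative to the
#' edited C at 0); each preceding binding motif sits one step further
#' upstream, so the k-th of n binding motifs gets offset `-(n+3) + (k-1)`.
#' E1 and E2, when present, extend the ladder at -3 and -2.
#'
#' @param factor A [ppr_factor()].
#' @return A `data.frame` with one row per offset-bearing motif: `index`
#'   (position in the motif list), `motif_class`, `aa5`, `aa_last`,
#'   `offset`.
#' @examples
#' align_offsets(synthetic_factor())
#' @export
align_offsets <- function(factor) {
  stopifnot(inherits(factor, "ppr_factor"))
  m <- factor$motifs
  bind_idx <- which(m$binds_nucleotide)
  n <- length(bind_idx)
  out <- data.frame(index = bind_idx,
                    motif_class = m$motif_class[bind_idx],
                    aa5 = m$aa5[bind_idx], aa_last = m$aa_last[bind_idx],
                    offset = -(n + 3L) + seq_len(n) - 1L,
                    stringsAsFactors = FALSE)
  for (cls in c("E1", "E2")) {
    i <- which(m$motif_class == cls)
    if (length(i) == 1L) {
      out <- rbind(out, data.frame(
        index = i, motif_class = cls, aa5 = m$aa5[i], aa_last = m$aa_last[i],
        offset = if (cls == "E1") -3L else -2L, stringsAsFactors = FALSE))
    }
  }
  out[order(out$offset), , drop = FALSE]
}

#' Offsets and preferred nucleotides for the scored motifs
#'
#' Nucleotide-binding motifs are always scored (a missing residue pair is an
#' error); E1/E2 are scored only when their pair is present in the table.
#' Ties in the per-motif argmax/argmin are broken alphabetically.
#'
#' @keywords internal
motif_preferences <- function(factor, table) {
  al <- align_offsets(factor)
  keep <- logical(nrow(al))
  rows <- vector("list", nrow(al))
  for (i in seq_len(nrow(al))) {
    key <- paste0(al$aa5[i], al$aa_last[i])
    present <- key %in% rownames(table$entries)
    if (al$motif_class[i] %in% c("E1", "E2") && !present) next
    keep[i] <- TRUE
    sc <- lookup_pair(table, al$aa5[i], al$aa_last[i])
    rows[[i]] <- data.frame(
      offset = al$offset[i], pair = key,
      top_base = RNA_BASES[which.max(sc)], top_score = max(sc),
      min_base = RNA_BASES[which.min(sc)], min_score = min(sc),
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows[keep])
  out$top_base_dna <- sub("U", "T", out$top_base)
  out$min_base_dna <- sub("U", "T", out$min_base)
  out[order(out$offset), , drop = FALSE]
}

#' Score one candidate cis-element
#'
#' Reads the transcript-strand nucleotide at each scored motif's aligned
#' offset (genomic T read as U), looks up the per-motif score, and sums.
#' Positions are classified as favored (score > `tau`), disfavored
#' (score < `-tau`) or neutral.
#'
#' @param factor A [ppr_factor()].
#' @param table A [scoring_table()].
#' @param genome Named character vector of length 1.
#' @param pos 1-based coordinate of the edited C.
#' @param strand Transcript strand, `"+"` or `"-"`.
#' @param tau Non-negative classification threshold (default 0).
#' @return An object of class `site_score_profile`: list with `offsets`,
#'   `nucleotides`, `scores`, `classes`, `total`, `pos`, `strand`.
#' @export
score_site <- function(factor, table, genome, pos, strand, tau = 0) {
  stopifnot(is.character(genome), length(genome) == 1L)
  bases <- seq_to_bases(genome[[1L]])
  L <- length(bases)
  prefs <- motif_preferences(factor, table)
  offsets <- prefs$offset
  gpos <- if (strand == "+") pos + offsets else pos - offsets
  if (pos < 1L || pos > L || any(gpos < 1L) || any(gpos > L)) {
    stop("cis-element window out of genome bounds", call. = FALSE)
  }
  ref_at_pos <- bases[pos]
  expected <- if (strand == "+") "C" else "G"
  if (ref_at_pos != expected) {
    stop(sprintf("base at position %d is %s, not %s as required for strand %s",
                 pos, ref_at_pos, expected, strand), call. = FALSE)
  }
  nt_dna <- if (strand == "+") bases[gpos] else complement_base(bases[gpos])
  nt <- sub("T", "U", nt_dna)
  scores <- vapply(seq_along(offsets), function(i) {
    lookup_pair(table, substr(prefs$pair[i], 1, 1),
                substr(prefs$pair[i], 2, 2))[nt[i]]
  }, numeric(1))
  total <- sum(scores)
  stopifnot(isTRUE(all.equal(total, sum(scores))))  # additivity, by construction
  classes <- ifelse(scores > tau, "favored",
                    ifelse(scores < -tau, "disfavored", "neutral"))
  structure(list(offsets = offsets, nucleotides = unname(nt),
                 scores = unname(scores), classes = unname(classes),
                 total = total, pos = pos, strand = strand),
            class = "site_score_profile")
}

#' @export
print.site_score_profile <- function(x, ...) {
  cat(sprintf("<site_score_profile> pos %d (%s)  total %.3f\n",
              x$pos, x$strand, x$total))
  print(data.frame(offset = x$offsets, nt = x$nucleotides,
                   score = x$scores, class = x$classes))
  invisible(x)
}

#' Scan a genome for predicted binding/editing sites
#'
#' Scores every C (on both strands) whose full upstream window is in bounds
#' and returns sites with total score at least `min_total`, sorted by total
#' descending with ties broken by (chrom, pos, strand).
#'
#' @inheritParams score_site
#' @param min_total Minimum total score to report.
#' @return A `data.frame` with columns `chrom`, `pos`, `strand`, `total`.
#' @export
scan_genome <- function(factor, table, genome, min_total = -Inf) {
  stopifnot(is.character(genome), length(genome) == 1L)
  prefs <- motif_preferences(factor, table)
  offsets <- prefs$offset
  bases <- seq_to_bases(genome[[1L]])
  L <- length(bases)
  code <- match(bases, DNA_BASES)           # A=1 C=2 G=3 T=4
  comp_code <- c(4L, 3L, 2L, 1L)[code]

  # score matrix indexed by DNA code of the transcript-strand base
  S <- t(vapply(seq_len(nrow(prefs)), function(i) {
    sc <- lookup_pair(table, substr(prefs$pair[i], 1, 1),
                      substr(prefs$pair[i], 2, 2))
    sc[c("A", "C", "G", "U")]
  }, numeric(4)))

  score_positions <- function(pos, strand) {
    if (length(pos) == 0L) {
      return(data.frame(chrom = character(0), pos = integer(0),
                        strand = character(0), total = numeric(0)))
    }
    total <- numeric(length(pos))
    for (i in seq_along(offsets)) {
      idx <- if (strand == "+") pos + offsets[i] else pos - offsets[i]
      cc <- if (strand == "+") code[idx] else comp_code[idx]
      total <- total + S[i, cc]
    }
    data.frame(chrom = names(genome)[1L], pos = pos, strand = strand,
               total = total, stringsAsFactors = FALSE)
  }

  span <- -min(offsets)                      # deepest upstream reach
  plus_pos <- which(bases == "C")
  plus_pos <- plus_pos[plus_pos - span >= 1L & plus_pos + max(offsets) >= 1L]
  minus_pos <- which(bases == "G")
  minus_pos <- minus_pos[minus_pos + span <= L]

  out <- rbind(score_positions(plus_pos, "+"), score_positions(minus_pos, "-"))
  out <- out[!is.na(out$total) & out$total >= min_total, , drop = FALSE]
  out <- out[order(-out$total, out$chrom, out$pos, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Export score profiles as a sites-by-offsets heat-map matrix
#'
#' @param profiles List of [score_site()] results.
#' @param path Optional TSV output path.
#' @return Invisibly, the numeric matrix (rows = sites, columns = offsets).
#' @export
score_heatmap_matrix <- function(profiles, path = NULL) {
  stopifnot(length(profiles) > 0L)
  offs <- profiles[[1L]]$offsets
  m <- t(vapply(profiles, function(p) {
    stopifnot(identical(p$offsets, offs))
    p$scores
  }, numeric(length(offs))))
  colnames(m) <- as.character(offs)
  rownames(m) <- vapply(profiles, function(p) {
    sprintf("%d%s", p$pos, p$strand)
  }, character(1))
  if (!is.null(path)) {
    utils::write.table(data.frame(site = rownames(m), m, check.names = FALSE),
                       path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(m)
}
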