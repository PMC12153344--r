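# Editing-extent-weighted position frequency matrices and information
# content over the -15..+1 window of off-target sequences.

LOGO_OFFSETS <- -15L:1L

#' Extract weighted cis-element windows around editing events
#'
#' Returns the 17-nt transcript-strand sequence at offsets -15..+1 around
#' each edited C (RNA alphabet, edited C included at offset 0), weighted by
#' the event's editing fraction.  The engineered target event is excluded;
#' events whose window leaves the genome are skipped with a warning.
#'
#' @param genome Named character vector of length 1.
#' @param events Event `data.frame` with `pos`, `strand`, `f_rna` and
#'   optionally `is_target`.
#' @param offsets Window offsets relative to the edited C.
#' @return A `data.frame` with columns `sequence` (RNA alphabet) and
#'   `weight`.
#' @export
extract_windows <- function(genome, events, offsets = LOGO_OFFSETS) {
  stopifnot(is.character(genome), length(genome) == 1L)
  bases <- seq_to_bases(genome[[1L]])
  L <- length(bases)
  if (!is.null(events$is_target)) {
    events <- events[!events$is_target, , drop = FALSE]
  }
  seqs <- character(0)
  weights <- numeric(0)
  for (i in seq_len(nrow(events))) {
    pos <- events$pos[i]
    strand <- events$strand[i]
    gpos <- if (strand == "+") pos + offsets else pos - offsets
    if (any(gpos < 1L) || any(gpos > L)) {
      warning(sprintf("window out of bounds for event at %d%s: skipped",
                      pos, strand), call. = FALSE)
      next
    }
    nt <- if (strand == "+") bases[gpos] else complement_base(bases[gpos])
    seqs <- c(seqs, paste(sub("T", "U", nt), collapse = ""))
    weights <- c(weights, events$f_rna[i])
  }
  data.frame(sequence = seqs, weight = weights, stringsAsFactors = FALSE)
}

#' Weighted position frequency matrix
#'
#' `freq(b, j) = sum_k w_k [s_k[j] == b] / sum_k w_k`: each sequence
#' contributes its weight (here, editing extent), so highly edited sites
#' dominate the profile.  No pseudocounts are added.
#'
#' @param windows A `data.frame` with columns `sequence` (equal-length RNA
#'   strings) and `weight` (non-negative, not all zero), as produced by
#'   [extract_windows()].
#' @param offsets Offset labels for the window columns.
#' @return An object of class `weighted_pfm`: list with `offsets`, `freqs`
#'   (4 x width matrix, rows A/C/G/U), `n_sequences`, `weight_sum`.
#' @export
weighted_pfm <- function(windows, offsets = NULL) {
  if (nrow(windows) == 0L) stop("no windows: PFM undefined", call. = FALSE)
  widths <- nchar(windows$sequence)
  if (length(unique(widths)) != 1L) {
    stop("window sequences must have equal length", call. = FALSE)
  }
  w <- windows$weight
  if (any(w < 0)) stop("weights must be non-negative", call. = FALSE)
  if (sum(w) <= 0) stop("all-zero weights: PFM undefined", call. = FALSE)
  width <- widths[1L]
  if (is.null(offsets)) {
    offsets <- if (width == length(LOGO_OFFSETS)) LOGO_OFFSETS
               else seq_len(width)
  }
  stopifnot(length(offsets) == width)
  chars <- matrix(unlist(strsplit(windows$sequence, "", fixed = TRUE)),
                  nrow = nrow(windows), byrow = TRUE)
  if (!all(chars %in% RNA_BASES)) {
    stop("window sequences must be over the RNA alphabet A/C/G/U",
         call. = FALSE)
  }
  freqs <- vapply(seq_len(width), function(j) {
    vapply(RNA_BASES, function(b) sum(w[chars[, j] == b]), numeric(1))
  }, numeric(4)) / sum(w)
  rownames(freqs) <- RNA_BASES
  colnames(freqs) <- as.character(offsets)
  stopifnot(all(abs(colSums(freqs) - 1) < 1e-9))
  structure(list(offsets = offsets, freqs = freqs,
                 n_sequences = nrow(windows), weight_sum = sum(w)),
            class = "weighted_pfm")
}

#' Per-offset information content
#'
#' `IC_j = 2 + sum_b p_bj log2 p_bj` bits (with `0 log 0 = 0`), i.e. the
#' reduction in entropy from the uniform background; no small-sample
#' correction is applied, matching frequency-input sequence-logo
#' conventions.
#'
#' @param pfm A [weighted_pfm()].
#' @return Numeric vector of IC values in `[0, 2]`, named by offset.
#' @export
information_content <- function(pfm) {
  stopifnot(inherits(pfm, "weighted_pfm"))
  apply(pfm$freqs, 2L, function(p) {
    p <- p[p > 0]
    2 + sum(p * log2(p))
  })
}

#' Consensus sequence of a PFM
#'
#' Arg-max base per offset; exact ties are broken alphabetically and
#' flagged.
#'
#' @param pfm A [weighted_pfm()].
#' @return A list with `sequence` (RNA string) and `tie` (logical vector,
#'   one element per offset).
#' @export
consensus <- function(pfm) {
  stopifnot(inherits(pfm, "weighted_pfm"))
  top <- apply(pfm$freqs, 2L, function(p) RNA_BASES[which.max(p)])
  tie <- apply(pfm$freqs, 2L, function(p) sum(p == max(p)) > 1L)
  list(sequence = paste(top, collapse = ""), tie = unname(tie))
}

#' Write PFM and IC matrices to TSV
#'
#' The canonical logo artifact: per-offset base frequencies, the
#' information content in bits, and the IC-scaled letter heights.
#'
#' @param pfm A [weighted_pfm()].
#' @param path Output TSV path.
#' @return Invisibly, the exported `data.frame`.
#' @export
write_pfm <- function(pfm, path) {
  ic <- information_content(pfm)
  df <- data.frame(offset = pfm$offsets, t(pfm$freqs), ic = ic,
                   t(pfm$freqs * rep(ic, each = 4L)),
                   check.names = FALSE, stringsAsFactors = FALSE)
  names(df) <- c("offset", paste0("p", RNA_BASES), "ic_bits",
                 paste0("h", RNA_BASES))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(df)
}
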