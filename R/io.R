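# File formats: FASTA genomes (via Biostrings), minimal VCF v4.2 and BED6
# event exports, and the rejection audit table.

#' Read a genome FASTA
#' @param path FASTA file.
#' @return Named character vector of sequences (upper case).
#' @export
read_genome_fasta <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  seqs <- toupper(as.character(ss))
  names(seqs) <- sub("\\s.*$", "", names(ss))
  seqs
}

#' Write a genome FASTA
#' @param genome Named character vector of sequences.
#' @param path Output path.
#' @export
write_genome_fasta <- function(genome, path) {
  ss <- Biostrings::DNAStringSet(unname(genome))
  names(ss) <- names(genome)
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}

#' Write surviving events as a minimal VCF v4.2
#'
#' One record per event: `REF/ALT` are `C/T` on the `+` strand and `G/A`
#' on the `-` strand (genome forward view); the INFO field carries
#' `EDF` (RNA editing fraction), `DDF` (DNA control fraction), `SCORE`,
#' `DP` and `STRAND`.
#'
#' @param events Event `data.frame` (see [run_cascade()]).
#' @param path Output path.
#' @param sample_id Sample name recorded in the header.
#' @export
write_events_vcf <- function(events, path, sample_id = NULL) {
  if (is.null(sample_id)) {
    sample_id <- if (nrow(events) > 0L) events$sample[1L] else "sample"
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    sprintf("##source=PPRedit-%s", utils::packageVersion("PPRedit")),
    sprintf("##sample=%s", sample_id),
    "##INFO=<ID=EDF,Number=1,Type=Float,Description=\"RNA editing fraction\">",
    "##INFO=<ID=DDF,Number=1,Type=Float,Description=\"DNA control mismatch fraction\">",
    "##INFO=<ID=SCORE,Number=1,Type=Float,Description=\"RNA-vs-DNA G-statistic\">",
    "##INFO=<ID=DP,Number=1,Type=Integer,Description=\"RNA read depth\">",
    "##INFO=<ID=STRAND,Number=1,Type=String,Description=\"Transcript strand\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO"), con)
  if (nrow(events) > 0L) {
    ref <- ifelse(events$strand == "+", "C", "G")
    alt <- ifelse(events$strand == "+", "T", "A")
    info <- sprintf("EDF=%.6g;DDF=%.6g;SCORE=%.6g;DP=%d;STRAND=%s",
                    events$f_rna, events$f_dna, events$score,
                    as.integer(events$depth), events$strand)
    writeLines(sprintf("%s\t%d\t.\t%s\t%s\t.\tPASS\t%s",
                       events$chrom, events$pos, ref, alt, info), con)
  }
  invisible(path)
}

#' Read the event records of a PPRedit VCF back into a data frame
#' @param path VCF path written by [write_events_vcf()].
#' @return Event `data.frame` (`chrom, pos, strand, f_rna, f_dna, depth,
#'   score`).
#' @export
read_events_vcf <- function(path) {
  lines <- readLines(path)
  body <- lines[!startsWith(lines, "#")]
  if (length(body) == 0L) {
    return(data.frame(chrom = character(0), pos = integer(0),
                      strand = character(0), f_rna = numeric(0),
                      f_dna = numeric(0), depth = integer(0),
                      score = numeric(0), stringsAsFactors = FALSE))
  }
  parts <- strsplit(body, "\t", fixed = TRUE)
  info <- vapply(parts, `[[`, character(1), 8L)
  grab <- function(key) {
    as.numeric(sub(sprintf(".*%s=([^;]+).*", key), "\\1", info))
  }
  data.frame(
    chrom = vapply(parts, `[[`, character(1), 1L),
    pos = as.integer(vapply(parts, `[[`, character(1), 2L)),
    strand = sub(".*STRAND=([^;]+).*", "\\1", info),
    f_rna = grab("EDF"), f_dna = grab("DDF"),
    depth = as.integer(grab("DP")), score = grab("SCORE"),
    stringsAsFactors = FALSE)
}

#' Write events as BED6
#'
#' Coordinates convert from the package's 1-based inclusive convention to
#' BED's 0-based half-open intervals.
#'
#' @param events Event `data.frame`.
#' @param path Output path.
#' @export
write_events_bed <- function(events, path) {
  lines <- if (nrow(events) > 0L) {
    sprintf("%s\t%d\t%d\t%s\t%.6g\t%s", events$chrom, events$pos - 1L,
            events$pos, event_keys(events), events$score, events$strand)
  } else character(0)
  writeLines(lines, path)
  invisible(path)
}

#' Write the cascade rejection audit table
#' @param audit Audit `data.frame` from [run_cascade()].
#' @param path Output TSV path.
#' @export
write_audit <- function(audit, path) {
  utils::write.table(audit, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
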