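# Cross-sample aggregation: the sites-by-samples editing-extent matrix
# with significance flags, multiplicity statistics, efficiency/selectivity
# regression, and score-extent correlation.

#' Cross-sample editing-extent matrix
#'
#' An object of class `cross_sample_matrix`:
#' * `sites`: `data.frame` with `site_id`, `chrom`, `pos`, `strand`,
#'   `is_target`;
#' * `samples`: character vector of sample ids (columns);
#' * `extent`: numeric matrix of editing extents in percent (`NA` where the
#'   site was not covered in a sample);
#' * `flag`: logical matrix, `TRUE` where the site passed the cascade in
#'   that sample (sub-threshold extents are retained unflagged);
#' * `n_samples`: per site, the number of flagged cells.
#'
#' @param sites,samples,extent,flag See above.
#' @return A validated `cross_sample_matrix`.
#' @export
cross_sample_matrix <- function(sites, samples, extent, flag) {
  extent <- as.matrix(extent)
  flag <- as.matrix(flag)
  stopifnot(nrow(extent) == nrow(sites), ncol(extent) == length(samples),
            identical(dim(extent), dim(flag)))
  if (any(extent < 0 | extent > 100, na.rm = TRUE)) {
    stop("extents must be percentages in [0, 100]", call. = FALSE)
  }
  if (any(flag & is.na(extent))) {
    stop("flagged cells must carry an extent", call. = FALSE)
  }
  dimnames(extent) <- dimnames(flag) <- list(sites$site_id, samples)
  structure(list(sites = sites, samples = samples, extent = extent,
                 flag = flag, n_samples = unname(rowSums(flag))),
            class = "cross_sample_matrix")
}

#' @export
print.cross_sample_matrix <- function(x, ...) {
  cat(sprintf("<cross_sample_matrix> %d sites (%d off-target) x %d samples\n",
              nrow(x$sites), sum(!x$sites$is_target), length(x$samples)))
  invisible(x)
}

#' Build the cross-sample matrix from per-sample events
#'
#' The row universe is the union of significant (cascade-surviving) sites
#' across samples.  A cell is flagged iff the site survived the cascade in
#' that sample; unflagged cells still carry the raw editing extent when the
#' site was covered (taken from `extents_by_sample`, typically the
#' candidate tables).
#'
#' @param events_by_sample Named list of surviving-event `data.frame`s
#'   (see [run_cascade()]).
#' @param extents_by_sample Optional named list of candidate
#'   `data.frame`s providing sub-threshold extents for covered sites.
#' @param target_key Optional `"chrom:pos:strand"` key of the engineered
#'   target (also honoured via an `is_target` column in the events).
#' @return A [cross_sample_matrix].
#' @export
build_matrix <- function(events_by_sample, extents_by_sample = NULL,
                         target_key = NULL) {
  samples <- names(events_by_sample)
  stopifnot(!is.null(samples))
  all_ev <- do.call(rbind, lapply(samples, function(s) {
    ev <- events_by_sample[[s]]
    if (nrow(ev) == 0L) return(NULL)
    data.frame(key = event_keys(ev), chrom = ev$chrom, pos = ev$pos,
               strand = ev$strand,
               is_target = if (!is.null(ev$is_target)) ev$is_target else FALSE,
               stringsAsFactors = FALSE)
  }))
  if (is.null(all_ev)) {
    sites <- data.frame(site_id = character(0), chrom = character(0),
                        pos = integer(0), strand = character(0),
                        is_target = logical(0), stringsAsFactors = FALSE)
    return(cross_sample_matrix(sites, samples,
                               matrix(numeric(0), 0L, length(samples)),
                               matrix(logical(0), 0L, length(samples))))
  }
  sites <- all_ev[!duplicated(all_ev$key), , drop = FALSE]
  sites <- sites[order(sites$chrom, sites$pos, sites$strand), , drop = FALSE]
  if (!is.null(target_key)) {
    sites$is_target <- sites$is_target | sites$key == target_key
  }
  sites <- data.frame(site_id = sites$key, chrom = sites$chrom,
                      pos = sites$pos, strand = sites$strand,
                      is_target = sites$is_target, stringsAsFactors = FALSE)

  extent <- matrix(NA_real_, nrow(sites), length(samples))
  flag <- matrix(FALSE, nrow(sites), length(samples))
  for (j in seq_along(samples)) {
    s <- samples[j]
    ev <- events_by_sample[[s]]
    i <- match(event_keys(ev), sites$site_id)
    flag[i, j] <- TRUE
    extent[i, j] <- 100 * ev$f_rna
    if (!is.null(extents_by_sample) && !is.null(extents_by_sample[[s]])) {
      cand <- extents_by_sample[[s]]
      k <- match(sites$site_id, event_keys(cand))
      fill <- is.na(extent[, j]) & !is.na(k)
      extent[fill, j] <- 100 * cand$f_rna[k[fill]]
    }
  }
  cross_sample_matrix(sites, samples, extent, flag)
}

#' Site multiplicity histogram
#'
#' Counts, over off-target rows only, how many sites were significant in
#' exactly n samples.
#'
#' @param matrix A [cross_sample_matrix].
#' @return Named integer vector mapping n_samples to site count (empty for
#'   an empty matrix).
#' @export
multiplicity_histogram <- function(matrix) {
  stopifnot(inherits(matrix, "cross_sample_matrix"))
  n <- matrix$n_samples[!matrix$sites$is_target]
  n <- n[n > 0]
  if (length(n) == 0L) return(stats::setNames(integer(0), character(0)))
  tab <- table(n)
  stats::setNames(as.integer(tab), names(tab))
}

#' Per-sample significant off-target counts
#'
#' @param matrix A [cross_sample_matrix].
#' @return Named integer vector, one count per sample (zeros included).
#' @export
per_sample_offtarget_counts <- function(matrix) {
  stopifnot(inherits(matrix, "cross_sample_matrix"))
  off <- !matrix$sites$is_target
  counts <- colSums(matrix$flag[off, , drop = FALSE])
  stats::setNames(as.integer(counts), matrix$samples)
}

#' Editing efficiency versus off-target count
#'
#' One point per sample: the target site's editing extent against the
#' number of significant off-targets; ordinary least squares on the
#' points.
#'
#' @param matrix A [cross_sample_matrix] containing a target row.
#' @return A list with `points` (`data.frame`: sample, target_extent,
#'   offtarget_count), `slope`, `intercept`, `r_squared`.
#' @export
efficiency_vs_offtargets <- function(matrix) {
  stopifnot(inherits(matrix, "cross_sample_matrix"))
  t_row <- which(matrix$sites$is_target)
  if (length(t_row) != 1L) {
    stop("matrix must contain exactly one target row", call. = FALSE)
  }
  pts <- data.frame(sample = matrix$samples,
                    target_extent = matrix$extent[t_row, ],
                    offtarget_count = per_sample_offtarget_counts(matrix),
                    stringsAsFactors = FALSE)
  pts <- pts[!is.na(pts$target_extent), , drop = FALSE]
  if (nrow(pts) < 2L) stop("need at least 2 points for the regression",
                           call. = FALSE)
  ols <- ols_fit(pts$target_extent, pts$offtarget_count)
  c(list(points = pts), ols)
}

#' Correlation of editing extent with recognition-code score
#'
#' R-squared of the regression of editing extent on total PPR score.
#'
#' @param extents Editing extents (percent or proportion).
#' @param scores Total cis-element scores, same length.
#' @return The R-squared value.
#' @export
score_vs_extent <- function(extents, scores) {
  stopifnot(length(extents) == length(scores))
  if (length(extents) < 3L) stop("need at least 3 scored events",
                                 call. = FALSE)
  if (stats::var(scores) == 0) {
    stop("degenerate score variance: R-squared undefined", call. = FALSE)
  }
  ols_fit(scores, extents)$r_squared
}

# Least squares with the convention r_squared = 0 for a constant response.
#' @keywords internal
ols_fit <- function(x, y) {
  fit <- stats::lm(y ~ x)
  tss <- sum((y - mean(y))^2)
  r2 <- if (tss == 0) 0 else 1 - sum(resid(fit)^2) / tss
  list(slope = unname(coef(fit)[2L]) %||% 0,
       intercept = unname(coef(fit)[1L]),
       r_squared = r2)
}

# --- fixture-style TSV serialisation -------------------------------------
# Layout mirrors the published comparison table: a `site` column (the
# target row named, off-targets keyed by coordinate), one column per
# sample whose cells are the extent in percent with a trailing '*' when
# the site passed the significance threshold in that sample, and a final
# `n_samples` column.

#' Write a cross-sample matrix as TSV
#' @param matrix A [cross_sample_matrix].
#' @param path Output TSV path.
#' @export
write_cross_sample_matrix <- function(matrix, path) {
  stopifnot(inherits(matrix, "cross_sample_matrix"))
  cells <- matrix(
    "", nrow(matrix$extent), ncol(matrix$extent),
    dimnames = dimnames(matrix$extent))
  has <- !is.na(matrix$extent)
  cells[has] <- formatC(matrix$extent[has], format = "fg")
  cells[matrix$flag] <- paste0(cells[matrix$flag], "*")
  df <- data.frame(site = matrix$sites$site_id, cells,
                   n_samples = matrix$n_samples,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a cross-sample matrix from TSV
#'
#' @param path TSV in the layout written by [write_cross_sample_matrix()].
#'   The row whose `site` value is non-numeric (e.g. a gene name) is taken
#'   to be the engineered target.
#' @return A [cross_sample_matrix].
#' @export
read_cross_sample_matrix <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE,
                          colClasses = "character")
  stopifnot(names(df)[1L] == "site",
            names(df)[ncol(df)] == "n_samples")
  samples <- names(df)[-c(1L, ncol(df))]
  cells <- as.matrix(df[, samples, drop = FALSE])
  flag <- matrix(grepl("\\*$", cells) & nzchar(cells), nrow = nrow(cells))
  nums <- suppressWarnings(array(as.numeric(sub("\\*$", "", cells)),
                                 dim = dim(cells)))
  nums[!nzchar(cells)] <- NA_real_
  is_target <- !grepl("^[0-9 ]+$", df$site)
  pos <- suppressWarnings(as.integer(gsub(" ", "", df$site)))
  sites <- data.frame(site_id = df$site, chrom = "chromosome", pos = pos,
                      strand = NA_character_, is_target = is_target,
                      stringsAsFactors = FALSE)
  m <- cross_sample_matrix(sites, samples, nums, flag)
  declared <- as.integer(df$n_samples)
  if (!identical(declared, as.integer(m$n_samples))) {
    warning("declared n_samples differs from flag counts; using flags",
            call. = FALSE)
  }
  m
}
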