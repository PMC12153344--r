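# The published filter sequence applied to candidate events, in order:
# editing-fraction difference + DNA error bound, depth quantile, score
# percentile (95th/98th switched on the site's own editing rate), and
# negative-control subtraction.  Every rejected candidate is attributed to
# the first filter that removed it (audit log).

#' Filter cascade configuration
#'
#' Thresholds of the event filter cascade.  Defaults are the published
#' ones: a minimum editing fraction difference of 1% between the DNA
#' control and RNA samples, a DNA mismatch fraction bounded by 1% of the
#' RNA editing fraction, read depth above the 1% lower quantile, and a
#' confidence score above the 95th percentile for sites with editing rate
#' >= 10% (98th percentile below that).
#'
#' @param min_fraction_delta Minimum `f_RNA - f_DNA` (proportion).
#' @param dna_error_ratio Maximum `f_DNA` as a multiple of `f_RNA`.
#' @param depth_quantile Lower depth quantile (proportion).
#' @param pct_high Score percentile (0-100) for high-rate sites.
#' @param pct_low Score percentile (0-100) for low-rate sites; must be at
#'   least `pct_high`.
#' @param rate_switch Editing-rate cut deciding the percentile branch; a
#'   site's own `f_RNA >= rate_switch` selects the high branch.
#' @return An object of class `filter_config`.
#' @export
filter_config <- function(min_fraction_delta = 0.01,
                          dna_error_ratio = 0.01,
                          depth_quantile = 0.01,
                          pct_high = 95,
                          pct_low = 98,
                          rate_switch = 0.10) {
  assert_proportion(min_fraction_delta, "min_fraction_delta")
  assert_proportion(dna_error_ratio, "dna_error_ratio")
  assert_proportion(depth_quantile, "depth_quantile")
  assert_proportion(rate_switch, "rate_switch")
  if (!is.numeric(pct_high) || !is.numeric(pct_low) ||
      pct_high <= 0 || pct_high > 100 || pct_low <= 0 || pct_low > 100) {
    stop("percentiles must lie in (0, 100]", call. = FALSE)
  }
  if (pct_low < pct_high) {
    stop("`pct_low` must be >= `pct_high`", call. = FALSE)
  }
  structure(list(min_fraction_delta = min_fraction_delta,
                 dna_error_ratio = dna_error_ratio,
                 depth_quantile = depth_quantile,
                 pct_high = pct_high, pct_low = pct_low,
                 rate_switch = rate_switch),
            class = "filter_config")
}

#' Editing-fraction filter
#'
#' Pass iff `f_RNA - f_DNA >= min_fraction_delta` and
#' `f_DNA <= dna_error_ratio * f_RNA`.
#'
#' @param events Candidate `data.frame` with columns `f_rna`, `f_dna` (see
#'   [call_candidates()]).
#' @param config A [filter_config()].
#' @return Logical vector, one element per candidate.
#' @export
fraction_filter <- function(events, config = filter_config()) {
  stopifnot(inherits(config, "filter_config"))
  (events$f_rna - events$f_dna) >= config$min_fraction_delta &
    events$f_dna <= config$dna_error_ratio * events$f_rna
}

#' Depth threshold of a candidate set
#'
#' The `depth_quantile` lower quantile (type-7 linear interpolation) of the
#' per-sample candidate depths; the cascade keeps events with depth
#' strictly above it (relaxed to `>=` when all depths are equal).
#'
#' @param depths Numeric vector of candidate read depths (non-empty).
#' @param config A [filter_config()].
#' @return The depth threshold (scalar).
#' @examples
#' depth_threshold(1:100)  # 1.99
#' @export
depth_threshold <- function(depths, config = filter_config()) {
  if (length(depths) == 0L) stop("no events: depth threshold undefined",
                                 call. = FALSE)
  quantile7(depths, config$depth_quantile)
}

#' Score threshold for a candidate
#'
#' The `pct_high` percentile of the per-sample score distribution when the
#' candidate's own editing rate is at least `rate_switch`, otherwise the
#' `pct_low` percentile (type-7 interpolation).  The cascade keeps events
#' with score strictly above the returned value.
#'
#' @param scores Numeric vector: the per-sample score distribution.
#' @param f_rna Editing fraction(s) of the candidate(s) being thresholded.
#' @param config A [filter_config()].
#' @return Numeric vector of thresholds, one per element of `f_rna`.
#' @examples
#' score_threshold(1:100, 0.20)  # 95.05
#' score_threshold(1:100, 0.05)  # 98.02
#' @export
score_threshold <- function(scores, f_rna, config = filter_config()) {
  if (length(scores) == 0L) stop("no events: score threshold undefined",
                                 call. = FALSE)
  hi <- quantile7(scores, config$pct_high / 100)
  lo <- quantile7(scores, config$pct_low / 100)
  ifelse(f_rna >= config$rate_switch, hi, lo)
}

#' Remove events shared with control samples
#'
#' Drops any event whose `(chrom, pos, strand)` key occurs in any control
#' sample's event list — the exclusion of events common with samples that
#' express neither the factor nor accessory proteins, which removes shared
#' SNPs and systematic mapping errors.
#'
#' @param events Event `data.frame` with `chrom`, `pos`, `strand`.
#' @param control_events A `data.frame` (or list of them) of control
#'   events with the same key columns.
#' @return The filtered `data.frame`.
#' @export
subtract_controls <- function(events, control_events) {
  if (is.data.frame(control_events)) control_events <- list(control_events)
  ctrl_keys <- unlist(lapply(control_events, event_keys), use.names = FALSE)
  events[!event_keys(events) %in% ctrl_keys, , drop = FALSE]
}

#' @keywords internal
event_keys <- function(df) {
  if (is.null(df) || nrow(df) == 0L) return(character(0))
  paste(df$chrom, df$pos, df$strand, sep = ":")
}

# One sample through the first three filters, attributing each rejection to
# the first failing stage.  Depth and score thresholds are computed over
# the sample's full candidate set (see the methods vignette for why not
# the post-fraction-filter subset).
#' @keywords internal
cascade_stage_filters <- function(cand, config) {
  n <- nrow(cand)
  stage <- rep(NA_character_, n)
  if (n == 0L) {
    return(list(stage = stage, depth_thr = NA_real_,
                score_thr_high = NA_real_, score_thr_low = NA_real_))
  }
  pass_frac <- fraction_filter(cand, config)
  stage[!pass_frac] <- "fraction"

  depth_thr <- depth_threshold(cand$depth, config)
  keep_depth <- keep_above(cand$depth, depth_thr, reference = cand$depth)
  stage[is.na(stage) & !keep_depth] <- "depth"

  thr <- score_threshold(cand$score, cand$f_rna, config)
  keep_score <- keep_above(cand$score, thr, reference = cand$score)
  stage[is.na(stage) & !keep_score] <- "score"

  list(stage = stage, depth_thr = depth_thr,
       score_thr_high = quantile7(cand$score, config$pct_high / 100),
       score_thr_low = quantile7(cand$score, config$pct_low / 100))
}

#' Run the full filter cascade
#'
#' Applies, per sample and in order: the editing-fraction filter, the depth
#' filter, the score filter, and control subtraction.  Control samples are
#' passed through the same three stage filters to define the control event
#' set.  Every rejected candidate is recorded with the first filter that
#' removed it.
#'
#' @param candidates Named list of candidate `data.frame`s (one per RNA
#'   sample, see [call_candidates()]); a single `data.frame` is accepted.
#' @param control_candidates Named list (possibly empty) of candidate
#'   `data.frame`s for the negative-control samples.
#' @param config A [filter_config()].
#' @param target_key Optional `"chrom:pos:strand"` string marking the
#'   engineered target site.
#' @return A list with elements:
#'   * `events`: named list of surviving-event `data.frame`s (candidate
#'     columns plus `passed_filters` and `is_target`);
#'   * `audit`: `data.frame` of rejections (`sample, chrom, pos, strand,
#'     stage`);
#'   * `thresholds`: per-sample depth/score thresholds;
#'   * `control_events`: the subtracted control event set.
#' @export
run_cascade <- function(candidates, control_candidates = list(),
                        config = filter_config(), target_key = NULL) {
  stopifnot(inherits(config, "filter_config"))
  if (is.data.frame(candidates)) {
    candidates <- stats::setNames(list(candidates),
                                  candidates$sample[1L] %||% "sample")
  }
  if (is.data.frame(control_candidates)) {
    control_candidates <- list(control_candidates)
  }
  if (is.null(names(candidates))) {
    names(candidates) <- paste0("sample", seq_along(candidates))
  }

  control_events <- lapply(control_candidates, function(cc) {
    st <- cascade_stage_filters(cc, config)
    cc[is.na(st$stage), , drop = FALSE]
  })

  events <- vector("list", length(candidates))
  names(events) <- names(candidates)
  audit <- list()
  thresholds <- list()
  filter_names <- c("fraction", "depth", "score", "control")
  for (s in names(candidates)) {
    cand <- candidates[[s]]
    st <- cascade_stage_filters(cand, config)
    stage <- st$stage
    ctrl_hit <- is.na(stage) &
      event_keys(cand) %in% unlist(lapply(control_events, event_keys),
                                   use.names = FALSE)
    stage[ctrl_hit] <- "control"

    surv <- cand[is.na(stage), , drop = FALSE]
    if (nrow(surv) > 0L) {
      surv$passed_filters <- paste(filter_names, collapse = ",")
      surv$is_target <- if (is.null(target_key)) FALSE else
        event_keys(surv) == target_key
    } else {
      surv$passed_filters <- character(0)
      surv$is_target <- logical(0)
    }
    rownames(surv) <- NULL
    events[[s]] <- surv
    rej <- which(!is.na(stage))
    if (length(rej)) {
      audit[[s]] <- data.frame(sample = s, chrom = cand$chrom[rej],
                               pos = cand$pos[rej], strand = cand$strand[rej],
                               stage = stage[rej], stringsAsFactors = FALSE)
    }
    thresholds[[s]] <- list(depth = st$depth_thr,
                            score_high = st$score_thr_high,
                            score_low = st$score_thr_low)
  }
  audit <- if (length(audit)) do.call(rbind, c(audit, make.row.names = FALSE))
           else data.frame(sample = character(0), chrom = character(0),
                           pos = integer(0), strand = character(0),
                           stage = character(0), stringsAsFactors = FALSE)
  list(events = events, audit = audit, thresholds = thresholds,
       control_events = control_events)
}

#' @keywords internal
`%||%` <- function(a, b) if (is.null(a) || length(a) == 0L || is.na(a[1L])) b else a
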