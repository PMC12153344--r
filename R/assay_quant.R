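# Quantification of companion assays: Sanger-trace editing extent, REMSA
# fraction bound, 1:1 binding isotherm Kd fits, and the descriptive
# additivity gap between accessory-protein combinations.

#' Sanger-trace editing extent
#'
#' Editing extent from the two chromatogram peak intensities at the edited
#' position: `100 * T / (T + C)` percent.
#'
#' @param peak_edited Intensity of the edited (T) peak.
#' @param peak_unedited Intensity of the unedited (C) peak.
#' @return Editing extent in percent.  Scale-invariant in the two
#'   intensities.
#' @examples
#' sanger_extent(819, 181)  # 81.9
#' @export
sanger_extent <- function(peak_edited, peak_unedited) {
  if (any(peak_edited < 0) || any(peak_unedited < 0)) {
    stop("peak intensities must be non-negative", call. = FALSE)
  }
  tot <- peak_edited + peak_unedited
  if (any(tot <= 0)) stop("both peaks zero: extent undefined", call. = FALSE)
  100 * peak_edited / tot
}

#' REMSA fraction bound
#'
#' `bound / (bound + unbound)` from the quantified band intensities of one
#' gel lane.
#'
#' @param bound_intensity Upper (bound complex) band intensity.
#' @param unbound_intensity Lower (free RNA) band intensity.
#' @return Proportion bound in `[0, 1]`.
#' @export
fraction_bound <- function(bound_intensity, unbound_intensity) {
  if (any(bound_intensity < 0) || any(unbound_intensity < 0)) {
    stop("band intensities must be non-negative", call. = FALSE)
  }
  tot <- bound_intensity + unbound_intensity
  if (any(tot <= 0)) stop("both bands zero: fraction undefined", call. = FALSE)
  bound_intensity / tot
}

#' Fit a 1:1 binding isotherm
#'
#' Least-squares fit of `F(c) = fmax * c / (Kd + c)` to a titration curve.
#' Initialisation is deterministic: `Kd0` is the concentration nearest the
#' half-maximal observed fraction and `fmax0` the maximum observed
#' fraction; the fit is bounded (`Kd > 0`, `0 < fmax <= 1.05`).
#'
#' @param curve A [simulate_titration()] result or any `data.frame` with
#'   columns `concentration` and `fraction_bound`.
#' @return An object of class `kd_fit`: list with `kd`, `fmax`, `rss`,
#'   `n_points`.
#' @examples
#' fit_kd(simulate_titration(0.5, 1, c(0.1, 0.25, 0.5, 1, 2, 4)))
#' @export
fit_kd <- function(curve) {
  stopifnot(all(c("concentration", "fraction_bound") %in% names(curve)))
  conc <- curve$concentration
  fb <- curve$fraction_bound
  if (length(unique(conc)) < 3L) {
    stop("Kd fit needs at least 3 distinct concentrations", call. = FALSE)
  }
  fmax0 <- max(fb)
  if (fmax0 <= 0) stop("all bound fractions are zero: cannot fit",
                       call. = FALSE)
  fmax0 <- min(max(fmax0, 1e-3), 1.05)
  pos <- conc[conc > 0]
  kd0 <- pos[which.min(abs(fb[conc > 0] - fmax0 / 2))]
  if (length(kd0) == 0L || kd0 <= 0) kd0 <- stats::median(pos)

  lower <- c(kd = 1e-9, fmax = 1e-6)
  upper <- c(kd = Inf, fmax = 1.05)
  fit <- tryCatch(
    stats::nls(fraction_bound ~ fmax * concentration / (kd + concentration),
               data = data.frame(concentration = conc, fraction_bound = fb),
               start = list(kd = kd0, fmax = fmax0),
               lower = lower, upper = upper, algorithm = "port",
               control = stats::nls.control(maxiter = 200,
                                            warnOnly = FALSE)),
    error = function(e) e)
  if (inherits(fit, "error")) {
    # fall back to bounded quasi-Newton on the residual sum of squares
    rss_fn <- function(p) sum((fb - p[2L] * conc / (p[1L] + conc))^2)
    opt <- stats::optim(c(kd0, fmax0), rss_fn, method = "L-BFGS-B",
                        lower = lower, upper = c(1e6, 1.05),
                        control = list(factr = 1e4))
    if (opt$convergence != 0) {
      stop("Kd fit failed to converge: nls error '", conditionMessage(fit),
           "'; optim code ", opt$convergence, call. = FALSE)
    }
    est <- c(kd = opt$par[1L], fmax = opt$par[2L])
    rss <- opt$value
  } else {
    est <- coef(fit)
    rss <- sum(resid(fit)^2)
  }
  structure(list(kd = unname(est["kd"]), fmax = unname(est["fmax"]),
                 rss = rss, n_points = length(conc)),
            class = "kd_fit")
}

#' @export
print.kd_fit <- function(x, ...) {
  cat(sprintf("<kd_fit> Kd = %.4g, fmax = %.4g (RSS %.3g over %d points)\n",
              x$kd, x$fmax, x$rss, x$n_points))
  invisible(x)
}

#' Additivity gap of editing extents
#'
#' The difference between the editing extent observed when two accessory
#' proteins are combined and the sum of their individual effects,
#' `combined - (a + b)`, in percentage points.  A gap near zero indicates
#' independent (additive) contributions; a strongly negative gap indicates
#' redundancy.
#'
#' @param combined,a,b Editing extents in percent, each in `[0, 100]`.
#' @return The gap in percentage points.
#' @examples
#' additivity_gap(82, 31, 56)  # -5
#' @export
additivity_gap <- function(combined, a, b) {
  for (v in list(combined, a, b)) {
    if (any(v < 0 | v > 100)) {
      stop("extents must be percentages in [0, 100]", call. = FALSE)
    }
  }
  combined - (a + b)
}
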