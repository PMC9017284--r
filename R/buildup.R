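# NOESY build-up / decay curve fitting: monoexponential diagonal decays,
# two-spin cross-peak build-ups, side averaging and quality filtering.

#' NOESY build-up curve
#'
#' One diagonal- or cross-peak intensity series over the NOESY mixing-time
#' grid. A diagonal peak has `group_i == group_j`.
#'
#' @param peak_id Peak identifier (character).
#' @param group_i,group_j Proton-group identifiers; equal for diagonal peaks.
#' @param mixing_times Mixing times in seconds, strictly increasing, >= 2.
#' @param intensities Peak integrals (arbitrary units), same length.
#' @param side Which side of the spectral diagonal the series was integrated
#'   on: `"above"`, `"below"` or `"averaged"`.
#' @return An object of class `buildup_curve`.
#' @export
buildup_curve <- function(peak_id, group_i, group_j, mixing_times, intensities,
                          side = c("above", "below", "averaged")) {
  side <- match.arg(side)
  mixing_times <- as.numeric(mixing_times)
  intensities <- as.numeric(intensities)
  if (length(mixing_times) < 2L)
    stop("a build-up curve needs at least 2 mixing times")
  if (length(intensities) != length(mixing_times))
    stop("mixing_times and intensities must have the same length")
  if (any(diff(mixing_times) <= 0))
    stop("mixing_times must be strictly increasing")
  structure(list(peak_id = as.character(peak_id),
                 group_i = as.character(group_i),
                 group_j = as.character(group_j),
                 mixing_times = mixing_times,
                 intensities = intensities,
                 side = side),
            class = "buildup_curve")
}

#' @export
print.buildup_curve <- function(x, ...) {
  cat(sprintf("<buildup_curve> %s: %s-%s (%s), %d mixing times\n", x$peak_id,
              x$group_i, x$group_j, x$side, length(x$mixing_times)))
  invisible(x)
}

is_diagonal <- function(curve) identical(curve$group_i, curve$group_j)

#' Fit a monoexponential diagonal-peak decay
#'
#' Least-squares fit of \eqn{M(t) = M_0 \exp(-\rho t)} to a diagonal peak
#' series, returning the autorelaxation rate \eqn{\rho} and initial
#' magnetization \eqn{M_0}. The rate is found by a deterministic 1-D search
#' with the amplitude profiled out in closed form. Non-decaying data are
#' flagged (`ok = FALSE`) rather than raising an error.
#'
#' @param curve A diagonal [buildup_curve()] with >= 3 points.
#' @param rho_max Upper bound of the rate search, s^-1.
#' @return A list of class `autorelax_fit` with elements `group_id`, `rho`,
#'   `m0`, `residual_rms` (RMS residual normalized by the maximum absolute
#'   intensity) and `ok`.
#' @export
fit_autorelaxation <- function(curve, rho_max = 100) {
  stopifnot(inherits(curve, "buildup_curve"))
  if (!is_diagonal(curve))
    stop("fit_autorelaxation expects a diagonal peak (group_i == group_j)")
  t <- curve$mixing_times
  y <- curve$intensities
  if (length(t) < 3L) stop("need >= 3 points for a 2-parameter fit")
  scale <- max(abs(y))
  if (scale == 0)
    return(structure(list(group_id = curve$group_i, rho = NA_real_,
                          m0 = NA_real_, residual_rms = 0, ok = FALSE),
                     class = "autorelax_fit"))
  # profile m0: for fixed rho, m0 = sum(y e) / sum(e^2), e = exp(-rho t)
  sse <- function(rho) {
    e <- exp(-rho * t)
    m0 <- sum(y * e) / sum(e * e)
    sum((y - m0 * e)^2)
  }
  opt <- stats::optimize(sse, c(0, rho_max), tol = 1e-12)
  rho <- opt$minimum
  # polish near the boundary / flat cases with a golden refinement around opt
  e <- exp(-rho * t)
  m0 <- sum(y * e) / sum(e * e)
  res_rms <- sqrt(mean((y - m0 * e)^2)) / scale
  ok <- rho > 1e-6 && m0 > 0 && sse(0) > opt$objective + 1e-30
  structure(list(group_id = curve$group_i, rho = if (ok) rho else NA_real_,
                 m0 = if (ok) m0 else NA_real_,
                 residual_rms = res_rms, ok = ok),
            class = "autorelax_fit")
}

# two-spin cross-peak solution; rho_bar = (rho_i+rho_j)/2, delta=(rho_i-rho_j)/2
# Delta = sqrt(delta^2 + sigma^2); M_ij(t) = -m0 (sigma/Delta) sinh(Delta t) e^{-rho_bar t}
two_spin_cross <- function(t, sigma, rho_i, rho_j, m0) {
  rb <- (rho_i + rho_j) / 2
  dl <- (rho_i - rho_j) / 2
  Dl <- sqrt(dl^2 + sigma^2)
  if (Dl == 0) return(-m0 * sigma * t * exp(-rb * t))
  -m0 * (sigma / Dl) * sinh(Dl * t) * exp(-rb * t)
}

#' Fit a two-spin cross-peak build-up
#'
#' Fits the isolated two-spin solution
#' \deqn{\Delta M_{ij}(t) = -M_0 \frac{\sigma}{\Delta}\sinh(\Delta t)
#'   e^{-\bar\rho t}, \quad \Delta = \sqrt{((\rho_i-\rho_j)/2)^2 + \sigma^2}}
#' with \eqn{\sigma} as the single free parameter; \eqn{\rho_i}, \eqn{\rho_j}
#' and \eqn{M_0} come from the diagonal fits. The search is a deterministic
#' bounded scalar least squares run separately on the negative and positive
#' sigma branch. Fit quality is the RMS residual normalized by the maximum
#' absolute intensity of the curve; fits above `threshold` are marked not
#' accepted (spin diffusion / noise rejection).
#'
#' @param curve A cross-peak [buildup_curve()] (`group_i != group_j`).
#' @param rho_i,rho_j Autorelaxation rates of the two groups, s^-1. If one is
#'   unavailable (`NA`), the other is used for both.
#' @param m0 Initial magnetization from the diagonal fit.
#' @param ctx Optional [relaxation_context()]; when supplied and the fit is
#'   accepted, the distance in Angstrom is attached.
#' @param threshold Acceptance threshold on the normalized RMS residual
#'   (default 0.15).
#' @param sigma_max Bound of the sigma search, s^-1.
#' @param sigma_scale Divide the fitted sigma by this factor before distance
#'   conversion (equivalent-proton multiplicity correction hook; default 1).
#' @return A list of class `crossrelax_fit` with `group_i`, `group_j`,
#'   `sigma`, `distance` (Angstrom or `NA`), `fit_quality`, `accepted`.
#' @export
fit_crossrelaxation <- function(curve, rho_i, rho_j, m0, ctx = NULL,
                                threshold = 0.15, sigma_max = 100,
                                sigma_scale = 1) {
  stopifnot(inherits(curve, "buildup_curve"))
  if (is_diagonal(curve))
    stop("fit_crossrelaxation expects a cross peak (group_i != group_j)")
  t <- curve$mixing_times
  y <- curve$intensities
  if (length(t) < 2L) stop("insufficient data: need >= 2 mixing times")
  if (is.na(rho_i) && is.na(rho_j)) stop("need at least one autorelaxation rate")
  if (is.na(rho_i)) rho_i <- rho_j
  if (is.na(rho_j)) rho_j <- rho_i
  scale <- max(abs(y))
  if (scale == 0) {
    fit <- list(group_i = curve$group_i, group_j = curve$group_j,
                sigma = 0, distance = NA_real_, fit_quality = Inf,
                accepted = FALSE, m0 = m0)
    return(structure(fit, class = "crossrelax_fit"))
  }
  sse <- function(s) sum((y - two_spin_cross(t, s, rho_i, rho_j, m0))^2)
  neg <- stats::optimize(sse, c(-sigma_max, 0), tol = 1e-13)
  pos <- stats::optimize(sse, c(0, sigma_max), tol = 1e-13)
  best <- if (neg$objective <= pos$objective) neg else pos
  sigma <- best$minimum
  quality <- sqrt(best$objective / length(t)) / scale
  accepted <- quality <= threshold && abs(sigma) > 1e-9
  distance <- NA_real_
  if (accepted && !is.null(ctx)) {
    distance <- tryCatch(distance_from_sigma(sigma / sigma_scale, ctx),
                         error = function(e) NA_real_)
    if (is.na(distance)) accepted <- FALSE
  }
  structure(list(group_i = curve$group_i, group_j = curve$group_j,
                 sigma = sigma, distance = distance, fit_quality = quality,
                 accepted = accepted, m0 = m0),
            class = "crossrelax_fit")
}

#' Average a cross peak over both sides of the diagonal
#'
#' Pointwise mean of the two series integrated above and below the spectral
#' diagonal, which reduces integration noise.
#'
#' @param curve_above,curve_below [buildup_curve()] objects for the same
#'   group pair on the same mixing-time grid.
#' @return A [buildup_curve()] with `side = "averaged"`.
#' @export
average_diagonal_sides <- function(curve_above, curve_below) {
  stopifnot(inherits(curve_above, "buildup_curve"),
            inherits(curve_below, "buildup_curve"))
  same <- (identical(curve_above$group_i, curve_below$group_i) &&
             identical(curve_above$group_j, curve_below$group_j)) ||
          (identical(curve_above$group_i, curve_below$group_j) &&
             identical(curve_above$group_j, curve_below$group_i))
  if (!same) stop("curves refer to different group pairs")
  if (length(curve_above$mixing_times) != length(curve_below$mixing_times) ||
      any(curve_above$mixing_times != curve_below$mixing_times))
    stop("alignment error: mixing-time grids differ")
  buildup_curve(curve_above$peak_id, curve_above$group_i, curve_above$group_j,
                curve_above$mixing_times,
                (curve_above$intensities + curve_below$intensities) / 2,
                side = "averaged")
}

#' Partition cross-relaxation fits by fit quality
#'
#' @param fits A list of `crossrelax_fit` objects.
#' @param threshold Maximum accepted normalized RMS residual (default 0.15).
#' @return List with elements `accepted` and `rejected` (each a list);
#'   every input lands in exactly one. Accepted fits keep their distance;
#'   rejected fits have it removed.
#' @export
quality_filter <- function(fits, threshold = 0.15) {
  if (threshold <= 0) stop("threshold must be positive")
  keep <- vapply(fits, function(f) f$fit_quality <= threshold &&
                   abs(f$sigma) > 1e-9, logical(1))
  rejected <- lapply(fits[!keep], function(f) {
    f$accepted <- FALSE; f$distance <- NA_real_; f
  })
  accepted <- lapply(fits[keep], function(f) { f$accepted <- TRUE; f })
  list(accepted = accepted, rejected = rejected)
}

#' Read / write a NOESY peak table
#'
#' The interchange format is delimited text with header columns `peak_id`,
#' `group_i`, `group_j`, `mixing_time_s`, `intensity`, `side` (long format:
#' one row per mixing time).
#'
#' @param path File path.
#' @param sep Field separator (default comma).
#' @return `read_peak_table`: a data.frame. `write_peak_table`: the path,
#'   invisibly.
#' @export
read_peak_table <- function(path, sep = ",") {
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE)
  required <- c("peak_id", "group_i", "group_j", "mixing_time_s", "intensity")
  missing <- setdiff(required, names(df))
  if (length(missing))
    stop("peak table is missing required column(s): ",
         paste(missing, collapse = ", "))
  if (!"side" %in% names(df)) df$side <- "averaged"
  df
}

#' @rdname read_peak_table
#' @param peaks Data.frame in the peak-table layout.
#' @export
write_peak_table <- function(peaks, path, sep = ",") {
  cols <- c("peak_id", "group_i", "group_j", "mixing_time_s", "intensity", "side")
  utils::write.table(peaks[cols], path, sep = sep, row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Group a long-format peak table into build-up curves
#'
#' @param peaks Data.frame as returned by [read_peak_table()].
#' @param average_sides Average `above`/`below` series of the same pair into
#'   one curve (default `TRUE`).
#' @return Named list of [buildup_curve()] objects (name = peak id).
#' @export
as_buildup_curves <- function(peaks, average_sides = TRUE) {
  key <- paste(peaks$group_i, peaks$group_j, peaks$side, sep = "\r")
  split_df <- split(peaks, key)
  curves <- lapply(split_df, function(d) {
    d <- d[order(d$mixing_time_s), ]
    buildup_curve(d$peak_id[1], d$group_i[1], d$group_j[1],
                  d$mixing_time_s, d$intensity, side = d$side[1])
  })
  if (average_sides) {
    pair_key <- vapply(curves, function(cv)
      paste(sort(c(cv$group_i, cv$group_j)), collapse = "\r"), character(1))
    curves <- lapply(split(curves, pair_key), function(cl) {
      if (length(cl) == 2L) average_diagonal_sides(cl[[1]], cl[[2]]) else cl[[1]]
    })
  }
  names(curves) <- vapply(curves, function(cv) cv$peak_id, character(1))
  curves
}

#' Fit every curve in a peak table
#'
#' Convenience driver: fits all diagonal peaks first, then all cross peaks
#' using the mean available autorelaxation rate and the source-side diagonal
#' amplitude.
#'
#' @param curves Named list from [as_buildup_curves()].
#' @param ctx A [relaxation_context()] for distance conversion.
#' @param threshold Fit-quality acceptance threshold.
#' @param sigma_scale Multiplicity correction passed to
#'   [fit_crossrelaxation()].
#' @return List with `auto` (autorelaxation fits by group id) and `cross`
#'   (cross-relaxation fits).
#' @export
fit_peak_table <- function(curves, ctx, threshold = 0.15, sigma_scale = 1) {
  diag_curves <- Filter(is_diagonal, curves)
  auto <- lapply(diag_curves, fit_autorelaxation)
  names(auto) <- vapply(diag_curves, function(cv) cv$group_i, character(1))
  get_rho <- function(g) {
    f <- auto[[g]]
    if (is.null(f) || !f$ok) NA_real_ else f$rho
  }
  get_m0 <- function(gi, gj) {
    for (g in c(gj, gi)) {  # source-side diagonal first
      f <- auto[[g]]
      if (!is.null(f) && f$ok) return(f$m0)
    }
    1
  }
  cross_curves <- Filter(function(cv) !is_diagonal(cv), curves)
  cross <- lapply(cross_curves, function(cv)
    fit_crossrelaxation(cv, get_rho(cv$group_i), get_rho(cv$group_j),
                        get_m0(cv$group_i, cv$group_j), ctx = ctx,
                        threshold = threshold, sigma_scale = sigma_scale))
  list(auto = auto, cross = cross)
}
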