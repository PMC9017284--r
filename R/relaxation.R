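# Two-spin dipolar cross-relaxation physics: spectral densities, sigma <-> r
# conversion, and isotropic rotational correlation time estimation from 15N
# relaxation rates.

# Physical constants (CODATA 2018). Fixed; never user-mutable.
.nmr2_const <- list(
  mu0     = 4 * pi * 1e-7,        # vacuum permeability, T m / A
  hbar    = 1.054571817e-34,      # reduced Planck constant, J s
  gamma_h = 2.6752218744e8,       # 1H gyromagnetic ratio, rad s^-1 T^-1
  gamma_n = -2.71261804e7,        # 15N gyromagnetic ratio, rad s^-1 T^-1
  r_nh    = 1.02e-10,             # backbone N-H bond length, m
  csa_n   = -160e-6               # 15N CSA (axially symmetric), unitless
)

#' Relaxation context for cross-relaxation / distance conversion
#'
#' Bundles the rotational correlation time, the proton Larmor frequency and
#' the physical constants needed to interconvert cross-relaxation rates and
#' interproton distances. The spectral density convention used throughout the
#' package is the plain Lorentzian \eqn{J(\omega) = \tau_c / (1 +
#' \omega^2\tau_c^2)} (so \eqn{J(0) = \tau_c}), with the 1/10 dipolar
#' prefactor carried in the rate expression.
#'
#' @param tau_c Rotational correlation time of the receptor, seconds
#'   (e.g. `10.5e-9` for a ~15 kDa bromodomain at 303 K).
#' @param field_mhz Spectrometer proton frequency in MHz (default 800).
#' @return An object of class `relaxation_context`.
#' @examples
#' ctx <- relaxation_context(tau_c = 10.1e-9, field_mhz = 800)
#' spectral_density(0, ctx)  # equals tau_c
#' @export
relaxation_context <- function(tau_c, field_mhz = 800) {
  if (!is.numeric(tau_c) || length(tau_c) != 1L || !is.finite(tau_c) || tau_c <= 0)
    stop("invalid relaxation context: tau_c must be a single positive number (seconds)")
  if (!is.numeric(field_mhz) || length(field_mhz) != 1L || field_mhz <= 0)
    stop("invalid relaxation context: field_mhz must be a single positive number")
  structure(
    list(tau_c = tau_c,
         field_mhz = field_mhz,
         proton_larmor = 2 * pi * field_mhz * 1e6,
         mu0 = .nmr2_const$mu0,
         hbar = .nmr2_const$hbar,
         gamma_h = .nmr2_const$gamma_h),
    class = "relaxation_context")
}

#' @export
print.relaxation_context <- function(x, ...) {
  cat(sprintf("<relaxation_context> tau_c = %.3g ns, field = %g MHz\n",
              x$tau_c * 1e9, x$field_mhz))
  invisible(x)
}

.check_ctx <- function(ctx) {
  if (!inherits(ctx, "relaxation_context"))
    stop("ctx must be a relaxation_context object")
  if (ctx$tau_c <= 0) stop("invalid relaxation context: tau_c must be positive")
  invisible(ctx)
}

#' Lorentzian spectral density
#'
#' \eqn{J(\omega) = \tau_c / (1 + \omega^2 \tau_c^2)} for isotropic rigid
#' tumbling. Vectorized over `omega`.
#'
#' @param omega Angular frequency, rad/s (>= 0).
#' @param ctx A [relaxation_context()].
#' @return Spectral density in seconds.
#' @export
spectral_density <- function(omega, ctx) {
  .check_ctx(ctx)
  if (any(omega < 0)) stop("omega must be >= 0")
  ctx$tau_c / (1 + omega^2 * ctx$tau_c^2)
}

# dipolar prefactor (mu0/4pi)^2 hbar^2 gamma_h^4 / 10, SI
.dipolar_prefactor <- function(ctx) {
  (ctx$mu0 / (4 * pi))^2 * ctx$hbar^2 * ctx$gamma_h^4 / 10
}

# spectral density combination entering the homonuclear cross-relaxation rate
.sigma_jterm <- function(ctx) {
  6 * spectral_density(2 * ctx$proton_larmor, ctx) - spectral_density(0, ctx)
}

#' Cross-relaxation rate from interproton distance
#'
#' Homonuclear dipolar cross-relaxation rate for an isolated two-spin pair:
#' \deqn{\sigma = (\mu_0/4\pi)^2 \hbar^2 \gamma_H^4 / (10 r^6) \,
#'   [6 J(2\omega_H) - J(0)]}
#' In the slow-tumbling regime (\eqn{\tau_c} of several ns) the bracket is
#' negative, so \eqn{\sigma < 0} and NOESY cross peaks have the same sign as
#' the diagonal.
#'
#' @param r Interproton distance in Angstrom (> 0). Vectorized.
#' @param ctx A [relaxation_context()].
#' @return Cross-relaxation rate(s) in s^-1.
#' @export
sigma_from_distance <- function(r, ctx) {
  .check_ctx(ctx)
  if (any(!is.finite(r)) || any(r <= 0)) stop("r must be positive (Angstrom)")
  r_m <- r * 1e-10
  .dipolar_prefactor(ctx) / r_m^6 * .sigma_jterm(ctx)
}

#' Interproton distance from cross-relaxation rate
#'
#' Exact algebraic inverse of [sigma_from_distance()]. The supplied rate must
#' have the sign implied by the context's correlation time (negative in slow
#' tumbling); a zero or wrong-signed rate has no solution.
#'
#' @param sigma Cross-relaxation rate(s), s^-1. Vectorized.
#' @param ctx A [relaxation_context()].
#' @return Distance(s) in Angstrom.
#' @export
distance_from_sigma <- function(sigma, ctx) {
  .check_ctx(ctx)
  jterm <- .sigma_jterm(ctx)
  ratio <- .dipolar_prefactor(ctx) * jterm / sigma
  if (any(!is.finite(ratio)) || any(ratio <= 0))
    stop("no solution: sigma must be nonzero with the sign of 6J(2w)-J(0) ",
         sprintf("(here %s)", if (jterm < 0) "negative" else "positive"))
  ratio^(1 / 6) * 1e10
}

# 15N longitudinal / transverse relaxation rates (dipolar N-H + CSA) under
# the package's Lorentzian J. R1rho is treated as R2 (no exchange term).
.n15_rate_parts <- function(tau_c, field_mhz) {
  cst <- .nmr2_const
  b0 <- 2 * pi * field_mhz * 1e6 / cst$gamma_h
  w_h <- cst$gamma_h * b0
  w_n <- abs(cst$gamma_n) * b0
  d <- (cst$mu0 / (4 * pi)) * cst$hbar * cst$gamma_h * abs(cst$gamma_n) / cst$r_nh^3
  cc <- w_n * cst$csa_n / sqrt(3)
  jj <- function(w) tau_c / (1 + w^2 * tau_c^2)
  r1 <- d^2 / 4 * (jj(w_h - w_n) + 3 * jj(w_n) + 6 * jj(w_h + w_n)) + cc^2 * jj(w_n)
  r2 <- d^2 / 8 * (4 * jj(0) + jj(w_h - w_n) + 3 * jj(w_n) + 6 * jj(w_h) +
                     6 * jj(w_h + w_n)) +
        cc^2 / 6 * (4 * jj(0) + 3 * jj(w_n))
  c(r1 = r1, r2 = r2)
}

#' Forward-simulate backbone 15N relaxation rates
#'
#' Longitudinal (R1) and transverse (R2, taken equal to R1rho) 15N rates for
#' a rigid isotropic tumbler, from the N-H dipolar and 15N CSA mechanisms.
#' Mainly useful to round-trip [estimate_tau_c()].
#'
#' @param tau_c Rotational correlation time, seconds.
#' @param field_mhz Spectrometer proton frequency, MHz.
#' @return Named numeric vector `c(r1 = ..., r2 = ...)`, s^-1.
#' @export
n15_rates <- function(tau_c, field_mhz = 800) {
  if (tau_c <= 0) stop("tau_c must be positive")
  .n15_rate_parts(tau_c, field_mhz)
}

#' Estimate the rotational correlation time from 15N relaxation
#'
#' Solves the isotropic \eqn{R_2/R_1} ratio relation for \eqn{\tau_c} by a
#' bracketed root search; \eqn{R_{1\rho}} is treated as \eqn{R_2} (no exchange
#' contribution). This is a simplified isotropic replacement for full
#' diffusion-tensor analyses: anisotropy, exchange and internal motion are
#' all neglected.
#'
#' @param t1_rate 15N R1 in s^-1 (> 0).
#' @param t1rho_rate 15N R1rho in s^-1 (>= `t1_rate`).
#' @param field_mhz Spectrometer proton frequency, MHz.
#' @param interval Search bracket for tau_c in seconds.
#' @return Estimated tau_c in seconds.
#' @export
estimate_tau_c <- function(t1_rate, t1rho_rate, field_mhz = 800,
                           interval = c(1e-12, 1e-6)) {
  if (t1_rate <= 0 || t1rho_rate <= 0) stop("relaxation rates must be positive")
  if (t1rho_rate < t1_rate) stop("t1rho_rate must be >= t1_rate")
  target <- t1rho_rate / t1_rate
  ratio_at <- function(tc) {
    p <- .n15_rate_parts(tc, field_mhz)
    p[["r2"]] / p[["r1"]]
  }
  lo <- ratio_at(interval[1])
  hi <- ratio_at(interval[2])
  if (target < lo)
    stop("out of range: R2/R1 ratio below the extreme-narrowing minimum (",
         signif(lo, 6), ")")
  if (target > hi)
    stop("out of range: R2/R1 ratio above the slow-tumbling bracket")
  stats::uniroot(function(tc) ratio_at(tc) - target,
                 interval = interval, tol = 1e-18)$root
}
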