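# Population-level collective states. The N-component population with a
# definite number ell of right-lateralized members lives in the
# permutation-symmetric (Dicke) sector, an (N+1)-dimensional space with
# basis |ell>, ell = 0..N. Working there (not in the 2^N product space)
# keeps everything exact for N in the thousands; the full product space is
# only ever built by the test oracle at small N.

#' Collective population state |ell> in the symmetric sector
#'
#' Represents the normalized symmetric superposition of `ell` right-biased
#' (`R`) and `N - ell` left-biased (`L`) individuals. Derived quantities:
#' \eqn{N_R = \ell}, \eqn{N_L = N - \ell}, the ratio \eqn{X = N_L/N_R}
#' (defined only when \eqn{\ell > 0}) and the asymmetry order parameter
#' \eqn{M = \ell - N/2 = (N_R - N_L)/2}.
#'
#' @param N Population size, positive integer.
#' @param ell Number of right-lateralized individuals, integer in `0..N`.
#' @return An object of class `"population_state"` with fields `N`, `ell`,
#'   `N_R`, `N_L`, `X` (`NA` with `X_defined = FALSE` when `ell = 0`), `M`,
#'   and `amplitudes` (length `N + 1`, a 1 in position `ell + 1`).
#' @examples
#' population_state(10, 7)   # M = 2, X = 3/7
#' @export
population_state <- function(N, ell) {
  N <- check_count(N, "N", min = 1)
  ell <- check_count(ell, "ell", min = 0)
  if (ell > N) stop("`ell` must lie in 0..N", call. = FALSE)
  amp <- numeric(N + 1)
  amp[ell + 1] <- 1
  X_defined <- ell > 0
  structure(
    list(
      N = N, ell = ell,
      N_R = ell, N_L = N - ell,
      X = if (X_defined) (N - ell) / ell else NA_real_,
      X_defined = X_defined,
      M = ell - N / 2,
      amplitudes = amp
    ),
    class = "population_state"
  )
}

check_count <- function(x, name, min = 0) {
  if (!is.numeric(x) || length(x) != 1 || !is.finite(x) ||
      x != round(x) || x < min) {
    stop(sprintf("`%s` must be an integer >= %d", name, min), call. = FALSE)
  }
  as.integer(x)
}

#' @export
print.population_state <- function(x, ...) {
  cat(sprintf("<population_state> N = %d, ell = N_R = %d, N_L = %d\n",
              x$N, x$N_R, x$N_L))
  cat(sprintf("  M = %g, X = %s\n", x$M,
              if (x$X_defined) format(x$X) else "undefined (N_R = 0)"))
  invisible(x)
}

#' Asymmetry order parameter M
#'
#' The collective order parameter \eqn{M = \langle\ell|S_3|\ell\rangle =
#' \ell - N/2 = (N_R - N_L)/2}; a nonzero value signals asymmetry of the
#' population under the R/L exchange. When \eqn{X} is defined the equivalent
#' form \eqn{M = N_R (1 - X)/2} is verified internally.
#'
#' @param state A `"population_state"`.
#' @return A real scalar.
#' @export
asymmetry_measure <- function(state) {
  stopifnot(inherits(state, "population_state"))
  M <- state$ell - state$N / 2
  if (state$X_defined) {
    M2 <- state$N_R * (1 - state$X) / 2
    if (abs(M - M2) > 1e-9 * max(1, abs(M))) {
      stop("internal inconsistency between the two forms of M")
    }
  }
  M
}

#' Collective ladder and projection operators in the Dicke basis
#'
#' The operators \eqn{S_\pm, S_3} of the total (pseudo)spin \eqn{j = N/2} in
#' the symmetric sector, as `(N+1) x (N+1)` matrices over the basis
#' \eqn{|\ell\rangle,\ \ell = 0..N}, with
#' \eqn{S_3|\ell\rangle = (\ell - N/2)|\ell\rangle} and
#' \eqn{S_+|\ell\rangle = \sqrt{(N-\ell)(\ell+1)}\,|\ell+1\rangle}.
#' They satisfy \eqn{[S_3, S_\pm] = \pm S_\pm} and \eqn{[S_+, S_-] = 2 S_3}
#' exactly at every N. The \eqn{1/\sqrt N}-rescaled ladder operators are
#' included for the large-N contraction analysis.
#'
#' @param N Population size.
#' @return An object of class `"collective_operators"`: list with `N`,
#'   `S_plus`, `S_minus`, `S_3`, and rescaled `S_plus_scaled`,
#'   `S_minus_scaled` (\eqn{S_\pm/\sqrt N}).
#' @export
collective_operators <- function(N) {
  N <- check_count(N, "N", min = 1)
  ell <- 0:N
  dim <- N + 1
  Sp <- matrix(0, dim, dim)
  # S_+ : |ell> -> sqrt((N - ell)(ell + 1)) |ell + 1>
  for (l in 0:(N - 1)) Sp[l + 2, l + 1] <- sqrt((N - l) * (l + 1))
  S3 <- diag(ell - N / 2)
  structure(
    list(
      N = N,
      S_plus = Sp,
      S_minus = t(Sp),
      S_3 = S3,
      S_plus_scaled = Sp / sqrt(N),
      S_minus_scaled = t(Sp) / sqrt(N)
    ),
    class = "collective_operators"
  )
}

#' Hyperbolic angle from population fractions
#'
#' Inverts the parameterization \eqn{N_L/N = \tanh^2\theta},
#' \eqn{N_R/N = 1/\cosh^2\theta}, under which the ratio is
#' \eqn{X = N_L/N_R = \sinh^2\theta}. Only \eqn{\theta \ge 0} is used: the
#' map \eqn{\theta \to -\theta} leaves every observable invariant.
#'
#' @param N_L Number of left-biased individuals, with `0 < N_L < N`; the
#'   boundary values are rejected (they correspond to \eqn{\theta = 0} or
#'   \eqn{\theta = \infty}, i.e. to the excluded all-R / all-L populations).
#' @param N Population size.
#' @return \eqn{\theta = \mathrm{artanh}\sqrt{N_L/N} \ge 0}.
#' @examples
#' th <- theta_from_fractions(5, 10)
#' sinh(th)^2   # X = N_L/N_R = 1
#' @export
theta_from_fractions <- function(N_L, N) {
  if (!is.numeric(N_L) || !is.numeric(N) || length(N_L) != 1 ||
      length(N) != 1 || !is.finite(N_L) || !is.finite(N)) {
    stop("`N_L` and `N` must be finite scalars", call. = FALSE)
  }
  if (N_L <= 0 || N_L >= N) {
    stop("`N_L` must satisfy 0 < N_L < N: the all-L and all-R populations ",
         "correspond to theta = Inf or 0 and are excluded", call. = FALSE)
  }
  atanh(sqrt(N_L / N))
}

#' Ratio X as a function of the hyperbolic angle
#'
#' @param theta Hyperbolic angle, \eqn{\theta \ge 0}.
#' @return \eqn{X(\theta) = \sinh^2\theta}.
#' @export
ratio_from_theta <- function(theta) {
  stopifnot(is.numeric(theta), all(theta >= 0))
  sinh(theta)^2
}

#' Occupation probability W_X
#'
#' Probability of drawing one R-state together with `X` L-states out of the
#' population, \eqn{W_X = (N_R/N)(N_L/N)^X = \tanh^{2X}\theta /
#' \cosh^2\theta}. As a function of the nonnegative integer index `X` this is
#' a geometric distribution: \eqn{\sum_{X \ge 0} W_X = 1} and
#' \eqn{0 < W_X < 1} for \eqn{\theta \ne 0}. (The continuous ratio
#' \eqn{X(\theta) = \sinh^2\theta} is a distinct, real-valued quantity; the
#' two meet only through \eqn{\theta}.)
#'
#' @param theta Hyperbolic angle (real; only \eqn{\theta^2} enters).
#' @param X Nonnegative integer index (vectorized).
#' @return `W_X` values in `(0, 1)` (with `W_0 = 1` at `theta = 0`).
#' @export
occupation_probability <- function(theta, X) {
  if (!is.numeric(theta) || length(theta) != 1 || !is.finite(theta)) {
    stop("`theta` must be a finite scalar", call. = FALSE)
  }
  if (!is.numeric(X) || any(!is.finite(X)) || any(X != round(X)) ||
      any(X < 0)) {
    stop("`X` must be a nonnegative integer (vector)", call. = FALSE)
  }
  t2 <- tanh(theta)^2
  (1 / cosh(theta)^2) * t2^X
}

#' su(2) -> e(2) contraction residual of the rescaled ladder operators
#'
#' At fixed asymmetry \eqn{M = \ell - N/2}, the rescaled collective ladder
#' operators \eqn{S_\pm/\sqrt N} approach commuting "translations"
#' \eqn{N_R \to N_R \pm 1,\ N_L \to N_L \mp 1} as \eqn{N \to \infty}: the
#' su(2) algebra contracts to e(2) (the rotation generator \eqn{S_3} is
#' untouched). This diagnostic returns the operator norm of
#' \eqn{[S_+/\sqrt N,\ S_-/\sqrt N] - (2M/N)\,I} restricted to a window of
#' Dicke states centred on \eqn{\ell}, which decays as \eqn{O(1/N)} at fixed
#' M and window.
#'
#' @param N Population size.
#' @param ell Dicke index; alternatively supply `M` and `ell` is derived as
#'   `N/2 + M` (N + 2M must then be even and nonnegative).
#' @param M Asymmetry (used only when `ell` is missing).
#' @param window Odd window width (number of Dicke states retained around
#'   `ell`), default 11.
#' @return The residual operator norm (a nonnegative scalar).
#' @examples
#' contraction_residual(200, M = 1) < contraction_residual(20, M = 1)
#' @export
contraction_residual <- function(N, ell = NULL, M = NULL, window = 11) {
  N <- check_count(N, "N", min = 1)
  if (is.null(ell)) {
    if (is.null(M)) stop("supply `ell` or `M`", call. = FALSE)
    ell2 <- N / 2 + M
    if (ell2 != round(ell2)) {
      stop("N/2 + M must be an integer (N + 2M even)", call. = FALSE)
    }
    ell <- as.integer(ell2)
  }
  ell <- check_count(ell, "ell", min = 0)
  if (ell > N) stop("`ell` must lie in 0..N", call. = FALSE)
  window <- check_count(window, "window", min = 1)
  if (window %% 2 == 0) stop("`window` must be odd", call. = FALSE)
  h <- (window - 1) / 2
  lo <- ell - h
  hi <- ell + h
  if (lo < 0 || hi > N) {
    stop("window exceeds the Dicke basis range 0..N", call. = FALSE)
  }
  ops <- collective_operators(N)
  comm <- ops$S_plus_scaled %*% ops$S_minus_scaled -
    ops$S_minus_scaled %*% ops$S_plus_scaled
  idx <- (lo:hi) + 1
  Mval <- ell - N / 2
  resid <- comm[idx, idx] - diag(2 * Mval / N, length(idx))
  # operator (spectral) norm
  max(svd(resid, nu = 0, nv = 0)$d)
}

#' Environment-coupling interaction energy
#'
#' Expectation of the interaction \eqn{H_I = \lambda (b^* \tau_- + b \tau_+)}
#' for a single doublet, or its collective form
#' \eqn{H_I = \lambda (b^* S_- + b S_+)} on a population state. The
#' environment mode is modelled as a classical complex amplitude `b_amp`
#' (a c-number). At large N, matrix elements of \eqn{S_\pm} near the
#' equatorial Dicke states grow linearly in N, so the effective coupling
#' scale is reported as \eqn{\lambda N} in collective mode (the
#' strong-coupling regime \eqn{\lambda N \gg \lambda}).
#'
#' @param lambda Nonnegative coupling constant.
#' @param b_amp Complex environment amplitude.
#' @param state A `"spin_state"` on the (R, L) doublet basis, or a
#'   `"population_state"`.
#' @param collective If `TRUE`, use the collective operators \eqn{S_\pm}
#'   (requires a `"population_state"`); if `FALSE`, the single-component
#'   \eqn{\tau_\pm} (requires a 2-dimensional `"spin_state"`).
#' @return A list with `energy` (real expectation value) and
#'   `coupling_scale` (`lambda` or `lambda * N`).
#' @export
interaction_energy <- function(lambda, b_amp, state, collective = FALSE) {
  if (!is.numeric(lambda) || length(lambda) != 1 || !is.finite(lambda) ||
      lambda < 0) {
    stop("`lambda` must be a nonnegative scalar", call. = FALSE)
  }
  b_amp <- as.complex(b_amp)
  if (collective) {
    if (!inherits(state, "population_state")) {
      stop("collective mode requires a population_state", call. = FALSE)
    }
    ops <- collective_operators(state$N)
    H <- lambda * (Conj(b_amp) * ops$S_minus + b_amp * ops$S_plus)
    psi <- state$amplitudes
    scale <- lambda * state$N
  } else {
    if (!inherits(state, "spin_state") || length(state$amplitudes) != 2) {
      stop("single-component mode requires a 2-dimensional spin_state",
           call. = FALSE)
    }
    so <- spin_operators()
    H <- lambda * (Conj(b_amp) * so$tau_minus + b_amp * so$tau_plus)
    psi <- state$amplitudes
    scale <- lambda
  }
  val <- drop(Conj(psi) %*% H %*% psi)
  if (abs(Im(val)) > 1e-10) stop("interaction expectation not real")
  list(energy = Re(val), coupling_scale = scale)
}
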