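# Thermodynamics of the population L/R ratio. Units: k_B = 1, energies
# dimensionless; beta and E_X enter every equilibrium quantity only through
# the product beta * E_X (the API exposes both for readability).
#
# Parameterization: N_L/N = a = tanh^2(theta), N_R/N = 1/cosh^2(theta),
# X = N_L/N_R = sinh^2(theta), theta >= 0.

#' Population entropy as a function of the hyperbolic angle
#'
#' \eqn{S(\theta) = -(\sinh^2\theta \ln \sinh^2\theta - \cosh^2\theta \ln
#' \cosh^2\theta)}, i.e. with \eqn{X = \sinh^2\theta},
#' \eqn{S = (1+X)\ln(1+X) - X\ln X}: the Shannon entropy of the geometric
#' occupation law [occupation_probability()]. The \eqn{\theta = 0} limit is
#' handled analytically (\eqn{x \ln x \to 0}), giving \eqn{S(0) = 0};
#' \eqn{S} is nonnegative and strictly increasing on \eqn{\theta > 0}.
#'
#' @param theta Hyperbolic angle(s), \eqn{\ge 0} (vectorized).
#' @return Entropy value(s), dimensionless (\eqn{k_B = 1}).
#' @examples
#' entropy(atanh(1 / sqrt(2)))   # sinh^2 = 1, cosh^2 = 2: 2 log(2)
#' @export
entropy <- function(theta) {
  if (!is.numeric(theta) || any(!is.finite(theta)) || any(theta < 0)) {
    stop("`theta` must be finite and >= 0", call. = FALSE)
  }
  X <- sinh(theta)^2
  xlx <- ifelse(X == 0, 0, X * log(X))
  (1 + X) * log1p(X) - xlx
}

#' Free energy of the configuration with ratio X(theta)
#'
#' \eqn{F(\theta) = H_X - S(\theta)/\beta} with configuration energy
#' \eqn{H_X = X E_X = \sinh^2\theta \; E_X}. `E_X` is the (constant) energy
#' scale per unit of the ratio X.
#'
#' @param theta Hyperbolic angle(s) \eqn{\ge 0} (vectorized).
#' @param beta Inverse temperature \eqn{\beta = 1/T > 0} (\eqn{k_B = 1}).
#' @param E_X Configuration energy scale, \eqn{> 0}.
#' @return Free energy value(s).
#' @export
free_energy <- function(theta, beta, E_X) {
  check_beta_ex(beta, E_X)
  sinh(theta)^2 * E_X - entropy(theta) / beta
}

#' Derivative of the free energy with respect to theta
#'
#' \eqn{dF/d\theta = \sinh 2\theta \,(E_X + \ln\tanh^2\theta \,/\, \beta)};
#' vanishes at \eqn{\theta = 0} and at the interior stationary point where
#' \eqn{-\beta E_X = \ln\tanh^2\theta}.
#'
#' @inheritParams free_energy
#' @return Derivative value(s).
#' @export
free_energy_dtheta <- function(theta, beta, E_X) {
  check_beta_ex(beta, E_X)
  ifelse(theta == 0, 0,
         sinh(2 * theta) * (E_X + log(tanh(theta)^2) / beta))
}

check_beta_ex <- function(beta, E_X) {
  if (!is.numeric(beta) || length(beta) != 1 || !is.finite(beta) ||
      beta <= 0) {
    stop("`beta` must be a positive finite scalar", call. = FALSE)
  }
  if (!is.numeric(E_X) || length(E_X) != 1 || !is.finite(E_X) || E_X <= 0) {
    stop("`E_X` must be a positive finite scalar", call. = FALSE)
  }
  invisible(NULL)
}

#' Equilibrium of the population ratio by free-energy minimization
#'
#' Solves the stationarity condition \eqn{dF = 0}, i.e.
#' \eqn{-\beta E_X = \ln \tanh^2\theta = \ln (N_L/N)}: the equilibrium
#' fraction of left-biased individuals is the Boltzmann factor
#' \eqn{N_L/N = e^{-\beta E_X}}, the angle is
#' \eqn{\theta^* = \mathrm{artanh}\, e^{-\beta E_X / 2}} and the ratio
#' \eqn{X^* = e^{-\beta E_X}/(1 - e^{-\beta E_X})}. Both boundary values are
#' excluded for physical reasons: \eqn{N_L/N = 1} would require
#' \eqn{\beta E_X \approx 0} (infinite temperature) and \eqn{N_L/N = 0}
#' would require \eqn{\beta E_X = \infty} (zero temperature), so the
#' equilibrium ratio is always nonzero and finite.
#'
#' @inheritParams free_energy
#' @return An object of class `"lat_equilibrium"`: list with `theta_star`,
#'   `a_star` (\eqn{= N_L/N}), `X_star`, `M_sign` considerations aside,
#'   `beta`, `E_X`, `beta_E` (their product).
#' @examples
#' eq <- stationarity_solve(beta = 1, E_X = log(2))
#' eq$a_star    # 1/2
#' eq$X_star    # 1
#' @export
stationarity_solve <- function(beta, E_X) {
  check_beta_ex(beta, E_X)
  bE <- beta * E_X
  a <- exp(-bE)            # N_L / N
  theta <- atanh(sqrt(a))
  structure(
    list(
      theta_star = theta,
      a_star = a,
      X_star = a / (1 - a),
      beta = beta, E_X = E_X, beta_E = bE
    ),
    class = "lat_equilibrium"
  )
}

#' @export
print.lat_equilibrium <- function(x, ...) {
  cat(sprintf("<lat_equilibrium> beta*E_X = %.6g\n", x$beta_E))
  cat(sprintf("  theta* = %.10g\n  N_L/N  = %.10g\n  X*     = %.10g\n",
              x$theta_star, x$a_star, x$X_star))
  invisible(x)
}

# Numeric route to the same stationary point: root of dF/dtheta on the
# monotone substitution u = tanh^2(theta) in (0, 1). Kept separate from the
# closed form so the two can cross-validate each other.
stationarity_solve_numeric <- function(beta, E_X, tol = 1e-14) {
  check_beta_ex(beta, E_X)
  g <- function(u) E_X + log(u) / beta   # dF/dtheta sign on u in (0,1)
  lo <- exp(-beta * E_X) * 1e-3
  lo <- max(lo, .Machine$double.xmin * 1e10)
  root <- stats::uniroot(g, lower = lo, upper = 1 - 1e-15, tol = tol)
  u <- root$root
  list(theta_star = atanh(sqrt(u)), a_star = u, X_star = u / (1 - u))
}

#' System temperature defined by the observed ratio
#'
#' Inverts the equilibrium relation \eqn{N_L/N = X/(1+X) = e^{-E_X/T}}: an
#' observed nonzero finite ratio \eqn{X} defines the temperature
#' \eqn{T = E_X / \ln((1+X)/X)}. Round-trips with [stationarity_solve()].
#'
#' @param X Observed ratio \eqn{N_L/N_R > 0}, finite.
#' @param E_X Configuration energy scale, \eqn{> 0}.
#' @return Temperature \eqn{T > 0} (\eqn{k_B = 1}).
#' @examples
#' temperature_from_ratio(1, 1)   # 1 / log(2)
#' @export
temperature_from_ratio <- function(X, E_X) {
  if (!is.numeric(X) || length(X) != 1 || !is.finite(X) || X <= 0) {
    stop("`X` must be a positive finite scalar", call. = FALSE)
  }
  if (!is.numeric(E_X) || length(E_X) != 1 || !is.finite(E_X) || E_X <= 0) {
    stop("`E_X` must be a positive finite scalar", call. = FALSE)
  }
  E_X / log((1 + X) / X)
}

#' Free-energy profile over a theta grid
#'
#' Tabulates entropy and free energy on a grid of hyperbolic angles and
#' locates the stationary point.
#'
#' @inheritParams free_energy
#' @param theta_grid Increasing vector of angles \eqn{\ge 0}.
#' @return An object of class `"free_energy_profile"`: a data frame with
#'   columns `theta`, `X`, `S`, `F`, and attributes `theta_star`, `X_star`,
#'   `a_star`, `beta`, `E_X`.
#' @export
free_energy_profile <- function(beta, E_X,
                                theta_grid = seq(0, 3, length.out = 301)) {
  check_beta_ex(beta, E_X)
  if (is.unsorted(theta_grid, strictly = TRUE) || any(theta_grid < 0)) {
    stop("`theta_grid` must be strictly increasing and nonnegative",
         call. = FALSE)
  }
  eq <- stationarity_solve(beta, E_X)
  out <- data.frame(
    theta = theta_grid,
    X = sinh(theta_grid)^2,
    S = entropy(theta_grid),
    F = free_energy(theta_grid, beta, E_X)
  )
  structure(out,
            theta_star = eq$theta_star, X_star = eq$X_star,
            a_star = eq$a_star, beta = beta, E_X = E_X,
            class = c("free_energy_profile", "data.frame"))
}

#' @export
plot.free_energy_profile <- function(x, ...) {
  graphics::plot(x$theta, x$F, type = "l", xlab = expression(theta),
                 ylab = "F", ...)
  graphics::abline(v = attr(x, "theta_star"), lty = 2)
  invisible(x)
}

# Shannon entropy of the occupation law W_X, truncated when the tail mass
# drops below `tail`. Used as a consistency diagnostic against entropy():
# the two coincide exactly (the geometric-law Shannon entropy has the same
# closed form), so any reported mismatch flags a numerical defect.
entropy_from_occupation <- function(theta, tail = 1e-12) {
  if (theta == 0) return(0)
  t2 <- tanh(theta)^2
  Xmax <- ceiling(log(tail) / log(t2)) + 1
  W <- occupation_probability(theta, 0:Xmax)
  -sum(W * log(W))
}
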