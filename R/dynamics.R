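# Relaxation of the population ratio toward the free-energy minimum.
#
# No equation of motion is prescribed by the equilibrium theory itself; two
# complementary schemes are provided. Metropolis single-individual flips
# N_L -> N_L +/- 1 use the finite-N free energy F_N(N_L) =
# F(theta(N_L/N)) as the potential, so the chain's stationary law is
# exactly the Boltzmann structure exp(-beta F_N) the equilibrium analysis
# derives, making the convergence claim testable. Gradient flow on theta is
# the deterministic counterpart, converging to the closed-form theta*.
# Boundary states N_L in {0, N} are excluded (infinite-F convention),
# mirroring the exclusion of the all-L / all-R populations.

# Finite-N free energy over N_L = 1..N-1 (vector indexed by N_L).
finite_n_free_energy <- function(N, beta, E_X) {
  N_L <- 1:(N - 1)
  theta <- atanh(sqrt(N_L / N))
  free_energy(theta, beta, E_X)
}

#' Exact Boltzmann law of the Metropolis chain over N_L
#'
#' Direct enumeration of the stationary distribution
#' \eqn{\pi(N_L) \propto e^{-\beta F_N(N_L)}} over the interior states
#' \eqn{N_L = 1..N-1}, where \eqn{F_N} is the finite-N free energy at
#' \eqn{\theta(N_L/N)}.
#'
#' @param N Population size (>= 3 for a nontrivial interior).
#' @param beta Inverse temperature.
#' @param E_X Configuration energy scale.
#' @return Named numeric vector of probabilities over `N_L = 1..N-1`.
#' @export
boltzmann_distribution <- function(N, beta, E_X) {
  N <- check_count(N, "N", min = 3)
  lp <- -beta * finite_n_free_energy(N, beta, E_X)
  p <- exp(lp - max(lp))
  p <- p / sum(p)
  names(p) <- 1:(N - 1)
  p
}

#' Relaxation of the population ratio to the free-energy minimum
#'
#' Simulates the return of a perturbed population ratio \eqn{X' \to X} to
#' the equilibrium set by \eqn{\beta E_X}. Two schemes:
#' \describe{
#'   \item{`"metropolis"`}{Single-individual flips \eqn{N_L \to N_L \pm 1},
#'     accepted with probability \eqn{\min(1, e^{-\beta\Delta F_N})}. The
#'     chain is ergodic on \eqn{1..N-1} with stationary law
#'     [boltzmann_distribution()]. An initial `N_L_init` of 0 or N is nudged
#'     to the nearest interior state with a warning.}
#'   \item{`"gradient_flow"`}{Deterministic descent
#'     \eqn{d\theta/dt = -\eta\, dF/d\theta} (explicit Euler, step `eta`),
#'     converging to the closed-form stationary angle \eqn{\theta^*}.}
#' }
#'
#' @param N Population size.
#' @param N_L_init Initial number of left-biased individuals (metropolis), or
#'   used as `theta0 = theta(N_L_init/N)` for gradient flow.
#' @param beta Inverse temperature.
#' @param E_X Configuration energy scale.
#' @param n_steps Number of steps, >= 1.
#' @param seed Integer RNG seed (metropolis only); recorded in the result.
#' @param scheme `"metropolis"` or `"gradient_flow"`.
#' @param eta Gradient-flow step size.
#' @param record_every Thinning for the stored trajectory (metropolis);
#'   every step is still taken.
#' @return An object of class `"lat_trajectory"`: data frame with columns
#'   `step`, `N_L` (real-valued `theta`-image for gradient flow), `X`, `F`,
#'   plus attributes `scheme`, `seed`, `N`, `beta`, `E_X`, `theta_star`,
#'   `X_star`, `accept_rate` (metropolis).
#' @examples
#' tr <- relax(N = 100, N_L_init = 10, beta = 1, E_X = log(2),
#'             n_steps = 2000, seed = 1)
#' summary(tr)
#' @export
relax <- function(N, N_L_init, beta, E_X, n_steps, seed = 1L,
                  scheme = c("metropolis", "gradient_flow"),
                  eta = 0.05, record_every = 1L) {
  scheme <- match.arg(scheme)
  N <- check_count(N, "N", min = 3)
  check_beta_ex(beta, E_X)
  n_steps <- check_count(n_steps, "n_steps", min = 1)
  if (!is.numeric(N_L_init) || N_L_init < 0 || N_L_init > N) {
    stop("`N_L_init` must lie in [0, N]", call. = FALSE)
  }
  eq <- stationarity_solve(beta, E_X)

  if (scheme == "metropolis") {
    traj <- relax_metropolis(N, N_L_init, beta, E_X, n_steps, seed,
                             record_every)
  } else {
    traj <- relax_gradient(N, N_L_init, beta, E_X, n_steps, eta)
  }
  structure(traj$df,
            scheme = scheme, seed = as.integer(seed), N = N,
            beta = beta, E_X = E_X,
            theta_star = eq$theta_star, X_star = eq$X_star,
            accept_rate = traj$accept_rate,
            class = c("lat_trajectory", "data.frame"))
}

relax_metropolis <- function(N, N_L_init, beta, E_X, n_steps, seed,
                             record_every) {
  N_L_init <- check_count(N_L_init, "N_L_init", min = 0)
  if (N_L_init == 0 || N_L_init == N) {
    nudged <- if (N_L_init == 0) 1L else N - 1L
    warning(sprintf(
      "N_L_init = %d is an excluded boundary state; starting from %d",
      N_L_init, nudged), call. = FALSE)
    N_L_init <- nudged
  }
  record_every <- check_count(record_every, "record_every", min = 1)
  lpi <- -beta * finite_n_free_energy(N, beta, E_X)  # index = N_L
  old_seed_state <- set_local_seed(seed)
  on.exit(restore_seed(old_seed_state), add = TRUE)
  dirs <- sample(c(-1L, 1L), n_steps, replace = TRUE)
  lu <- log(stats::runif(n_steps))
  nl <- N_L_init
  n_rec <- n_steps %/% record_every
  rec_nl <- integer(n_rec)
  acc <- 0L
  j <- 0L
  for (t in seq_len(n_steps)) {
    prop <- nl + dirs[t]
    if (prop >= 1L && prop <= N - 1L && lu[t] <= lpi[prop] - lpi[nl]) {
      nl <- prop
      acc <- acc + 1L
    }
    if (t %% record_every == 0L) {
      j <- j + 1L
      rec_nl[j] <- nl
    }
  }
  steps <- seq_len(n_rec) * record_every
  df <- data.frame(
    step = steps,
    N_L = rec_nl,
    X = rec_nl / (N - rec_nl),
    F = free_energy(atanh(sqrt(rec_nl / N)), beta, E_X)
  )
  list(df = df, accept_rate = acc / n_steps)
}

relax_gradient <- function(N, N_L_init, beta, E_X, n_steps, eta) {
  if (N_L_init <= 0 || N_L_init >= N) {
    stop("gradient flow needs an interior starting ratio (0 < N_L_init < N)",
         call. = FALSE)
  }
  theta <- atanh(sqrt(N_L_init / N))
  th <- numeric(n_steps)
  for (t in seq_len(n_steps)) {
    theta <- theta - eta * free_energy_dtheta(theta, beta, E_X)
    if (theta <= 0) theta <- 1e-12   # reflect off the excluded boundary
    th[t] <- theta
  }
  df <- data.frame(
    step = seq_len(n_steps),
    N_L = N * tanh(th)^2,
    X = sinh(th)^2,
    F = free_energy(th, beta, E_X)
  )
  list(df = df, accept_rate = NA_real_)
}

# Seed discipline: touch only a local RNG stream, restore the caller's.
set_local_seed <- function(seed) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  set.seed(as.integer(seed))
  old
}

restore_seed <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

#' @export
print.lat_trajectory <- function(x, ...) {
  cat(sprintf("<lat_trajectory> scheme = %s, N = %d, beta*E_X = %.4g, %d records\n",
              attr(x, "scheme"), attr(x, "N"),
              attr(x, "beta") * attr(x, "E_X"), nrow(x)))
  cat(sprintf("  equilibrium X* = %.6g; final X = %.6g\n",
              attr(x, "X_star"), x$X[nrow(x)]))
  if (!is.na(attr(x, "accept_rate"))) {
    cat(sprintf("  seed = %d, acceptance rate = %.3f\n",
                attr(x, "seed"), attr(x, "accept_rate")))
  }
  invisible(x)
}

#' @export
summary.lat_trajectory <- function(object, burn_frac = 0.5, ...) {
  n <- nrow(object)
  keep <- object$X[seq.int(floor(burn_frac * n) + 1, n)]
  out <- list(
    scheme = attr(object, "scheme"),
    N = attr(object, "N"),
    X_star = attr(object, "X_star"),
    X_mean = mean(keep),
    X_se = batch_means_se(keep),
    n_kept = length(keep)
  )
  class(out) <- "summary.lat_trajectory"
  out
}

#' @export
print.summary.lat_trajectory <- function(x, ...) {
  cat(sprintf("lat_trajectory summary (%s, N = %d)\n", x$scheme, x$N))
  cat(sprintf("  post-burn-in mean X = %.5g (batch-means SE %.3g, %d records)\n",
              x$X_mean, x$X_se, x$n_kept))
  cat(sprintf("  closed-form equilibrium X* = %.5g\n", x$X_star))
  invisible(x)
}

#' @export
plot.lat_trajectory <- function(x, ...) {
  graphics::plot(x$step, x$X, type = "l", xlab = "step", ylab = "X", ...)
  graphics::abline(h = attr(x, "X_star"), lty = 2)
  invisible(x)
}

# Monte-Carlo standard error of a correlated series by batch means.
batch_means_se <- function(x, n_batches = 30) {
  n <- length(x)
  if (n < 2 * n_batches) return(stats::sd(x) / sqrt(n))
  bsize <- n %/% n_batches
  bm <- vapply(seq_len(n_batches),
               function(b) mean(x[((b - 1) * bsize + 1):(b * bsize)]),
               numeric(1))
  stats::sd(bm) / sqrt(n_batches)
}

#' Empirical stationary histogram of the Metropolis chain
#'
#' Runs the Metropolis relaxation, discards a burn-in, and tabulates the
#' visited `N_L` values. The total-variation distance to the exact
#' enumeration [boltzmann_distribution()] is reported: small values confirm
#' that free-energy minimization concentrates the population on Boltzmann
#' weights.
#'
#' @inheritParams relax
#' @param n_samples Post-burn-in samples to keep.
#' @param burn_in Steps discarded before sampling (default `n_samples %/% 4`).
#' @return List of class `"lat_histogram"`: `counts` (named, over
#'   `N_L = 1..N-1`), `probs`, `exact` (the enumerated law), `tv_distance`,
#'   `seed`, `n_samples`.
#' @export
stationary_histogram <- function(N, beta, E_X, n_samples,
                                 N_L_init = NULL, seed = 1L,
                                 burn_in = NULL) {
  N <- check_count(N, "N", min = 3)
  n_samples <- check_count(n_samples, "n_samples", min = 1)
  if (is.null(burn_in)) burn_in <- n_samples %/% 4
  if (is.null(N_L_init)) N_L_init <- max(1L, N %/% 2)
  if (n_samples < 10 * N) {
    warning(sprintf(
      "n_samples = %d is below 10*N = %d; the histogram may be undersampled",
      n_samples, 10 * N), call. = FALSE)
  }
  tr <- relax(N, N_L_init, beta, E_X, n_steps = burn_in + n_samples,
              seed = seed, scheme = "metropolis")
  nl <- tr$N_L[tr$step > burn_in]
  counts <- tabulate(nl, nbins = N - 1)
  names(counts) <- 1:(N - 1)
  probs <- counts / sum(counts)
  exact <- boltzmann_distribution(N, beta, E_X)
  structure(
    list(counts = counts, probs = probs, exact = exact,
         tv_distance = 0.5 * sum(abs(probs - exact)),
         seed = as.integer(seed), n_samples = n_samples),
    class = "lat_histogram"
  )
}

#' @export
print.lat_histogram <- function(x, ...) {
  cat(sprintf("<lat_histogram> %d samples over %d states\n",
              x$n_samples, length(x$counts)))
  cat(sprintf("  TV distance to exact Boltzmann law: %.4f\n", x$tv_distance))
  invisible(x)
}

#' Evolutionarily stable equilibrium of a lateralization fitness function
#'
#' Maximizes a population fitness \eqn{f(X) = a(X) + c\,s(X)} over the ratio
#' \eqn{X}, where `a` models antagonistic (competitive) and `s` synergistic
#' (cooperative) interactions and `c` tunes their relative strength. The
#' equilibrium ratio of left- to right-lateralized individuals is the
#' maximizer; with suitable `a`, `s` it departs from the symmetric
#' \eqn{X = 1}, and it moves with `c`. No specific functional forms are
#' shipped: `a` and `s` are user-supplied.
#'
#' @param a Function of X: antagonistic component.
#' @param s Function of X: synergistic component.
#' @param c_param Control parameter weighting `s` against `a`.
#' @param domain Length-2 interval of admissible ratios, `X > 0`.
#' @param n_grid Coarse grid size before local refinement.
#' @param tol Degeneracy tolerance: if near-maximal fitness is attained over
#'   a spread-out set of X, the maximizer is flagged degenerate.
#' @return List with `X_star`, `f_star`, `degenerate` (logical).
#' @examples
#' # toy quadratics: maximizer of -(X-1)^2 - (X-3)^2 is X = 2
#' ess_equilibrium(function(X) -(X - 1)^2, function(X) -(X - 3)^2,
#'                 c_param = 1, domain = c(0.01, 10))
#' @export
ess_equilibrium <- function(a, s, c_param, domain, n_grid = 1001,
                            tol = 1e-8) {
  stopifnot(is.function(a), is.function(s))
  if (!is.numeric(domain) || length(domain) != 2 || domain[1] <= 0 ||
      diff(domain) <= 0) {
    stop("`domain` must be an increasing positive interval", call. = FALSE)
  }
  f <- function(X) a(X) + c_param * s(X)
  grid <- seq(domain[1], domain[2], length.out = n_grid)
  fg <- vapply(grid, f, numeric(1))
  if (any(!is.finite(fg))) stop("fitness not finite on the domain",
                                call. = FALSE)
  k <- which.max(fg)
  lo <- grid[max(1, k - 1)]
  hi <- grid[min(n_grid, k + 1)]
  opt <- stats::optimize(f, lower = lo, upper = hi, maximum = TRUE,
                         tol = 1e-12)
  near <- grid[fg >= max(fg) - tol]
  degenerate <- (max(near) - min(near)) > 10 * diff(domain) / n_grid
  list(X_star = opt$maximum, f_star = opt$objective, degenerate = degenerate)
}
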