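# Individual-level lateralization: two coupled two-state components
# (doublets), resolved into singlet/triplet configurations of the total
# spin. All linear algebra is exact finite-dimensional (2x2 and 4x4
# complex matrices); no approximation enters anywhere in this file.

#' Pauli and spin-1/2 operator set for a single doublet
#'
#' Builds the 2x2 operator algebra used throughout: the Pauli matrices
#' \eqn{\sigma_i}, the spin-1/2 generators \eqn{\tau_i = \sigma_i/2} and the
#' ladder operators \eqn{\tau_\pm = \tau_1 \pm i\tau_2}. The basis is ordered
#' (R, L) with R the \eqn{\tau_3} eigenvector of eigenvalue \eqn{+1/2}, so a
#' "right-lateralized" component is spin-up.
#'
#' @return An object of class `"spin_operators"`: a list with complex 2x2
#'   matrices `sigma` (list of 3), `tau` (list of 3), `tau_plus`, `tau_minus`,
#'   and `id`.
#'
#' @details The generators satisfy the su(2) commutation relations
#'   \eqn{[\tau_1,\tau_2] = i\tau_3} (and cyclic), the Pauli matrices the
#'   Clifford anticommutation \eqn{\sigma_i\sigma_j + \sigma_j\sigma_i =
#'   2\delta_{ij}}, and \eqn{\tau_+} maps the L basis vector to the R basis
#'   vector.
#'
#' @examples
#' ops <- spin_operators()
#' ops$tau_plus %*% c(0, 1)   # raises L to R
#' @export
spin_operators <- function() {
  s1 <- matrix(c(0, 1, 1, 0), 2, 2)
  s2 <- matrix(c(0, 1i, -1i, 0), 2, 2)
  s3 <- matrix(c(1, 0, 0, -1), 2, 2)
  sigma <- list(s1 + 0i, s2, s3 + 0i)
  tau <- lapply(sigma, function(s) s / 2)
  structure(
    list(
      sigma = sigma,
      tau = tau,
      tau_plus = tau[[1]] + 1i * tau[[2]],
      tau_minus = tau[[1]] - 1i * tau[[2]],
      id = diag(2) + 0i,
      basis = c("R", "L")
    ),
    class = "spin_operators"
  )
}

#' Construct a normalized spin state over a labelled basis
#'
#' @param amplitudes Complex (or numeric) amplitude vector.
#' @param basis Character vector of basis labels, same length as `amplitudes`.
#' @param normalize If `TRUE` (default), rescale to unit norm; if `FALSE` the
#'   amplitudes must already be normalized to within `tol`.
#' @param tol Normalization tolerance.
#' @return An object of class `"spin_state"` with fields `amplitudes` and
#'   `basis`. The global phase is fixed so that the first nonzero amplitude
#'   is real and positive.
#' @export
spin_state <- function(amplitudes, basis, normalize = TRUE, tol = 1e-12) {
  amplitudes <- as.complex(amplitudes)
  if (length(amplitudes) != length(basis)) {
    stop("`amplitudes` and `basis` must have the same length", call. = FALSE)
  }
  nrm <- sqrt(sum(Mod(amplitudes)^2))
  if (normalize) {
    if (nrm == 0) stop("cannot normalize the zero vector", call. = FALSE)
    amplitudes <- amplitudes / nrm
  } else if (abs(nrm - 1) > tol) {
    stop(sprintf("state not normalized: |psi| = %.15g", nrm), call. = FALSE)
  }
  amplitudes <- fix_phase(amplitudes)
  structure(list(amplitudes = amplitudes, basis = basis),
            class = "spin_state")
}

# Global-phase convention: first amplitude with modulus > tol made
# real-positive, so returned states are reproducible.
fix_phase <- function(z, tol = 1e-12) {
  k <- which(Mod(z) > tol)
  if (length(k) == 0) return(z)
  ph <- z[k[1]] / Mod(z[k[1]])
  z / ph
}

#' @export
print.spin_state <- function(x, ...) {
  cat("<spin_state> on basis (", paste(x$basis, collapse = ", "), ")\n",
      sep = "")
  amp <- x$amplitudes
  for (i in seq_along(amp)) {
    if (Mod(amp[i]) > 1e-12) {
      cat(sprintf("  %+.6f%+.6fi |%s>\n", Re(amp[i]), Im(amp[i]), x$basis[i]))
    }
  }
  invisible(x)
}

# Two-spin product basis, fixed ordering.
pair_basis <- function() c("RR", "RL", "LR", "LL")

#' Singlet and triplet states of two coupled doublets
#'
#' Couples two doublets \eqn{\psi_1 \times \psi_2} into total-spin
#' eigenstates on the product basis (RR, RL, LR, LL): the three symmetric
#' triplet states with \eqn{s_{tot} = 1},
#' \eqn{s_{3,tot} \in \{+1, 0, -1\}}, and the antisymmetric singlet with
#' \eqn{s_{tot} = 0}. Mixed states carry the \eqn{1/\sqrt 2} normalization.
#'
#' @return A named list of four objects of class `"coupled_pair"`, named
#'   `"triplet_p1"`, `"triplet_0"`, `"triplet_m1"`, `"singlet"`. Each has
#'   fields `state` (a [spin_state()]), `s_tot`, `s3_tot` and `symmetry`
#'   (`"symmetric"` or `"antisymmetric"`).
#' @examples
#' st <- coupled_states()
#' st$singlet$state$amplitudes   # (0, 1, -1, 0)/sqrt(2)
#' @export
coupled_states <- function() {
  b <- pair_basis()
  # `raw` holds the exact integer amplitudes before normalization; they are
  # kept on the object so that expectation values of dyadic-entry operators
  # can be evaluated in exact floating-point arithmetic (the 1/sqrt(2)
  # normalization would otherwise shed one or two ulp).
  mk <- function(raw, s_tot, s3_tot) {
    structure(
      list(
        state = spin_state(raw, b, normalize = TRUE),
        raw_amplitudes = raw,
        raw_norm2 = sum(raw^2),
        s_tot = s_tot,
        s3_tot = s3_tot,
        symmetry = if (s_tot == 0L) "antisymmetric" else "symmetric"
      ),
      class = "coupled_pair"
    )
  }
  list(
    triplet_p1 = mk(c(1, 0, 0, 0), 1L, 1L),
    triplet_0  = mk(c(0, 1, 1, 0), 1L, 0L),
    triplet_m1 = mk(c(0, 0, 0, 1), 1L, -1L),
    singlet    = mk(c(0, 1, -1, 0), 0L, 0L)
  )
}

#' @export
print.coupled_pair <- function(x, ...) {
  cat(sprintf("<coupled_pair> s_tot = %d, s3_tot = %+d (%s)\n",
              x$s_tot, x$s3_tot, x$symmetry))
  print(x$state)
  invisible(x)
}

# The 4x4 scalar-coupling operator tau1.tau2 = sum_i tau_i (x) tau_i.
tau_dot_tau <- function() {
  ops <- spin_operators()
  Reduce(`+`, lapply(ops$tau, function(t) kronecker(t, t)))
}

# Exchange operator swapping the two components (R<->L roles of slots):
# |ab> -> |ba> on the (RR, RL, LR, LL) basis.
exchange_operator <- function() {
  P <- matrix(0, 4, 4)
  P[1, 1] <- P[4, 4] <- 1
  P[2, 3] <- P[3, 2] <- 1
  P + 0i
}

#' Scalar spin-spin coupling expectation
#'
#' Expectation value \eqn{\langle \psi | \bar\tau_1\cdot\bar\tau_2 |
#' \psi\rangle} of the rotation-invariant coupling on a two-component state.
#' The coupling evaluates to \eqn{-3/4} on the singlet and \eqn{+1/4} on each
#' triplet state, so any energy of the form \eqn{g\,\bar\tau_1\cdot\bar\tau_2}
#' with \eqn{g > 0} is minimized by the antisymmetric singlet.
#'
#' @param state A `"coupled_pair"` (from [coupled_states()]) or a
#'   `"spin_state"` on the 4-dimensional product basis.
#' @param tol Normalization tolerance; a non-normalized state is an error.
#' @return A real scalar.
#' @export
scalar_coupling_expectation <- function(state, tol = 1e-12) {
  if (inherits(state, "coupled_pair") && !is.null(state$raw_amplitudes)) {
    # exact path: integer amplitudes against the dyadic-entry operator,
    # normalized by the integer squared norm afterwards
    v <- as.complex(state$raw_amplitudes)
    q <- drop(Conj(v) %*% tau_dot_tau() %*% v)
    return(Re(q) / state$raw_norm2)
  }
  psi <- as_pair_amplitudes(state)
  if (abs(sum(Mod(psi)^2) - 1) > tol) {
    stop("state must be normalized", call. = FALSE)
  }
  val <- Conj(psi) %*% tau_dot_tau() %*% psi
  val <- drop(val)
  if (abs(Im(val)) > tol) {
    stop("expectation has a non-negligible imaginary part", call. = FALSE)
  }
  Re(val)
}

as_pair_amplitudes <- function(state) {
  if (inherits(state, "coupled_pair")) state <- state$state
  if (inherits(state, "spin_state")) {
    if (length(state$amplitudes) != 4) {
      stop("state must live on the 4-dimensional product basis", call. = FALSE)
    }
    return(state$amplitudes)
  }
  if (is.numeric(state) || is.complex(state)) {
    if (length(state) != 4) stop("amplitude vector must have length 4",
                                 call. = FALSE)
    return(as.complex(state))
  }
  stop("unsupported state type", call. = FALSE)
}

#' Singlet/triplet energy spectrum of the coupled pair
#'
#' Energies \eqn{E = g\,\langle\bar\tau_1\cdot\bar\tau_2\rangle} of the four
#' total-spin eigenstates under the scalar coupling with constant \eqn{g}.
#' With \eqn{g > 0} the singlet at \eqn{-3g/4} is the unique ground state and
#' the triplet sits at \eqn{+g/4}; the singlet-triplet gap is exactly
#' \eqn{g} (1 in dimensionless units when \eqn{g = 1}).
#'
#' @param g Positive coupling constant (default 1, dimensionless units).
#' @return A data frame with one row per state: `state`, `s_tot`, `s3_tot`,
#'   `coupling` (the \eqn{\bar\tau_1\cdot\bar\tau_2} expectation) and
#'   `energy`. The attribute `"gap"` holds the triplet-minus-singlet energy
#'   difference.
#' @examples
#' sp <- energy_spectrum(g = 1)
#' attr(sp, "gap")   # exactly 1
#' @export
energy_spectrum <- function(g = 1) {
  if (!is.numeric(g) || length(g) != 1 || !is.finite(g) || g <= 0) {
    stop("`g` must be a positive finite scalar", call. = FALSE)
  }
  st <- coupled_states()
  coupling <- vapply(st, scalar_coupling_expectation, numeric(1))
  out <- data.frame(
    state = names(st),
    s_tot = vapply(st, `[[`, integer(1), "s_tot"),
    s3_tot = vapply(st, `[[`, integer(1), "s3_tot"),
    coupling = coupling,
    energy = g * coupling,
    row.names = NULL
  )
  attr(out, "gap") <- g * (max(coupling) - min(coupling))
  out
}
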