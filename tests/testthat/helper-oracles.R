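# Brute-force oracles, independent of the package's Dicke-sector code:
# everything here is built in the full 2^N tensor-product space by direct
# kronecker products, and only at small N.

# Single-site basis ordering (R, L): R is spin-up (tau3 = +1/2).
.tau_plus_2 <- matrix(c(0, 0, 1, 0), 2, 2)   # maps L -> R
.tau_minus_2 <- t(.tau_plus_2)
.tau3_2 <- diag(c(0.5, -0.5))

# Operator acting as `op` on site k of an N-site chain (identity elsewhere).
site_operator <- function(op, k, N) {
  out <- 1
  for (i in seq_len(N)) {
    out <- kronecker(out, if (i == k) op else diag(2))
  }
  out
}

# Collective operator sum_k op_k in the full 2^N space.
full_collective <- function(op, N) {
  Reduce(`+`, lapply(seq_len(N), function(k) site_operator(op, k, N)))
}

# Normalized symmetric superposition of all arrangements of `ell` R-sites
# among N, as a 2^N vector. Site state index: bit 0 = R, bit 1 = L; the
# kronecker ordering makes site 1 the most significant bit.
dicke_state_full <- function(N, ell) {
  v <- numeric(2^N)
  combs <- utils::combn(N, ell)
  if (ell == 0) combs <- matrix(integer(0), nrow = 0, ncol = 1)
  for (j in seq_len(ncol(combs))) {
    bits <- rep(1L, N)            # 1 = L
    bits[combs[, j]] <- 0L        # 0 = R
    idx <- sum(bits * 2^((N - 1):0)) + 1
    v[idx] <- 1
  }
  v / sqrt(sum(v^2))
}

# All Dicke states of an N-site chain as columns of a 2^N x (N+1) matrix.
dicke_basis_full <- function(N) {
  vapply(0:N, function(l) dicke_state_full(N, l), numeric(2^N))
}

# Independent 4x4 route to the scalar coupling: (tau_tot^2 - tau1^2 -
# tau2^2) / 2 built from explicit per-site operators on the pair space.
tau_dot_tau_oracle <- function() {
  taus <- list(
    matrix(c(0, 1, 1, 0), 2, 2) / 2,
    matrix(c(0, 1i, -1i, 0), 2, 2) / 2,
    diag(c(0.5, -0.5)) + 0i
  )
  tot2 <- matrix(0i, 4, 4)
  sq1 <- matrix(0i, 4, 4)
  sq2 <- matrix(0i, 4, 4)
  for (t in taus) {
    ti <- kronecker(t, diag(2)) + kronecker(diag(2), t)
    tot2 <- tot2 + ti %*% ti
    t1 <- kronecker(t, diag(2)); sq1 <- sq1 + t1 %*% t1
    t2 <- kronecker(diag(2), t); sq2 <- sq2 + t2 %*% t2
  }
  (tot2 - sq1 - sq2) / 2
}

# Random normalized complex state of dimension d.
random_state <- function(d) {
  z <- complex(real = stats::rnorm(d), imaginary = stats::rnorm(d))
  z / sqrt(sum(Mod(z)^2))
}

# Central finite difference.
fdiff <- function(f, x, h = 1e-6) (f(x + h) - f(x - h)) / (2 * h)
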