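test_that("population_state records counts, ratio and order parameter", {
  st <- population_state(2, 1)
  expect_equal(st$M, 0)
  expect_equal(st$X, 1)
  st <- population_state(10, 7)
  expect_equal(st$M, 2)
  expect_equal(st$X, 3 / 7)
  expect_equal(st$N_L, 3)
  # all-L population: ratio undefined, flagged rather than infinite
  st0 <- population_state(5, 0)
  expect_false(st0$X_defined)
  expect_true(is.na(st0$X))
  expect_error(population_state(5, 6), "0..N")
  expect_error(population_state(0, 0), ">= 1")
})

test_that("both printed forms of the asymmetry measure agree", {
  expect_equal(asymmetry_measure(population_state(100, 60)), 10)
  expect_equal(asymmetry_measure(population_state(8, 4)), 0)
  for (ell in 1:25) {
    st <- population_state(25, ell)
    expect_equal(asymmetry_measure(st), ell - 25 / 2)
    expect_equal(asymmetry_measure(st), st$N_R * (1 - st$X) / 2)
  }
})

test_that("Dicke states match brute-force symmetrization at N = 4", {
  V <- dicke_basis_full(4)
  # columns normalized and orthogonal
  expect_equal(t(V) %*% V, diag(5))
  # S_3 eigenvalue ell - N/2 in the full space
  S3_full <- full_collective(.tau3_2, 4)
  for (l in 0:4) {
    expect_equal(drop(S3_full %*% V[, l + 1]), (l - 2) * V[, l + 1])
  }
  # the (N+1)-dim representation puts amplitude 1 on position ell + 1
  st <- population_state(4, 3)
  expect_equal(st$amplitudes, c(0, 0, 0, 1, 0))
})

test_that("Dicke-sector ladder operators reproduce the 2^N oracle", {
  for (N in c(2, 3, 5, 8, 10)) {
    V <- dicke_basis_full(N)
    Sp_full <- full_collective(.tau_plus_2, N)
    S3_full <- full_collective(.tau3_2, N)
    ops <- collective_operators(N)
    expect_equal(t(V) %*% Sp_full %*% V, ops$S_plus, tolerance = 1e-12)
    expect_equal(t(V) %*% t(Sp_full) %*% V, ops$S_minus, tolerance = 1e-12)
    expect_equal(t(V) %*% S3_full %*% V, ops$S_3, tolerance = 1e-12)
  }
})

test_that("collective algebra is exact at every N", {
  comm <- function(a, b) a %*% b - b %*% a
  for (N in c(4, 20, 57)) {
    ops <- collective_operators(N)
    expect_equal(comm(ops$S_3, ops$S_plus), ops$S_plus)
    expect_equal(comm(ops$S_3, ops$S_minus), -ops$S_minus)
    expect_equal(comm(ops$S_plus, ops$S_minus), 2 * ops$S_3)
    # ladder property: S_+- shift the S_3 eigenvalue (and hence M) by +-1,
    # acting as the translations N_R -> N_R +- 1, N_L -> N_L -+ 1
    for (l in 0:(N - 1)) {
      v <- ops$S_plus[, l + 1]
      expect_equal(v[l + 2], sqrt((N - l) * (l + 1)))
      expect_equal(sum(v != 0), 1)
    }
  }
})

test_that("occupation law W_X is a geometric distribution in the index", {
  expect_equal(occupation_probability(0, 0), 1)
  th <- atanh(sqrt(1 / 2))           # tanh^2 = 1/2
  expect_equal(occupation_probability(th, 0:3), (1 / 2)^(1:4))
  for (th in c(0.3, 1, 2.5)) {
    # truncate once the geometric tail is below the target tolerance
    xmax <- ceiling(log(1e-12) / log(tanh(th)^2))
    W <- occupation_probability(th, 0:xmax)
    expect_true(all(W > 0 & W < 1))
    expect_equal(sum(W), 1, tolerance = 1e-10)
  }
  expect_error(occupation_probability(1, -1), "nonnegative")
  expect_error(occupation_probability(1, 1.5), "integer")
})

test_that("hyperbolic-angle parameterization inverts the fractions", {
  th <- theta_from_fractions(5, 10)        # N_L/N = 1/2
  expect_equal(th, atanh(1 / sqrt(2)))
  expect_equal(sinh(th)^2, 1)              # X = 1
  expect_equal(ratio_from_theta(th), 1)
  # theta -> 0+ as N_L/N -> 0+
  expect_lt(theta_from_fractions(1, 1e6), 1e-2)
  set.seed(7)
  for (k in 1:50) {
    N <- sample(10:5000, 1)
    N_L <- sample(seq_len(N - 1), 1)
    th <- theta_from_fractions(N_L, N)
    expect_gte(th, 0)
    expect_equal(sinh(th)^2, N_L / (N - N_L), tolerance = 1e-9)
  }
  expect_error(theta_from_fractions(0, 10), "excluded")
  expect_error(theta_from_fractions(10, 10), "excluded")
})

test_that("rescaled ladder operators contract toward commuting translations", {
  r20 <- contraction_residual(20, M = 1)
  r200 <- contraction_residual(200, M = 1)
  expect_lt(r200, r20)
  # O(1/N) decay: log-log slope within -1 +- 0.2 at fixed M and window
  Ns <- c(20, 40, 80, 160)
  res <- vapply(Ns, function(n) contraction_residual(n, M = 1), numeric(1))
  slope <- coef(lm(log(res) ~ log(Ns)))[[2]]
  expect_lt(abs(slope + 1), 0.2)
  expect_error(contraction_residual(10, ell = 1), "window")
  expect_error(contraction_residual(20, M = 0.5), "even")
})

test_that("environment coupling is real, vanishes without drive, scales with N", {
  st2 <- spin_state(c(0.6, 0.8), c("R", "L"))
  expect_equal(interaction_energy(2, 0, st2)$energy, 0)
  e <- interaction_energy(1.5, 0.3 + 0.4i, st2)
  expect_true(is.numeric(e$energy))
  expect_equal(e$coupling_scale, 1.5)
  # collective mode on a population state: real expectation, lambda*N scale
  pop <- population_state(30, 15)
  ec <- interaction_energy(0.2, 1i, pop, collective = TRUE)
  expect_true(is.numeric(ec$energy))
  expect_equal(ec$coupling_scale, 0.2 * 30)
  # strong-coupling scaling: peak matrix element of S_+ + S_- doubles
  # between N = 20 and N = 40 (near the equatorial Dicke states)
  m20 <- max(abs(collective_operators(20)$S_plus))
  m40 <- max(abs(collective_operators(40)$S_plus))
  expect_equal(m40 / m20, 2, tolerance = 0.05)
})
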