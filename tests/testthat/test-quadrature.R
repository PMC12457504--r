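test_that("quadrature sizing follows (p_q + 1)^d", {
  expect_equal(nrow(subcell_factor_matrix(2, 8)$points), 27)
  expect_equal(nrow(subcell_factor_matrix(1, 8)$points), 8)
  q <- moment_fit_weights(rep(1, 8), p_q = 2, n_c = 1000)
  expect_equal(q$n_i, 27)
  expect_error(moment_fit_weights(rep(1, 8), p_q = 0), "p_q")
  expect_error(subcell_factor_matrix(2, 100), "perfect cube")
})

test_that("full-solid elements recover the standard Gauss-Legendre weights", {
  q <- moment_fit_weights(rep(1, 8))
  gl <- gauss_legendre(3)
  w_ref <- as.vector(kronecker(kronecker(gl$w, gl$w), gl$w))
  expect_lt(max(abs(q$weights - w_ref)), 1e-12)
  expect_equal(sum(q$weights), 8, tolerance = 1e-12)
  expect_equal(q$element_class, "solid")
})

test_that("fully void elements receive a zero rule", {
  q <- moment_fit_weights(rep(-1, 8))
  expect_true(all(q$weights == 0))
  expect_equal(q$element_class, "void")
})

test_that("half-cube cut gives sum 4 and matches analytic Lagrange integrals", {
  S <- ringhomog:::hex_corner_signs()
  q <- moment_fit_weights(-S[, 1])   # phi = -xi: solid half xi <= 0
  expect_equal(sum(q$weights), 4, tolerance = 1e-12)
  # analytic: integrate the tensor Lagrange basis over xi in [-1, 0]
  gl <- gauss_legendre(3)
  g4 <- gauss_legendre(4)
  int_half <- vapply(1:3, function(j) {
    x <- g4$x / 2 - 0.5   # map to [-1, 0]
    L <- 1
    for (k in setdiff(1:3, j)) L <- L * (x - gl$x[k]) / (gl$x[j] - gl$x[k])
    sum(g4$w / 2 * L)
  }, numeric(1))
  int_full <- gl$w
  w_expect <- as.vector(kronecker(kronecker(int_full, int_full), int_half))
  expect_lt(max(abs(q$weights - w_expect)), 1e-12)
})

test_that("weight sums equal the sub-cell solid volume on random cut planes", {
  set.seed(21)
  basis <- subcell_factor_matrix(2, 1000)
  S <- ringhomog:::hex_corner_signs()
  for (i in 1:25) {
    nrm <- rnorm(3); nrm <- nrm / sqrt(sum(nrm^2))
    off <- runif(1, -0.8, 0.8)
    phin <- as.vector(S %*% nrm) - off
    if (all(phin >= 0) || all(phin < 0)) next
    q <- moment_fit_weights(phin, basis = basis)
    H <- as.numeric(basis$W_tri %*% phin >= 0)
    expect_equal(sum(q$weights), sum(H) * 8 / 1000, tolerance = 1e-12)
  }
})

test_that("factored sub-cell accumulation equals the naive per-sub-cell rule", {
  basis <- subcell_factor_matrix(2, 27)
  S <- ringhomog:::hex_corner_signs()
  phin <- as.vector(S %*% c(0.6, -0.5, 0.2)) - 0.1
  q <- moment_fit_weights(phin, n_c = 27, basis = basis)
  # naive oracle: loop sub-cells, 2x2x2 Gauss each, evaluate Lagrange basis
  gl <- gauss_legendre(3)
  g2 <- gauss_legendre(2)
  na <- 3; s <- 2 / na
  centers <- -1 + (seq_len(na) - 0.5) * s
  lag <- function(x, j) {
    L <- 1
    for (k in setdiff(1:3, j)) L <- L * (x - gl$x[k]) / (gl$x[j] - gl$x[k])
    L
  }
  w_naive <- numeric(27)
  tri <- function(p, corner) {
    0.125 * (1 + p[1] * corner[1]) * (1 + p[2] * corner[2]) * (1 + p[3] * corner[3])
  }
  for (cx in 1:na) for (cy in 1:na) for (cz in 1:na) {
    ctr <- c(centers[cx], centers[cy], centers[cz])
    phic <- sum(vapply(1:8, function(a) tri(ctr, S[a, ]) * phin[a], numeric(1)))
    if (phic < 0) next
    for (hx in 1:2) for (hy in 1:2) for (hz in 1:2) {
      pt <- ctr + c(g2$x[hx], g2$x[hy], g2$x[hz]) * s / 2
      v <- (s / 2)^3 * g2$w[hx] * g2$w[hy] * g2$w[hz]
      idx <- 0
      for (c3 in 1:3) for (b in 1:3) for (a in 1:3) {
        idx <- idx + 1
        w_naive[idx] <- w_naive[idx] +
          v * lag(pt[1], a) * lag(pt[2], b) * lag(pt[3], c3)
      }
    }
  }
  expect_lt(max(abs(q$weights - w_naive)), 1e-12)
})

test_that("elements classify by nodal level-set signs with H(0) = 1", {
  phin <- cbind(rep(1, 8), rep(0, 8), c(rep(1, 4), rep(-1, 4)), rep(-0.1, 8))
  cls <- classify_elements(phin)
  expect_equal(cls, c(1L, 1L, 2L, 0L))   # solid, solid (phi = 0), cut, void
})

test_that("element integrals match an independent dense-quadrature oracle", {
  C <- iso_stiffness(5000, 0.25)
  q <- moment_fit_weights(rep(1, 8))
  el <- integrate_element(C, c(0.1, 0.2, 0.3), q, c(1.5, 1, 2))
  K_oracle <- oracle_hex_stiffness(C, c(1.5, 1, 2))
  expect_lt(max(abs(el$K - K_oracle)), 1e-8 * max(abs(K_oracle)))
  # rigid translations are zero-energy modes
  for (dir in 1:3) {
    u <- rep(0, 24); u[seq(dir, 24, by = 3)] <- 1
    expect_lt(max(abs(el$K %*% u)), 1e-9 * max(abs(el$K)))
  }
  ev <- eigen((el$K + t(el$K)) / 2, symmetric = TRUE, only.values = TRUE)$values
  expect_equal(sum(abs(ev) < 1e-8 * max(ev)), 6)   # 3 translations + 3 rotations
  expect_gt(min(ev), -1e-10 * max(ev))             # positive semi-definite
  # void element: zero contribution
  elv <- integrate_element(C, c(0.1, 0.2, 0.3), moment_fit_weights(rep(-1, 8)), 1)
  expect_true(all(elv$K == 0) && all(elv$F == 0) && all(elv$f == 0))
  # cut element: at least 6 zero-energy modes
  S <- ringhomog:::hex_corner_signs()
  qc <- moment_fit_weights(as.vector(S %*% c(1, 0.3, 0)) - 0.2)
  elc <- integrate_element(C, c(0.1, 0.2, 0.3), qc, 1)
  evc <- eigen((elc$K + t(elc$K)) / 2, symmetric = TRUE, only.values = TRUE)$values
  expect_gte(sum(abs(evc) < 1e-8 * max(evc)), 6)
})
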