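# Shared fixtures and independent oracles for the test suite.

# Brute-force signed face distance: enumerate every solid/void interface
# face and minimize the exact point-to-rectangle distance. Independent of
# the production kernel (plain R).
brute_force_face_distance <- function(binary, spacing = 1) {
  d <- dim(binary)
  h <- rep(spacing, length.out = 3)
  faces <- list()
  add_face <- function(axis, cx, cy, cz) {
    faces[[length(faces) + 1]] <<- c(axis, cx, cy, cz)
  }
  for (k in seq_len(d[3])) for (j in seq_len(d[2])) for (i in seq_len(d[1])) {
    s <- binary[i, j, k]
    if (i < d[1] && s != binary[i + 1, j, k])
      add_face(1, i * h[1], (j - 0.5) * h[2], (k - 0.5) * h[3])
    if (j < d[2] && s != binary[i, j + 1, k])
      add_face(2, (i - 0.5) * h[1], j * h[2], (k - 0.5) * h[3])
    if (k < d[3] && s != binary[i, j, k + 1])
      add_face(3, (i - 0.5) * h[1], (j - 0.5) * h[2], k * h[3])
  }
  fm <- do.call(rbind, faces)
  phi <- array(0, d)
  for (k in seq_len(d[3])) for (j in seq_len(d[2])) for (i in seq_len(d[1])) {
    p <- c((i - 0.5) * h[1], (j - 0.5) * h[2], (k - 0.5) * h[3])
    dx <- abs(p[1] - fm[, 2]); dy <- abs(p[2] - fm[, 3]); dz <- abs(p[3] - fm[, 4])
    dx <- ifelse(fm[, 1] == 1, dx, pmax(0, dx - h[1] / 2))
    dy <- ifelse(fm[, 1] == 2, dy, pmax(0, dy - h[2] / 2))
    dz <- ifelse(fm[, 1] == 3, dz, pmax(0, dz - h[3] / 2))
    dist <- min(sqrt(dx^2 + dy^2 + dz^2))
    phi[i, j, k] <- if (binary[i, j, k]) dist else -dist
  }
  phi
}

# isotropic stiffness in engineering Voigt form (MPa)
iso_stiffness <- function(E, nu) {
  lam <- E * nu / ((1 + nu) * (1 - 2 * nu))
  mu <- E / (2 * (1 + nu))
  C <- matrix(0, 6, 6)
  C[1:3, 1:3] <- lam
  diag(C)[1:3] <- lam + 2 * mu
  diag(C)[4:6] <- mu
  C
}

# Exact effective stiffness of a periodic two-phase laminate with layers
# normal to x (Backus averaging; closed form, independent oracle).
backus_laminate <- function(Cl, fractions) {
  avg <- function(fun) sum(mapply(function(C, f) f * fun(C), Cl, fractions))
  C11 <- 1 / avg(function(C) 1 / C[1, 1])
  r2 <- avg(function(C) C[1, 2] / C[1, 1])
  r3 <- avg(function(C) C[1, 3] / C[1, 1])
  C12 <- C11 * r2
  C13 <- C11 * r3
  C22 <- avg(function(C) C[2, 2] - C[1, 2]^2 / C[1, 1]) + C11 * r2^2
  C33 <- avg(function(C) C[3, 3] - C[1, 3]^2 / C[1, 1]) + C11 * r3^2
  C23 <- avg(function(C) C[2, 3] - C[1, 2] * C[1, 3] / C[1, 1]) + C11 * r2 * r3
  out <- matrix(0, 6, 6)
  out[1, 1] <- C11; out[2, 2] <- C22; out[3, 3] <- C33
  out[1, 2] <- out[2, 1] <- C12
  out[1, 3] <- out[3, 1] <- C13
  out[2, 3] <- out[3, 2] <- C23
  out[4, 4] <- avg(function(C) C[4, 4])          # yz: in-plane shear
  out[5, 5] <- 1 / avg(function(C) 1 / C[5, 5])  # xz: across layers
  out[6, 6] <- 1 / avg(function(C) 1 / C[6, 6])  # xy: across layers
  out
}

# Build an all-solid xfem model with a two-phase laminate material field
# (layers normal to x, half/half).
laminate_model <- function(n, Ca, Cb, ba, bb) {
  phi <- new_level_set(array(1, c(n, n, n)), 1)
  model <- suppressWarnings(build_xfem_model(phi))
  g <- model$groups$solid
  ei <- (g$elements - 1) %% n + 1
  A <- ei <= n / 2
  Cm <- matrix(0, 36, length(g$elements))
  Bm <- matrix(0, 6, length(g$elements))
  Cm[, A] <- as.vector(Ca); Cm[, !A] <- as.vector(Cb)
  Bm[, A] <- ba; Bm[, !A] <- bb
  model$groups$solid$C <- Cm
  model$groups$solid$beta <- Bm
  model
}

# Independent dense-quadrature element stiffness oracle: plain R loops,
# its own shape-function derivatives, 4^3 Gauss points.
oracle_hex_stiffness <- function(C, spacing = c(1, 1, 1)) {
  spacing <- rep(spacing, length.out = 3)
  gl <- gauss_legendre(4)
  signs <- matrix(c(-1, -1, -1, 1, -1, -1, 1, 1, -1, -1, 1, -1,
                    -1, -1, 1, 1, -1, 1, 1, 1, 1, -1, 1, 1),
                  ncol = 3, byrow = TRUE)
  K <- matrix(0, 24, 24)
  detJ <- prod(spacing) / 8
  for (a in seq_len(4)) for (b in seq_len(4)) for (c3 in seq_len(4)) {
    xi <- gl$x[a]; eta <- gl$x[b]; zeta <- gl$x[c3]
    w <- gl$w[a] * gl$w[b] * gl$w[c3]
    Bm <- matrix(0, 6, 24)
    for (m in 1:8) {
      dN <- c(0.125 * signs[m, 1] * (1 + eta * signs[m, 2]) * (1 + zeta * signs[m, 3]),
              0.125 * (1 + xi * signs[m, 1]) * signs[m, 2] * (1 + zeta * signs[m, 3]),
              0.125 * (1 + xi * signs[m, 1]) * (1 + eta * signs[m, 2]) * signs[m, 3])
      dN <- dN * 2 / spacing
      cx <- 3 * m - 2
      Bm[1, cx] <- dN[1]; Bm[2, cx + 1] <- dN[2]; Bm[3, cx + 2] <- dN[3]
      Bm[4, cx + 1] <- dN[3]; Bm[4, cx + 2] <- dN[2]
      Bm[5, cx] <- dN[3]; Bm[5, cx + 2] <- dN[1]
      Bm[6, cx] <- dN[2]; Bm[6, cx + 1] <- dN[1]
    }
    K <- K + w * detJ * t(Bm) %*% C %*% Bm
  }
  K
}

# small deterministic phantom used across tests
small_phantom_spec <- function(...) {
  phantom_spec(domain_size_voxels = c(30L, 14L, 4L), noise_sd = 0,
               inhomogeneity_amplitude = 0, ...)
}

angle_error_deg <- function(a, b) {
  abs(((a - b + pi / 2) %% pi) - pi / 2) * 180 / pi
}
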