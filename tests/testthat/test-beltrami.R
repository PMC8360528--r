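test_that("face gradients are exact for affine fields and match a direct solve", {
  m <- ring_disk_mesh(3, 8, jitter = 0.05, seed = 3)
  u <- m$vertices
  g1 <- face_gradients(u, u[, 1], m$faces)
  expect_equal(unname(g1[, 1]), rep(1, nrow(m$faces)), tolerance = 1e-12)
  expect_equal(unname(g1[, 2]), rep(0, nrow(m$faces)), tolerance = 1e-12)
  g2 <- face_gradients(u, 3 * u[, 1] - 2 * u[, 2] + 7, m$faces)
  expect_equal(unname(g2[, 1]), rep(3, nrow(m$faces)), tolerance = 1e-12)
  expect_equal(unname(g2[, 2]), rep(-2, nrow(m$faces)), tolerance = 1e-12)
  # single triangle vs 2x2 interpolation-system oracle
  set.seed(9)
  for (rep in 1:10) {
    tri <- matrix(rnorm(6), 3)
    vals <- rnorm(3)
    got <- face_gradients(tri, vals, rbind(1:3))
    A <- rbind(tri[2, ] - tri[1, ], tri[3, ] - tri[1, ])
    oracle <- solve(A, c(vals[2] - vals[1], vals[3] - vals[1]))
    expect_equal(as.numeric(got), oracle, tolerance = 1e-10)
  }
})

test_that("Beltrami coefficients of affine maps equal b/a exactly", {
  m <- ring_disk_mesh(3, 8, jitter = 0.05, seed = 4)
  u <- complex(real = m$vertices[, 1], imaginary = m$vertices[, 2])
  bf0 <- compute_beltrami(u, u, m$faces)
  expect_lt(max(Mod(bf0$mu)), 1e-11)
  expect_false(any(bf0$flipped))
  bf1 <- compute_beltrami(u, u + 0.3 * Conj(u), m$faces)
  expect_complex_equal(bf1$mu, rep(0.3 + 0i, nrow(m$faces)), tol = 1e-11)
  # dominant anti-conformal part: |mu| = 1/0.2 = 5, everything flipped
  bf2 <- compute_beltrami(u, 0.2 * u + Conj(u), m$faces)
  expect_equal(unname(Mod(bf2$mu)), rep(5, nrow(m$faces)), tolerance = 1e-10)
  expect_true(all(bf2$flipped))
  expect_true(all(bf2$jac < 0))
  # anti-conformal map: sentinel, finite magnitude, flagged
  bf3 <- compute_beltrami(u, Conj(u), m$faces)
  expect_true(all(bf3$sentinel))
  expect_true(all(bf3$flipped))
  expect_true(all(is.finite(Mod(bf3$mu))))
  expect_equal(unname(Mod(bf3$mu)), rep(1e9, nrow(m$faces)))
})

test_that("mu is invariant under similarity re-parameterization", {
  m <- ring_disk_mesh(4, 9, jitter = 0.04, seed = 5)
  u <- complex(real = m$vertices[, 1], imaginary = m$vertices[, 2])
  f <- random_topological_map(m, seed = 11)
  mu0 <- compute_beltrami(u, f, m$faces)$mu
  set.seed(12)
  for (rep in 1:5) {
    s <- complex(modulus = exp(rnorm(1, 0, 0.5)), argument = runif(1, 0, 2 * pi))
    t <- complex(real = rnorm(1), imaginary = rnorm(1))
    mu1 <- compute_beltrami(s * u + t, f, m$faces)$mu
    # pre-composition with a similarity multiplies mu by conj(s)/s on
    # the parametric side; magnitudes are preserved and for the
    # rotation-free scale map mu itself is unchanged
    expect_lt(max(abs(Mod(mu1) - Mod(mu0))), 1e-10)
    mu2 <- compute_beltrami(Mod(s) * u + t, f, m$faces)$mu
    expect_complex_equal(mu2, mu0, tol = 1e-10)
  }
})

test_that("|mu| > 1 is equivalent to a signed-area flip", {
  set.seed(21)
  for (rep in 1:8) {
    m <- ring_disk_mesh(3, 7 + rep %% 3, jitter = 0.04, seed = rep)
    u <- complex(real = m$vertices[, 1], imaginary = m$vertices[, 2])
    f <- u + complex(real = rnorm(length(u), 0, 0.15),
                     imaginary = rnorm(length(u), 0, 0.15))
    bf <- compute_beltrami(u, f, m$faces)
    fl <- count_flipped(u, f, m$faces)
    expect_equal(bf$flipped, Mod(bf$mu) > 1 | bf$sentinel)
    expect_equal(unname(bf$flipped), unname(fl$flipped | bf$sentinel))
  }
})

test_that("J = |f_z|^2 (1 - |mu|^2) matches the direct Jacobian determinant", {
  m <- ring_disk_mesh(4, 8, jitter = 0.05, seed = 6)
  u <- complex(real = m$vertices[, 1], imaginary = m$vertices[, 2])
  set.seed(31)
  f <- u + 0.4 * Conj(u) * Mod(u) + complex(real = rnorm(length(u), 0, 0.05),
                                            imaginary = rnorm(length(u), 0, 0.05))
  bf <- compute_beltrami(u, f, m$faces)
  gid <- Mod(bf$fz)^2 * (1 - Mod(bf$mu[!bf$sentinel])^2)
  # direct 2x2 Jacobian oracle per face
  g <- face_gradients(u, f, m$faces)
  direct <- Re(g[, 1]) * Im(g[, 2]) - Im(g[, 1]) * Re(g[, 2])
  expect_equal(unname(bf$jac), unname(direct), tolerance = 1e-10)
  expect_equal(unname(bf$jac[!bf$sentinel]), unname(gid), tolerance = 1e-10)
})

test_that("angle distortion is zero for conformal and axis-stretch maps", {
  m <- ring_disk_mesh(3, 8, jitter = 0.03, seed = 7)
  u <- complex(real = m$vertices[, 1], imaginary = m$vertices[, 2])
  # similarity: conformal, zero distortion
  ad0 <- angle_distortion(u, (0.7 + 0.4i) * u + 2, m$faces)
  expect_lt(max(ad0$per_face), 1e-8)
  # pure stretch keeps the coordinate tangents orthogonal even though
  # mu = -1/3 is far from 0: this metric is orthogonality, not |mu|
  fs <- complex(real = Re(u), imaginary = 2 * Im(u))
  ads <- angle_distortion(u, fs, m$faces)
  expect_lt(max(ads$per_face), 1e-8)
  mus <- compute_beltrami(u, fs, m$faces)$mu
  expect_complex_equal(mus, rep(-1/3 + 0i, length(mus)), tol = 1e-10)
  # shear map vs explicit Jacobian column-angle oracle
  f <- u + 0.5 * Conj(u) + 0.3i * Im(u)
  ad <- angle_distortion(u, f, m$faces)
  g <- face_gradients(u, f, m$faces)
  oracle <- vapply(seq_len(nrow(g)), function(k) {
    c1 <- c(Re(g[k, 1]), Im(g[k, 1])); c2 <- c(Re(g[k, 2]), Im(g[k, 2]))
    abs(90 - acos(sum(c1 * c2) / sqrt(sum(c1^2) * sum(c2^2))) * 180 / pi)
  }, numeric(1))
  expect_equal(unname(ad$per_face), oracle, tolerance = 1e-10)
})

test_that("beltrami_table exports one labelled row per face", {
  m <- fan_mesh(6)
  u <- complex(real = m$vertices[, 1], imaginary = m$vertices[, 2])
  tab <- beltrami_table(compute_beltrami(u, u + 0.2 * Conj(u), m$faces))
  expect_equal(nrow(tab), 6)
  expect_named(tab, c("face", "re_mu", "im_mu", "abs_mu", "jac", "flipped"))
  expect_equal(tab$abs_mu, rep(0.2, 6), tolerance = 1e-12)
})
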