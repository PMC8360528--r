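test_that("topological projection follows the printed rescaling rule", {
  expect_equal(project_beltrami(0.5 + 0i), 0.5 + 0i)
  expect_equal(project_beltrami(1.5 + 0i, 0.01), 1.5 / 1.51 + 0i,
               tolerance = 1e-12)
  got <- project_beltrami(2i, 0.01)
  expect_equal(Mod(got), 2 / 2.01, tolerance = 1e-12)
  expect_equal(Arg(got), pi / 2, tolerance = 1e-12)
  # arguments preserved in general
  z <- complex(modulus = 3, argument = 2.3)
  expect_equal(Arg(project_beltrami(z)), 2.3, tolerance = 1e-12)
  # sentinel faces map to magnitude 1/(1+eps), argument 0
  m <- fan_mesh(6)
  u <- complex(real = m$vertices[, 1], imaginary = m$vertices[, 2])
  bf <- compute_beltrami(u, Conj(u), m$faces)
  pj <- project_beltrami(bf, 0.01)
  expect_equal(unname(pj$mu), rep(complex(real = 1 / 1.01), 6))
  expect_error(project_beltrami(0.5 + 0i, eps_proj = 0), "positive")
})

test_that("extended polar angle matches the printed transformations", {
  expect_equal(extend_polar(0.2, "V1v", "left"), 0.2 + pi)
  expect_equal(extend_polar(2.0, "V2v", "right"), -2.0 + pi)
  expect_equal(extend_polar(5.0, "V1d", "left"), 5.0 - pi)
  expect_equal(extend_polar(0.3, "V3v", "left"), 0.3 + 2 * pi)
  expect_error(extend_polar(0.2, "V9x", "left"), "unknown region")
})

test_that("the six extended ranges form a continuous monotone chain", {
  # at each shared border the two adjacent regions agree after the
  # canonical offsets; verified by enumerating all 12 transformations
  borders <- list(
    left = list(
      c("V1v", "V2v", pi / 2),    # upper vertical meridian
      c("V1d", "V2d", 3 * pi / 2),# lower vertical meridian
      c("V2v", "V3v", 0),         # horizontal meridian (upper chain end)
      c("V2d", "V3d", 2 * pi - 1e-12),
      c("V1v", "V1d", 0)),        # V1 horizontal meridian (theta 0 vs 2pi)
    right = list(
      c("V1v", "V2v", pi / 2),
      c("V1d", "V2d", 3 * pi / 2),
      c("V2v", "V3v", pi),
      c("V2d", "V3d", pi),
      c("V1v", "V1d", pi)))
  for (h in c("left", "right")) {
    for (b in borders[[h]]) {
      th <- as.numeric(b[3])
      th2 <- if (b[1] == "V1v" && b[2] == "V1d" && h == "left") 2 * pi - 1e-12 else th
      e1 <- extend_polar(th, b[1], h)
      e2 <- extend_polar(th2, b[2], h)
      expect_lt(abs(e1 - e2), 1e-9)
    }
    # ranges tile [-pi/2, 5pi/2] without overlap
    tab <- retinosmooth:::.ext_table[[h]]
    expect_equal(sort(c(tab$lo, tab$hi)),
                 sort(c(-pi / 2, rep(seq(0, 2 * pi, by = pi / 2), each = 2),
                        5 * pi / 2)),
                 tolerance = 1e-12)
  }
})

test_that("extend/invert extended polar angle is an exact round trip", {
  set.seed(17)
  n <- 10000
  regions <- c("V1v", "V1d", "V2v", "V2d", "V3v", "V3d")
  for (h in c("left", "right")) {
    # draw angles from each region's nominal quadrant
    reg <- sample(regions, n, replace = TRUE)
    vent <- grepl("v$", reg)
    th <- if (h == "left") {
      ifelse(vent, runif(n, 0, pi / 2), runif(n, 3 * pi / 2, 2 * pi))
    } else {
      ifelse(vent, runif(n, pi / 2, pi), runif(n, pi, 3 * pi / 2))
    }
    ext <- extend_polar(th, reg, h)
    dec <- invert_extended_polar(ext, h)
    expect_equal(dec$ang, th, tolerance = 1e-9)
    expect_equal(dec$region, reg)
  }
  # border value resolves to the earlier region in the documented order
  b <- invert_extended_polar(extend_polar(pi / 2, "V1v", "left"), "left")
  expect_equal(b$region, "V1v")  # V1v before V2v
  expect_error(invert_extended_polar(100, "left"), "outside")
})

test_that("boundary update adopts exact fits and enforces the tolerance", {
  m <- square_grid_mesh(6)
  u <- complex(real = m$vertices[, 1], imaginary = m$vertices[, 2])
  bl <- m$boundary_loop
  lin <- (2 - 1i) * u + (0.3 + 0.2i)
  # interior exactly linear, initial equal to the linear field: adopted
  got <- update_boundary(u, m$faces, lin, bl, lin[bl], eps_boundary = 0.05)
  expect_complex_equal(got, lin[bl], tol = 1e-10)
  # initial offset an order of magnitude beyond the tolerance: restored
  init_off <- lin[bl] + 10 * 0.05
  got2 <- update_boundary(u, m$faces, lin, bl, init_off, eps_boundary = 0.05)
  expect_complex_equal(got2, init_off, tol = 1e-12)
  # clamp mode moves exactly eps toward the proposal
  got3 <- update_boundary(u, m$faces, lin, bl, init_off, eps_boundary = 0.05,
                          mode = "clamp")
  expect_equal(max(Mod(got3 - init_off)), 0.05, tolerance = 1e-9)
  expect_lt(max(Mod(got3 - lin[bl])), 10 * 0.05)
})

test_that("boundary update denoises a noisy linear field", {
  m <- square_grid_mesh(8)
  u <- complex(real = m$vertices[, 1], imaginary = m$vertices[, 2])
  bl <- m$boundary_loop
  lin <- (1.5 + 0.5i) * u
  set.seed(18)
  sigma <- 0.01
  noisy <- lin + complex(real = rnorm(length(u), 0, sigma),
                         imaginary = rnorm(length(u), 0, sigma))
  got <- update_boundary(u, m$faces, noisy, bl, lin[bl], eps_boundary = 0.1)
  # pooled least squares beats the raw noise level at the boundary
  expect_lt(sqrt(mean(Mod(got - lin[bl])^2)), sigma)
})

test_that("the solver returns only maps satisfying the topology constraint", {
  for (seed in 1:6) {
    dat <- gen_log_model(psnr = 10, seed = 600 + seed)
    fit <- qc_smooth(dat$v, dat$mesh$faces, dat$u_noisy, s = 0.001)
    expect_true(fit$converged)
    bf <- compute_beltrami(dat$v, fit$f, dat$mesh$faces)
    expect_lt(max(Mod(bf$mu)), 1)
    expect_equal(count_flipped(dat$v, fit$f, dat$mesh$faces)$count, 0)
  }
})

test_that("a clean topological input passes through unchanged", {
  dat <- gen_log_model(psnr = Inf)
  fit <- qc_smooth(dat$v, dat$mesh$faces, dat$u_clean, s = 0.001)
  expect_equal(fit$iterations, 0)
  expect_lt(mean(Mod(fit$f - dat$u_clean)), 1e-3)
  expect_equal(count_flipped(dat$v, fit$f, dat$mesh$faces)$count, 0)
})

test_that("non-convergence raises an error carrying the max|mu| trace", {
  dat <- gen_log_model(psnr = 5, seed = 77)
  # boundary values traversing the target boundary in reversed
  # orientation can never support an orientation-preserving map, so the
  # solver must give up at the iteration cap
  bl <- dat$mesh$boundary_loop
  err <- tryCatch(
    qc_smooth(dat$v, dat$mesh$faces, Conj(dat$u_noisy), s = 0.001,
              max_iter = 3, boundary_values = Conj(dat$u_clean[bl])),
    error = function(e) e)
  expect_s3_class(err, "error")
  expect_match(conditionMessage(err), "did not converge")
  expect_true(length(err$mu_trace) >= 1)
  expect_true(all(is.finite(err$mu_trace)))
})

test_that("each boundary update step stays within the change tolerance", {
  dat <- gen_log_model(psnr = 10, seed = 19)
  v <- dat$v; faces <- dat$mesh$faces
  bl <- boundary_loops(faces)[[1]]
  favg <- baseline_smooth("average", v, faces, dat$u_noisy)
  vB <- favg[bl]
  f <- laplacian_smooth(v, faces, dat$u_noisy, s = 0.001,
                        boundary = bl, boundary_values = vB)
  for (k in 1:5) {
    vB2 <- update_boundary(v, faces, f, bl, vB, eps_boundary = 0.01,
                           mode = "clamp", fit = "local")
    expect_lte(max(Mod(vB2 - vB)), 0.01 + 1e-12)
    vB <- vB2
  }
})
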