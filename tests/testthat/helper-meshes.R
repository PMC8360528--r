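# Mesh and map fixtures, built in code.

# n x n unit-square grid mesh (ear-free diagonal split via the package's
# own grid helper is avoided here: tests build the plain split so mesh
# validation is exercised on an independent construction)
square_grid_mesh <- function(n = 5, lim = c(0, 1)) {
  s <- seq(lim[1], lim[2], length.out = n)
  g <- expand.grid(x = s, y = s)
  idx <- function(i, j) (j - 1L) * n + i
  f <- list(); q <- 0L
  for (j in seq_len(n - 1)) for (i in seq_len(n - 1)) {
    a <- idx(i, j); b <- idx(i + 1L, j); cc <- idx(i + 1L, j + 1L); d <- idx(i, j + 1L)
    f[[q + 1L]] <- c(a, b, cc); f[[q + 2L]] <- c(a, cc, d); q <- q + 2L
  }
  triangle_mesh(cbind(g$x, g$y), do.call(rbind, f))
}

# symmetric fan: one interior vertex at the origin surrounded by k rim
# vertices on the unit circle
fan_mesh <- function(k = 6) {
  th <- 2 * pi * (seq_len(k) - 1) / k
  v <- rbind(c(0, 0), cbind(cos(th), sin(th)))
  f <- cbind(1L, 1L + seq_len(k), 1L + c(seq_len(k)[-1], 1L))
  triangle_mesh(v, f)
}

# disk mesh: concentric rings around a center vertex, optionally jittered
# (jitter is rejected if it would flip a face, so the mesh stays valid)
ring_disk_mesh <- function(n_ring = 4, k = 8, jitter = 0, seed = 1) {
  set.seed(seed)
  v <- matrix(c(0, 0), 1)
  ring_start <- integer(n_ring)
  for (r in seq_len(n_ring)) {
    ring_start[r] <- nrow(v) + 1L
    th <- 2 * pi * (seq_len(k) - 1) / k + (r %% 2) * pi / k
    v <- rbind(v, (r / n_ring) * cbind(cos(th), sin(th)))
  }
  f <- list()
  for (i in seq_len(k))   # inner fan
    f[[length(f) + 1L]] <- c(1L, 1L + i, 1L + (i %% k) + 1L)
  for (r in seq_len(n_ring - 1)) {   # quad strips between rings
    a0 <- ring_start[r]; b0 <- ring_start[r + 1]
    for (i in seq_len(k)) {
      i2 <- (i %% k) + 1L
      f[[length(f) + 1L]] <- c(a0 + i - 1L, b0 + i - 1L, b0 + i2 - 1L)
      f[[length(f) + 1L]] <- c(a0 + i - 1L, b0 + i2 - 1L, a0 + i2 - 1L)
    }
  }
  faces <- do.call(rbind, f)
  if (jitter > 0) {
    bl <- unique(c(ring_start[n_ring]:(ring_start[n_ring] + k - 1L)))
    for (i in setdiff(seq_len(nrow(v)), bl)) {
      for (try in 1:20) {
        cand <- v[i, ] + stats::rnorm(2, 0, jitter)
        vv <- v; vv[i, ] <- cand
        if (all(signed_areas(vv, faces) > 0)) { v <- vv; break }
      }
    }
  }
  triangle_mesh(v, faces)
}

# random orientation-preserving ("topological") map on a mesh's vertex
# set: small random holomorphic polynomial plus a bounded anti-conformal
# part, rejected until flip-free
random_topological_map <- function(mesh, seed = 1, strength = 0.15) {
  set.seed(seed)
  u <- complex(real = mesh$vertices[, 1], imaginary = mesh$vertices[, 2])
  repeat {
    a <- 1 + strength * complex(real = rnorm(1), imaginary = rnorm(1))
    b <- strength * complex(real = rnorm(1), imaginary = rnorm(1))
    c2 <- strength * complex(real = rnorm(1), imaginary = rnorm(1)) / 2
    c3 <- strength * complex(real = rnorm(1), imaginary = rnorm(1)) / 4
    f <- a * u + c2 * u^2 + c3 * u^3 + b * Conj(u)
    if (count_flipped(u, f, mesh$faces)$count == 0 &&
        max(Mod(compute_beltrami(u, f, mesh$faces)$mu)) < 0.95) return(f)
    strength <- strength * 0.8
  }
}

expect_complex_equal <- function(x, y, tol = 1e-8) {
  expect_lt(max(Mod(x - y)), tol)
}
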