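test_that("triangle_mesh validates and orients a disk mesh", {
  m <- square_grid_mesh(4)
  expect_s3_class(m, "triangle_mesh")
  expect_equal(nrow(m$vertices), 16)
  expect_equal(nrow(m$faces), 18)
  # consistent CCW orientation in the plane
  expect_true(all(signed_areas(m$vertices, m$faces) > 0))
  # single ordered boundary loop of the 12 rim vertices
  expect_length(m$boundary_loop, 12)
  expect_setequal(m$boundary_loop, which(
    m$vertices[, 1] %in% range(m$vertices[, 1]) |
    m$vertices[, 2] %in% range(m$vertices[, 2])))
  # scrambling face orientations is repaired
  f2 <- m$faces
  flip <- c(1, 5, 9)
  f2[flip, c(2, 3)] <- f2[flip, c(3, 2)]
  m2 <- triangle_mesh(m$vertices, f2)
  expect_true(all(signed_areas(m2$vertices, m2$faces) > 0))
})

test_that("triangle_mesh rejects invalid input", {
  v <- rbind(c(0, 0), c(1, 0), c(0, 1))
  expect_error(triangle_mesh(v, rbind(c(1, 2, 4))), "out of range")
  expect_error(triangle_mesh(v, rbind(c(1, 2, 2))), "repeated")
  expect_error(triangle_mesh(v, matrix(1:4, 1)), "non-triangular")
  # zero-area face
  v4 <- rbind(c(0, 0), c(1, 0), c(2, 0), c(0, 1))
  expect_error(triangle_mesh(v4, rbind(c(1, 2, 3), c(1, 3, 4))), "degenerate")
  # annulus (two boundary loops) is not a disk
  ann <- ring_disk_mesh(3, 8)
  inner_fan <- 1:8
  faces_holed <- ann$faces[-inner_fan, ]
  keep <- sort(unique(as.integer(faces_holed)))
  remap <- integer(nrow(ann$vertices)); remap[keep] <- seq_along(keep)
  expect_error(
    triangle_mesh(ann$vertices[keep, ], matrix(remap[faces_holed], ncol = 3)),
    "boundary loops")
})

test_that("mesh file formats round trip", {
  m <- square_grid_mesh(4)
  for (fmt in c("off", "obj")) {
    path <- tempfile(fileext = paste0(".", fmt))
    write_mesh(m, path)
    m2 <- read_mesh(path)
    expect_equal(m2$vertices[, 1:2], m$vertices, tolerance = 1e-12,
                 ignore_attr = TRUE)
    expect_equal(m2$faces, m$faces, ignore_attr = TRUE)
    unlink(path)
  }
  # minimal OFF: single face
  off <- tempfile(fileext = ".off")
  writeLines(c("OFF", "3 1 0", "0 0 0", "1 0 0", "0 1 0", "3 0 1 2"), off)
  m3 <- read_mesh(off)
  expect_equal(nrow(m3$vertices), 3)
  expect_equal(nrow(m3$faces), 1)
  expect_length(m3$boundary_loop, 3)
  # quad face is refused
  off_quad <- tempfile(fileext = ".off")
  writeLines(c("OFF", "4 1 0", "0 0 0", "1 0 0", "1 1 0", "0 1 0",
               "4 0 1 2 3"), off_quad)
  expect_error(read_mesh(off_quad), "non-triangular")
  unlink(c(off, off_quad))
})

test_that("PLY and table formats parse", {
  m <- square_grid_mesh(3)
  ply <- tempfile(fileext = ".ply")
  writeLines(c("ply", "format ascii 1.0",
               paste("element vertex", nrow(m$vertices)),
               "property float x", "property float y", "property float z",
               paste("element face", nrow(m$faces)),
               "property list uchar int vertex_indices", "end_header",
               apply(cbind(m$vertices, 0), 1, paste, collapse = " "),
               apply(cbind(3, m$faces - 1L), 1, paste, collapse = " ")), ply)
  m2 <- read_mesh(ply)
  expect_equal(m2$vertices[, 1:2], m$vertices, tolerance = 1e-6,
               ignore_attr = TRUE)
  vt <- tempfile(); ft <- tempfile()
  utils::write.table(m$vertices, vt, row.names = FALSE, col.names = FALSE)
  utils::write.table(m$faces, ft, row.names = FALSE, col.names = FALSE)
  m3 <- read_mesh(vt, format = "tables", faces_path = ft)
  expect_equal(m3$faces, m$faces, ignore_attr = TRUE)
  unlink(c(ply, vt, ft))
})

test_that("count_flipped matches a cross-product orientation oracle", {
  # closed-form cases
  src <- rbind(c(0, 0), c(1, 0), c(0, 1))
  expect_equal(count_flipped(src, src, rbind(1:3))$count, 0)
  refl <- rbind(c(0, 0), c(1, 0), c(0, -1))
  expect_equal(count_flipped(src, refl, rbind(1:3))$count, 1)
  # degenerate source face flagged, not counted
  degen <- count_flipped(rbind(c(0, 0), c(1, 0), c(2, 0)), refl, rbind(1:3))
  expect_equal(degen$count, 0)
  expect_true(degen$degenerate[1])
  # randomized oracle equivalence on a jittered mesh
  m <- ring_disk_mesh(3, 8, jitter = 0.05, seed = 2)
  set.seed(42)
  for (rep in 1:5) {
    mapped <- m$vertices + matrix(rnorm(length(m$vertices), 0, 0.15), ncol = 2)
    got <- count_flipped(m$vertices, mapped, m$faces)
    oracle <- vapply(seq_len(nrow(m$faces)), function(k) {
      f <- m$faces[k, ]
      cr <- function(P) {
        e1 <- P[f[2], ] - P[f[1], ]; e2 <- P[f[3], ] - P[f[1], ]
        e1[1] * e2[2] - e1[2] * e2[1]
      }
      cr(m$vertices) * cr(mapped) < 0
    }, logical(1))
    expect_equal(got$flipped, oracle)
  }
})

test_that("cut_geodesic_disk matches a brute-force shortest-path oracle", {
  m <- square_grid_mesh(6)
  center <- 15L  # interior vertex
  # brute-force Bellman-Ford over the edge graph
  e <- retinosmooth:::mesh_edges(m$faces)
  w <- sqrt(rowSums((m$vertices[e[, 1], ] - m$vertices[e[, 2], ])^2))
  d <- rep(Inf, nrow(m$vertices)); d[center] <- 0
  for (it in seq_len(nrow(m$vertices))) {
    d1 <- d
    for (k in seq_len(nrow(e))) {
      d1[e[k, 2]] <- min(d1[e[k, 2]], d1[e[k, 1]] + w[k])
      d1[e[k, 1]] <- min(d1[e[k, 1]], d1[e[k, 2]] + w[k])
    }
    if (identical(d1, d)) break
    d <- d1
  }
  expect_equal(geodesic_distances(m, center), d)
  radius <- 2 * 0.2  # twice the grid step
  patch <- cut_geodesic_disk(m, center, radius)
  # oracle for the patch vertex set: faces with all corners within the
  # radius, connected to the center by breadth-first search over them
  inset <- which(d <= radius)
  fk <- m$faces[rowSums(matrix(m$faces %in% inset, ncol = 3)) == 3, , drop = FALSE]
  reach <- center
  repeat {
    grow <- unique(as.integer(fk[rowSums(matrix(fk %in% reach, ncol = 3)) > 0, ]))
    if (all(grow %in% reach)) break
    reach <- union(reach, grow)
  }
  expect_setequal(attr(patch, "vertex_map"), sort(reach))
  expect_true(all(attr(patch, "vertex_map") %in% inset))
  # radius covering everything returns the whole mesh
  whole <- cut_geodesic_disk(m, center, 10)
  expect_equal(nrow(whole$vertices), nrow(m$vertices))
  expect_equal(nrow(whole$faces), nrow(m$faces))
  # radius below the shortest incident edge leaves no faces
  expect_error(cut_geodesic_disk(m, center, 1e-6), "empty patch")
})

test_that("flatten_to_disk is exact on harmonic data and always flip-free", {
  # a mesh already on the unit disk with boundary on the circle is a
  # fixed point (harmonic map with fixed boundary is unique)
  m <- ring_disk_mesh(4, 10)
  dp <- flatten_to_disk(m)
  u0 <- complex(real = m$vertices[, 1], imaginary = m$vertices[, 2])
  # boundary spacing differs from arc-length placement only through edge
  # lengths; here rim edges are equal so placement matches up to rotation
  rot <- dp$u[dp$boundary[1]] / u0[dp$boundary[1]]
  expect_complex_equal(dp$u, u0 * rot, tol = 1e-8)
  # Dirichlet constraint and flip-freeness on irregular meshes
  for (seed in 1:3) {
    mj <- ring_disk_mesh(4, 9, jitter = 0.04, seed = seed)
    mj3 <- triangle_mesh(cbind(mj$vertices, 0.2 * sin(mj$vertices[, 1] * 3)),
                         mj$faces)  # bent 3D patch
    dpj <- flatten_to_disk(mj3)
    expect_lt(max(abs(Mod(dpj$u[dpj$boundary]) - 1)), 1e-10)
    expect_equal(count_flipped(dpj$u,
                               complex(real = mj$vertices[, 1],
                                       imaginary = mj$vertices[, 2]),
                               mj$faces)$count, 0)
    expect_equal(sum(signed_areas(dpj$u, mj$faces) <= 0), 0)
  }
})
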