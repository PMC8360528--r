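# Discrete differential operators on the 2D parametric mesh: per-face
# linear-interpolant gradients, FEM/cotangent stiffness with an arbitrary
# symmetric per-face coefficient matrix, and dual-cell (mixed Voronoi)
# vertex areas. These back both the Linear Beltrami Solver and Laplacian
# smoothing.

# per-face barycentric gradient vectors: list of three m x 2 matrices
# (grad of the hat function of corner 1, 2, 3) plus signed areas
face_basis_gradients <- function(param, faces) {
  P <- as_coord_matrix(param)
  p1 <- P[faces[, 1], , drop = FALSE]
  p2 <- P[faces[, 2], , drop = FALSE]
  p3 <- P[faces[, 3], , drop = FALSE]
  sa <- signed_areas(P, faces)
  if (any(sa == 0)) stop("degenerate face in parametric domain (zero area)")
  rot <- function(e) cbind(-e[, 2], e[, 1])
  g1 <- rot(p3 - p2) / (2 * sa)
  g2 <- rot(p1 - p3) / (2 * sa)
  g3 <- rot(p2 - p1) / (2 * sa)
  list(g1 = g1, g2 = g2, g3 = g3, area = abs(sa), signed_area = sa)
}

#' Per-face gradients of a piecewise-linear vertex field
#'
#' Gradient of the linear (barycentric) interpolant of per-vertex values,
#' constant within each face; exact for globally affine fields. Complex
#' values are differentiated componentwise.
#'
#' @param param per-vertex 2D parametric coordinates (n x 2 or complex).
#' @param values per-vertex values, real or complex.
#' @param faces integer face matrix.
#' @return m x 2 matrix (or complex m x 2 for complex input) with columns
#'   \eqn{\partial/\partial u^1} and \eqn{\partial/\partial u^2}.
#' @export
face_gradients <- function(param, values, faces) {
  g <- face_basis_gradients(param, faces)
  v1 <- values[faces[, 1]]; v2 <- values[faces[, 2]]; v3 <- values[faces[, 3]]
  cbind(g$g1[, 1] * v1 + g$g2[, 1] * v2 + g$g3[, 1] * v3,
        g$g1[, 2] * v1 + g$g2[, 2] * v2 + g$g3[, 2] * v3)
}

# sparse FEM stiffness for the operator -div(A grad .):
# K[p, q] = sum_T area_T * gradB_p' A_T gradB_q.
# A is either NULL (identity: the classic cotangent matrix) or an m x 3
# matrix of per-face symmetric coefficients (a11, a12, a22).
stiffness_matrix <- function(param, faces, A = NULL) {
  g <- face_basis_gradients(param, faces)
  n <- nrow(as_coord_matrix(param))
  gl <- list(g$g1, g$g2, g$g3)
  if (is.null(A)) {
    Ag <- gl
  } else {
    A <- as.matrix(A)
    Ag <- lapply(gl, function(gv)
      cbind(A[, 1] * gv[, 1] + A[, 2] * gv[, 2],
            A[, 2] * gv[, 1] + A[, 3] * gv[, 2]))
  }
  ii <- jj <- xx <- vector("list", 9L)
  k <- 0L
  for (p in 1:3) for (q in 1:3) {
    k <- k + 1L
    ii[[k]] <- faces[, p]
    jj[[k]] <- faces[, q]
    xx[[k]] <- g$area * rowSums(gl[[p]] * Ag[[q]])
  }
  Matrix::sparseMatrix(i = unlist(ii), j = unlist(jj), x = unlist(xx),
                       dims = c(n, n))
}

# mixed Voronoi (circumcentric, obtuse-clamped) dual-cell areas per vertex;
# scheme = "barycentric" uses area/3 per corner instead
dual_cell_areas <- function(param, faces, scheme = c("mixed", "barycentric")) {
  scheme <- match.arg(scheme)
  P <- as_coord_matrix(param)
  n <- nrow(P)
  area <- abs(signed_areas(P, faces))
  if (scheme == "barycentric") {
    w <- rep(area / 3, 3L)
  } else {
    p <- lapply(1:3, function(k) P[faces[, k], , drop = FALSE])
    lensq <- function(e) rowSums(e^2)
    # squared edge lengths opposite each corner
    l1 <- lensq(p[[3]] - p[[2]]); l2 <- lensq(p[[1]] - p[[3]]); l3 <- lensq(p[[2]] - p[[1]])
    cot1 <- (l2 + l3 - l1) / (4 * area)
    cot2 <- (l3 + l1 - l2) / (4 * area)
    cot3 <- (l1 + l2 - l3) / (4 * area)
    vor1 <- (l3 * cot3 + l2 * cot2) / 8
    vor2 <- (l1 * cot1 + l3 * cot3) / 8
    vor3 <- (l2 * cot2 + l1 * cot1) / 8
    ob1 <- cot1 < 0; ob2 <- cot2 < 0; ob3 <- cot3 < 0
    anyob <- ob1 | ob2 | ob3
    w1 <- ifelse(anyob, ifelse(ob1, area / 2, area / 4), vor1)
    w2 <- ifelse(anyob, ifelse(ob2, area / 2, area / 4), vor2)
    w3 <- ifelse(anyob, ifelse(ob3, area / 2, area / 4), vor3)
    w <- c(w1, w2, w3)
  }
  tapply_sum <- function(idx, val) {
    out <- numeric(n); t <- tapply(val, idx, sum); out[as.integer(names(t))] <- t; out
  }
  tapply_sum(c(faces[, 1], faces[, 2], faces[, 3]), w)
}

#' Harmonic flattening of a disk-topology mesh to the unit disk
#'
#' Maps the boundary loop to the unit circle with arc-length proportional
#' spacing and solves the discrete harmonic (cotangent-weight) equations
#' for the interior. By the Rado-Kneser-Choquet property the harmonic map
#' onto a convex target is one-to-one, so the parameterization has zero
#' flipped faces; this is asserted before returning.
#'
#' @param mesh a \code{triangle_mesh} with disk topology.
#' @return list of class \code{disk_param}: \code{u} (complex per-vertex
#'   coordinates, \eqn{|u| \le 1}, boundary on the unit circle),
#'   \code{boundary} (ordered boundary indices), \code{mesh}.
#' @export
flatten_to_disk <- function(mesh) {
  stopifnot(inherits(mesh, "triangle_mesh"))
  bl <- mesh$boundary_loop
  V <- mesh$vertices
  n <- nrow(V)
  # arc-length proportional boundary placement
  edge <- sqrt(rowSums((V[c(bl[-1], bl[1]), , drop = FALSE] - V[bl, , drop = FALSE])^2))
  s <- c(0, cumsum(edge))
  theta <- 2 * pi * s[-length(s)] / s[length(s)]
  ub <- complex(modulus = 1, argument = theta)
  # cotangent weights need a 2D chart only for the coefficient A; for a 3D
  # patch use intrinsic cotangents from edge lengths (same formula as the
  # 2D FEM stiffness, assembled from angles)
  K <- intrinsic_stiffness(mesh)
  interior <- setdiff(seq_len(n), bl)
  u <- complex(length.out = n)
  u[bl] <- ub
  if (length(interior)) {
    rhs <- -K[interior, bl, drop = FALSE] %*% cbind(Re(ub), Im(ub))
    sol <- Matrix::solve(K[interior, interior], rhs)
    u[interior] <- complex(real = sol[, 1], imaginary = sol[, 2])
  }
  # global reflection if the chart came out clockwise
  if (sum(signed_areas(u, mesh$faces) > 0) < nrow(mesh$faces) / 2) u <- Conj(u)
  fl <- count_flipped_param(u, mesh$faces)
  if (fl > 0)
    stop(sprintf("flattening produced %d flipped face(s); mesh quality too poor", fl))
  structure(list(u = u, boundary = bl, mesh = mesh), class = "disk_param")
}

count_flipped_param <- function(u, faces) sum(signed_areas(u, faces) <= 0)

# cotangent stiffness from intrinsic edge lengths (valid for 2D and 3D
# embeddings; equals stiffness_matrix(param, faces) for planar meshes)
intrinsic_stiffness <- function(mesh) {
  V <- mesh$vertices; faces <- mesh$faces
  n <- nrow(V)
  p <- lapply(1:3, function(k) V[faces[, k], , drop = FALSE])
  lensq <- function(e) rowSums(e^2)
  l1 <- lensq(p[[3]] - p[[2]]); l2 <- lensq(p[[1]] - p[[3]]); l3 <- lensq(p[[2]] - p[[1]])
  area <- face_areas(V, faces)
  cot1 <- (l2 + l3 - l1) / (4 * area)
  cot2 <- (l3 + l1 - l2) / (4 * area)
  cot3 <- (l1 + l2 - l3) / (4 * area)
  ii <- c(faces[, 2], faces[, 3], faces[, 3], faces[, 1], faces[, 1], faces[, 2])
  jj <- c(faces[, 3], faces[, 2], faces[, 1], faces[, 3], faces[, 2], faces[, 1])
  xx <- -c(cot1, cot1, cot2, cot2, cot3, cot3) / 2
  W <- Matrix::sparseMatrix(i = ii, j = jj, x = xx, dims = c(n, n))
  Matrix::Diagonal(n, -Matrix::rowSums(W)) + W
}
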