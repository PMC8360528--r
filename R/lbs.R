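#' Elliptic coefficients of the Linear Beltrami Solver
#'
#' For a per-face Beltrami coefficient \eqn{\mu = \rho + i\tau}, the map
#' with that \eqn{\mu} satisfies \eqn{\nabla\cdot A\nabla f^{(1)} = 0} and
#' \eqn{\nabla\cdot A\nabla f^{(2)} = 0} with
#' \deqn{\alpha_1 = \frac{(\rho-1)^2+\tau^2}{\rho^2+\tau^2-1},\quad
#'       \alpha_2 = \frac{-2\tau}{\rho^2+\tau^2-1},\quad
#'       \alpha_3 = \frac{(\rho+1)^2+\tau^2}{\rho^2+\tau^2-1}.}
#' The coefficients blow up as \eqn{|\mu| \to 1}; values inside the guard
#' band are rejected so callers must project ("chop") first.
#'
#' @param mu complex vector of per-face Beltrami coefficients.
#' @param guard reject faces with \eqn{||\mu|^2 - 1|} below this.
#' @return m x 3 matrix with columns \code{alpha1, alpha2, alpha3}.
#' @export
lbs_coefficients <- function(mu, guard = 1e-6) {
  rho <- Re(mu); tau <- Im(mu)
  den <- rho^2 + tau^2 - 1
  if (any(abs(den) < guard))
    stop(sprintf("%d face(s) with |mu| within the guard band of 1; project the Beltrami field first",
                 sum(abs(den) < guard)))
  cbind(alpha1 = ((rho - 1)^2 + tau^2) / den,
        alpha2 = -2 * tau / den,
        alpha3 = ((rho + 1)^2 + tau^2) / den)
}

#' Assemble the discrete divergence operator for given face coefficients
#'
#' Builds the sparse operator encoding \eqn{-\nabla\cdot A\nabla} with
#' per-face constant gradients and dual-cell boundary integration: the row
#' of vertex \eqn{i} accumulates \eqn{G_T \cdot s_i/2} over incident faces,
#' where \eqn{G_T = A_T\nabla f|_T} and \eqn{s_i = (u_k - u_j)^\perp} is
#' the rotated edge opposite \eqn{i}, and is scaled by the dual-cell area
#' \eqn{|D_i|}. For \eqn{A = I} and unit row scaling this is the classic
#' cotangent Laplacian; linear fields are in its kernel at interior
#' vertices, and with face-constant \eqn{A} constants are in its kernel.
#'
#' @param param per-vertex parametric coordinates.
#' @param faces integer face matrix.
#' @param A per-face symmetric coefficients, m x 3 (a11, a12, a22), or
#'   \code{NULL} for the identity.
#' @param dual dual-cell scheme for the row scaling, \code{"mixed"}
#'   (circumcentric with obtuse clamping) or \code{"barycentric"}.
#' @param scale_rows divide each row by its dual-cell area (default
#'   \code{TRUE}); the unscaled matrix is the symmetric FEM stiffness.
#' @return sparse \code{dgCMatrix}; attribute \code{"dual_area"} carries
#'   the per-vertex dual-cell areas.
#' @export
assemble_divergence <- function(param, faces, A = NULL,
                                dual = c("mixed", "barycentric"),
                                scale_rows = TRUE) {
  dual <- match.arg(dual)
  n <- nrow(as_coord_matrix(param))
  deg <- tabulate(faces, nbins = n)
  if (any(deg == 0L)) stop("isolated vertex: every vertex must belong to a face")
  K <- stiffness_matrix(param, faces, A)
  d <- dual_cell_areas(param, faces, dual)
  L <- if (scale_rows) Matrix::Diagonal(n, 1 / d) %*% K else K
  attr(L, "dual_area") <- d
  L
}

#' Recover a mapping from a prescribed Beltrami field (Linear Beltrami Solver)
#'
#' Solves the two decoupled elliptic systems
#' \eqn{\nabla\cdot A\nabla f^{(1)} = 0}, \eqn{\nabla\cdot A\nabla f^{(2)} = 0}
#' with Dirichlet values on the boundary loop, where \eqn{A} is built from
#' the per-face Beltrami coefficients. With \eqn{|\mu| < 1} everywhere the
#' solution exists and is unique (the Beltrami coefficient uniquely encodes
#' the mapping up to the boundary data); both real systems share one
#' factorization.
#'
#' @param param per-vertex parametric coordinates (complex or n x 2).
#' @param faces integer face matrix.
#' @param mu per-face complex Beltrami coefficients (all \eqn{|\mu| < 1}),
#'   or a \code{beltrami_field}.
#' @param boundary integer indices of the boundary vertices.
#' @param boundary_values complex values on those vertices.
#' @param dual dual-cell scheme (see [assemble_divergence()]).
#' @return complex per-vertex mapping \eqn{\hat f}.
#' @export
solve_lbs <- function(param, faces, mu, boundary, boundary_values,
                      dual = c("mixed", "barycentric")) {
  if (inherits(mu, "beltrami_field")) mu <- mu$mu
  if (any(Mod(mu) >= 1))
    stop("|mu| >= 1 on some face; apply project_beltrami() before solving")
  if (length(boundary) != length(boundary_values))
    stop("boundary and boundary_values lengths differ")
  A <- lbs_coefficients(mu)
  K <- assemble_divergence(param, faces, A, dual = match.arg(dual),
                           scale_rows = FALSE)
  n <- nrow(as_coord_matrix(param))
  interior <- setdiff(seq_len(n), boundary)
  f <- complex(length.out = n)
  bv <- as_complex_coords(boundary_values)
  f[boundary] <- bv
  if (length(interior)) {
    rhs <- -K[interior, boundary, drop = FALSE] %*% cbind(Re(bv), Im(bv))
    sol <- tryCatch(Matrix::solve(K[interior, interior], rhs),
                    error = function(e)
                      stop("singular LBS system: ", conditionMessage(e),
                           " (rcond ~ ",
                           format(Matrix::rcond(K[interior, interior, drop = FALSE]),
                                  digits = 3), ")", call. = FALSE))
    f[interior] <- complex(real = sol[, 1], imaginary = sol[, 2])
  }
  f
}
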