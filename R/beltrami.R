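#' Per-face Beltrami coefficients of a discrete mapping
#'
#' For the piecewise-linear map \eqn{\hat f : u \mapsto \hat f(u)} between
#' two 2D embeddings of a triangulation, computes on every face the
#' Beltrami coefficient
#' \deqn{\mu = \frac{\partial\hat f/\partial u^1 + i\,\partial\hat f/\partial u^2}
#'                  {\partial\hat f/\partial u^1 - i\,\partial\hat f/\partial u^2},}
#' with \eqn{u = u^1 + iu^2} and \eqn{\hat f} complex. \eqn{\mu} is constant
#' per face because the interpolant is linear. \eqn{|\mu| < 1} iff the face
#' preserves orientation; \eqn{\mu = 0} iff the face is mapped conformally.
#' Also returns the Jacobian determinant \eqn{J = |f_z|^2(1 - |\mu|^2)} and
#' per-face orientation flags.
#'
#' Anti-conformal faces (denominator exactly zero, i.e. \eqn{f_z = 0}) get
#' a finite sentinel magnitude of \code{1e9} and \code{sentinel = TRUE},
#' so downstream projection stays well defined.
#'
#' @param param per-vertex parametric coordinates (complex or n x 2).
#' @param mapped per-vertex mapped coordinates (complex or n x 2).
#' @param faces integer face matrix.
#' @return object of class \code{beltrami_field}: list with complex
#'   \code{mu}, numeric \code{jac}, logical \code{flipped}, logical
#'   \code{sentinel}, and complex \code{fz}, \code{fzbar} per face.
#' @export
compute_beltrami <- function(param, mapped, faces) {
  f <- as_complex_coords(mapped)
  g <- face_gradients(param, f, faces)
  fz    <- (g[, 1] - 1i * g[, 2]) / 2
  fzbar <- (g[, 1] + 1i * g[, 2]) / 2
  # anti-conformal faces leave fz at rounding level, not exactly zero
  sentinel <- Mod(fz) <= 1e-12 * (Mod(fz) + Mod(fzbar))
  mu <- complex(length.out = length(fz))
  ok <- !sentinel
  mu[ok] <- fzbar[ok] / fz[ok]
  mu[sentinel] <- complex(modulus = 1e9, argument = Arg(fzbar[sentinel]))
  jac <- Mod(fz)^2 - Mod(fzbar)^2
  flipped <- jac < 0 | sentinel
  structure(list(mu = mu, jac = jac, flipped = flipped, sentinel = sentinel,
                 fz = fz, fzbar = fzbar),
            class = "beltrami_field")
}

#' @export
print.beltrami_field <- function(x, ...) {
  finite <- !x$sentinel
  cat(sprintf("beltrami_field: %d faces, max|mu| = %.4g%s, %d flipped\n",
              length(x$mu),
              if (any(finite)) max(Mod(x$mu[finite])) else NA_real_,
              if (any(x$sentinel)) sprintf(" (+%d anti-conformal sentinels)", sum(x$sentinel)) else "",
              sum(x$flipped)))
  invisible(x)
}

#' Angle distortion of a discrete mapping
#'
#' Per face, the absolute deviation from 90 degrees of the angle between
#' the images of the two parametric coordinate directions (the tangents of
#' the \eqn{u^1}- and \eqn{u^2}-contour families), in degrees. Conformal
#' maps score 0. Note this orthogonality measure is not \eqn{|\mu|}: a pure
#' coordinate-axis stretch also scores 0 while its \eqn{\mu \neq 0}.
#'
#' Faces whose Jacobian has a zero column are excluded from the summary
#' statistics (with their count reported); flipped faces are included with
#' their computed values.
#'
#' @inheritParams compute_beltrami
#' @return list with \code{per_face} (degrees), \code{mean}, \code{sd},
#'   and \code{n_excluded}.
#' @export
angle_distortion <- function(param, mapped, faces) {
  f <- as_complex_coords(mapped)
  g <- face_gradients(param, f, faces)
  # Jacobian columns: image of e1 is (Re g1, Im g1), image of e2 likewise
  c1x <- Re(g[, 1]); c1y <- Im(g[, 1])
  c2x <- Re(g[, 2]); c2y <- Im(g[, 2])
  n1 <- sqrt(c1x^2 + c1y^2); n2 <- sqrt(c2x^2 + c2y^2)
  bad <- n1 == 0 | n2 == 0
  cosang <- (c1x * c2x + c1y * c2y) / (n1 * n2)
  ang <- acos(pmin(1, pmax(-1, cosang))) * 180 / pi
  per_face <- abs(90 - ang)
  per_face[bad] <- NA_real_
  list(per_face = per_face,
       mean = mean(per_face[!bad]),
       sd = stats::sd(per_face[!bad]),
       n_excluded = sum(bad))
}

#' Export a Beltrami field as a data frame
#'
#' One row per face with real/imaginary parts, magnitude, Jacobian and
#' flip flag, suitable for writing as TSV.
#'
#' @param bf a \code{beltrami_field}.
#' @return data.frame with columns
#'   \code{face, re_mu, im_mu, abs_mu, jac, flipped}.
#' @export
beltrami_table <- function(bf) {
  data.frame(face = seq_along(bf$mu),
             re_mu = Re(bf$mu), im_mu = Im(bf$mu), abs_mu = Mod(bf$mu),
             jac = bf$jac, flipped = bf$flipped)
}
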