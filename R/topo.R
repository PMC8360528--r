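#' Topological projection ("chopping") of a Beltrami field
#'
#' Faces with \eqn{|\mu| \le 1} are left unchanged; faces with
#' \eqn{|\mu| > 1} are rescaled to \eqn{\mu' = \mu/(|\mu| + \epsilon)},
#' which keeps the argument and brings the magnitude strictly below 1.
#' Anti-conformal sentinel faces are set to magnitude
#' \eqn{1/(1+\epsilon)} with argument 0. Faces whose magnitude falls
#' inside the narrow guard band just below 1 (where the reconstruction
#' PDE coefficients of [lbs_coefficients()] degenerate) are rescaled the
#' same way, so the projected field is always solvable.
#'
#' @param bf a \code{beltrami_field} or complex vector of per-face
#'   coefficients.
#' @param eps_proj positive projection epsilon.
#' @param guard half-width of the degeneracy guard band below
#'   \eqn{|\mu| = 1}.
#' @return same type as the input, with all magnitudes \eqn{< 1} where
#'   they exceeded \eqn{1 - guard} (already-admissible faces untouched).
#' @export
project_beltrami <- function(bf, eps_proj = 0.01, guard = 1e-6) {
  if (eps_proj <= 0) stop("eps_proj must be positive")
  is_field <- inherits(bf, "beltrami_field")
  mu <- if (is_field) bf$mu else bf
  sentinel <- if (is_field) bf$sentinel else rep(FALSE, length(mu))
  m <- Mod(mu)
  over <- m > 1 - guard & !sentinel
  mu[over] <- mu[over] / (m[over] + eps_proj)
  mu[sentinel] <- complex(real = 1 / (1 + eps_proj), imaginary = 0)
  if (is_field) { bf$mu <- mu; bf } else mu
}

# Extended polar-angle coding.
#
# Raw polar angle theta is measured in [0, 2*pi) from the positive x-axis
# of the visual field. The left hemisphere sees the right hemifield
# (quadrants I and IV), the right hemisphere the left hemifield (II, III);
# ventral areas carry the upper quadrant, dorsal the lower. Two affine
# transformations per (region, hemisphere) remove the 0/2pi wrap
# ("phase jumping") and the alternating visual-field sign across V1/V2/V3
# borders ("phase reversal"). On top of the raw transformations a fixed
# per-(region, hemisphere) multiple of 2*pi is added so the six extended
# ranges form one continuous monotone chain
# V3d -> V2d -> V1d -> V1v -> V2v -> V3v covering [-pi/2, 5*pi/2] for both
# hemispheres. Rows: slope a, intercept b (raw transformation T = a*theta
# + b0 plus the canonical 2*pi offset), and the extended range [lo, hi].
.ext_regions <- c("V1v", "V1d", "V2v", "V2d", "V3v", "V3d")
.ext_table <- list(
  left = data.frame(
    region = .ext_regions,
    a  = c( 1,  1, -1, -1,  1,  1),
    b  = c( pi, -pi, 2 * pi, 2 * pi, 2 * pi, -2 * pi),  # V2d: -2*pi raw + 4*pi offset
    lo = c( pi,  pi / 2, 3 * pi / 2, 0, 2 * pi, -pi / 2),
    hi = c(3 * pi / 2, pi, 2 * pi, pi / 2, 5 * pi / 2, 0)),
  right = data.frame(
    region = .ext_regions,
    a  = c( 1,  1, -1, -1,  1,  1),
    b  = c( 0,  0,  pi, 3 * pi, -pi, pi),  # V2d: -pi + 4*pi; V3v: pi - 2*pi; V3d: -pi + 2*pi
    lo = c( pi / 2,  pi, 0, 3 * pi / 2, -pi / 2, 2 * pi),
    hi = c( pi, 3 * pi / 2, pi / 2, 2 * pi, 0, 5 * pi / 2)))

#' Extended polar angle from raw polar angle, visual area and hemisphere
#'
#' Applies the per-(region, hemisphere) affine re-coding of the polar
#' angle that removes phase jumping at the horizontal meridian and the
#' visual-field sign reversals at the V1/V2 and V2/V3 borders, plus a
#' fixed multiple of \eqn{2\pi} per region so the six extended ranges form
#' a single numerically continuous monotone chain over
#' \eqn{[-\pi/2, 5\pi/2]}. The coding is bijective: see
#' [invert_extended_polar()].
#'
#' @param ang polar angle in radians (reduced mod \eqn{2\pi}).
#' @param region visual-area labels, in
#'   \code{V1v, V1d, V2v, V2d, V3v, V3d} (recycled).
#' @param hemi \code{"left"} or \code{"right"} (scalar).
#' @return extended polar angle in radians.
#' @export
extend_polar <- function(ang, region, hemi = c("left", "right")) {
  hemi <- match.arg(hemi)
  tab <- .ext_table[[hemi]]
  region <- as.character(region)
  ri <- match(region, tab$region)
  if (anyNA(ri))
    stop("unknown region label: ", paste(unique(region[is.na(ri)]), collapse = ", "))
  ri <- rep_len(ri, length(ang))
  theta <- ang %% (2 * pi)
  ext <- tab$a[ri] * theta + tab$b[ri]
  # wrap into the region's own extended bin (choose the 2*pi translate
  # closest to the bin; noisy angles just outside their nominal quadrant
  # stay continuous across the border)
  lo <- tab$lo[ri]; hi <- tab$hi[ri]
  for (k in c(-2, -1, 1, 2)) {
    cand <- ext + 2 * pi * k
    better <- bin_dist(cand, lo, hi) < bin_dist(ext, lo, hi)
    ext[better] <- cand[better]
  }
  ext
}

bin_dist <- function(x, lo, hi) pmax(lo - x, x - hi, 0)

#' Recover polar angle and visual area from the extended polar angle
#'
#' Exact inverse of [extend_polar()]: the visual area is decoded from the
#' extended-range bins and the raw angle by the inverse affine map. Values
#' at a shared border resolve to the region earlier in the order
#' \code{V1v, V1d, V2v, V2d, V3v, V3d}. Values outside the total range
#' \eqn{[-\pi/2, 5\pi/2]} are clamped with a warning; values farther than
#' \code{tol} outside raise an error.
#'
#' @param ext_ang extended polar angle in radians.
#' @param hemi \code{"left"} or \code{"right"}.
#' @param tol clamping tolerance.
#' @return list with \code{ang} (radians in \eqn{[0, 2\pi)}) and
#'   \code{region} (character).
#' @export
invert_extended_polar <- function(ext_ang, hemi = c("left", "right"), tol = 1e-8) {
  hemi <- match.arg(hemi)
  tab <- .ext_table[[hemi]]
  lo_all <- -pi / 2; hi_all <- 5 * pi / 2
  out_of_range <- ext_ang < lo_all - tol | ext_ang > hi_all + tol
  if (any(out_of_range))
    stop(sprintf("%d extended angle(s) outside [-pi/2, 5pi/2] beyond tolerance",
                 sum(out_of_range)))
  if (any(ext_ang < lo_all | ext_ang > hi_all))
    warning("extended angle(s) clamped to the valid range")
  x <- pmin(pmax(ext_ang, lo_all), hi_all)
  n <- length(x)
  ri <- rep(NA_integer_, n)
  for (r in seq_len(nrow(tab))) {   # table order implements the tie-break
    hit <- is.na(ri) & x >= tab$lo[r] - tol & x <= tab$hi[r] + tol
    ri[hit] <- r
  }
  theta <- (tab$a[ri] * (x - tab$b[ri])) %% (2 * pi)
  list(ang = theta, region = tab$region[ri])
}

#' Boundary update by a linear fit near the boundary
#'
#' Fits, for each coordinate, a linear function of \eqn{(u^1, u^2)} by
#' least squares to the interior values within a collar of the boundary
#' (one-ring neighbours of boundary vertices plus interior vertices within
#' parametric distance \code{collar_dist}) and evaluates it at the
#' boundary vertices. The change tolerance \code{eps_boundary} is then
#' enforced against the reference values \code{initial} in one of two
#' ways: \code{mode = "restore"} rejects any proposal deviating by more
#' than \code{eps_boundary} (that vertex keeps its reference value);
#' \code{mode = "clamp"} moves at most \code{eps_boundary} from the
#' reference toward the proposal. The solver loop uses \code{"clamp"}
#' against the current boundary values, so each iteration changes the
#' boundary by at most the tolerance while repeated updates can migrate
#' a locally folded boundary toward the near-boundary trend of the data.
#'
#' @param param per-vertex parametric coordinates (complex or n x 2).
#' @param faces integer face matrix.
#' @param values current per-vertex complex mapping.
#' @param boundary boundary vertex indices.
#' @param initial reference boundary values \eqn{v_B} (complex, same
#'   order as \code{boundary}).
#' @param eps_boundary boundary change tolerance.
#' @param collar_dist parametric distance defining the collar.
#' @param mode tolerance enforcement, \code{"restore"} or \code{"clamp"}.
#' @param fit \code{"global"}: one least-squares linear function over the
#'   whole collar; \code{"local"}: a separate linear fit per boundary
#'   vertex over the interior vertices within graph distance 2 (used by
#'   the solver loop, where the boundary must track the local trend of
#'   the data rather than a single affine model of the whole patch).
#' @export
update_boundary <- function(param, faces, values, boundary, initial,
                            eps_boundary, collar_dist = 0.1,
                            mode = c("restore", "clamp"),
                            fit = c("global", "local")) {
  mode <- match.arg(mode)
  fit <- match.arg(fit)
  P <- as_coord_matrix(param)
  f <- as_complex_coords(values)
  n <- nrow(P)
  interior <- setdiff(seq_len(n), boundary)
  onb <- faces[rowSums(matrix(faces %in% boundary, ncol = 3)) > 0L, , drop = FALSE]
  ring <- intersect(unique(as.integer(onb)), interior)
  if (length(interior)) {
    d2 <- outer(P[interior, 1], P[boundary, 1], "-")^2 +
          outer(P[interior, 2], P[boundary, 2], "-")^2
    near <- interior[sqrt(apply(d2, 1, min)) <= collar_dist]
  } else near <- integer(0)
  collar <- union(ring, near)
  if (length(collar) < 3) {
    warning("fewer than 3 interior vertices in the boundary collar; keeping previous boundary values")
    return(initial)
  }
  if (fit == "global") {
    X <- cbind(1, P[collar, 1], P[collar, 2])
    if (qr(X)$rank < 3L) {
      warning("rank-deficient boundary fit; keeping previous boundary values")
      return(initial)
    }
    Xb <- cbind(1, P[boundary, 1], P[boundary, 2])
    pred_re <- Xb %*% stats::lm.fit(X, Re(f[collar]))$coefficients
    pred_im <- Xb %*% stats::lm.fit(X, Im(f[collar]))$coefficients
    prop <- complex(real = pred_re, imaginary = pred_im)
  } else {
    # per-vertex fits over the interior vertices within graph distance 2
    # of each boundary vertex: local extrapolation of the interior trend
    lf <- local_boundary_fit(P, faces, f, boundary, interior)
    prop <- lf$pred
    prop[is.na(prop)] <- initial[is.na(lf$pred)]
  }
  dev <- Mod(prop - initial)
  if (mode == "restore") {
    prop[dev > eps_boundary] <- initial[dev > eps_boundary]
  } else {
    far <- dev > eps_boundary
    prop[far] <- initial[far] +
      (prop[far] - initial[far]) * (eps_boundary / dev[far])
  }
  prop
}

# Per-boundary-vertex linear extrapolation of a per-vertex field from
# the interior vertices within graph distance 2. Returns the complex
# prediction (NA where no stable fit exists), the fit's residual scale
# and the leverage of the prediction point, so callers can judge how
# trustworthy each extrapolation is.
local_boundary_fit <- function(P, faces, f, boundary, interior) {
  n <- nrow(P)
  nb <- one_rings(faces, n)
  m <- length(boundary)
  pred <- complex(length.out = m) * NA
  sig <- lev <- rep(NA_real_, m)
  for (k in seq_len(m)) {
    b <- boundary[k]
    n1 <- setdiff(nb[[b]], b)
    n2 <- setdiff(unique(unlist(nb[n1])), b)
    loc <- intersect(n2, interior)
    if (length(loc) < 3) next
    X <- cbind(1, P[loc, 1], P[loc, 2])
    qx <- qr(X)
    if (qx$rank < 3L) next
    xb <- c(1, P[b, 1], P[b, 2])
    fit_re <- stats::lm.fit(X, Re(f[loc]))
    fit_im <- stats::lm.fit(X, Im(f[loc]))
    pred[k] <- complex(real = sum(xb * fit_re$coefficients),
                       imaginary = sum(xb * fit_im$coefficients))
    dfree <- length(loc) - 3
    sig[k] <- sqrt((sum(fit_re$residuals^2) + sum(fit_im$residuals^2)) /
                   max(dfree, 1))
    lev[k] <- sum(backsolve(qr.R(qx), xb, transpose = TRUE)^2)
  }
  list(pred = pred, sig = sig, lev = lev)
}

#' Quasiconformal topological smoothing of a 2D mapping
#'
#' The core solver. Starting from noisy per-vertex target coordinates
#' \eqn{f_0} over a flip-free parametric mesh, it alternates the two
#' subproblems of the constrained smoothing model:
#' \enumerate{
#'   \item \emph{Smoothing}: one weighted Laplacian-smoothing pass
#'     (weight \code{s}, fidelity weights \code{W}) with the boundary
#'     held at the Dirichlet values \eqn{v_B} (initialized, unless
#'     given, from the one-ring average of the input).
#'   \item \emph{Topological projection}: while the current map violates
#'     \eqn{\max|\mu| < 1}, chop the per-face Beltrami coefficients
#'     (\eqn{\mu' = \mu/(|\mu| + \epsilon)} where \eqn{|\mu| > 1}) and
#'     reconstruct the map from \eqn{\mu'} with the Linear Beltrami
#'     Solver under the boundary values \eqn{v_B}. After each
#'     reconstruction, \eqn{v_B} is re-estimated by a linear fit near
#'     the boundary, restoring any vertex that drifts more than
#'     \code{eps_boundary} from its initial value.
#' }
#' The loop terminates as soon as the current iterate satisfies
#' \eqn{\max|\mu| < 1} with zero flipped faces (so the returned map
#' always satisfies the topology constraint exactly), or errors out at
#' \code{max_iter}. The smoothing pass is not re-run between projection
#' passes: for small \code{s} its solution is governed by the boundary
#' values rather than by the current iterate, so re-smoothing would
#' discard projection progress without changing the smooth component.
#' An input that already satisfies the topology constraint is returned
#' unchanged (there is nothing to fix).
#'
#' @param param per-vertex parametric coordinates (complex or n x 2), the
#'   source embedding; must itself be flip-free.
#' @param faces integer face matrix.
#' @param f0 per-vertex target coordinates, complex (or n x 2).
#' @param boundary boundary vertex indices (default: boundary loop of the
#'   parametric triangulation).
#' @param boundary_values initial boundary values \eqn{v_B} (default: the
#'   one-ring average-smoothed input at the boundary).
#' @param s Laplacian smoothing weight (small = heavy smoothing).
#' @param weights per-vertex fidelity weights \eqn{W}.
#' @param eps_proj projection epsilon.
#' @param eps_boundary boundary change tolerance.
#' @param max_iter iteration cap.
#' @param collar_dist collar size for the boundary fit.
#' @param dual dual-cell scheme.
#' @return list of class \code{qc_smooth}: \code{f} (smoothed complex
#'   coordinates), \code{iterations}, \code{trace} (per-iteration
#'   \eqn{\max|\mu|}), \code{flip_trace}, \code{converged},
#'   \code{boundary}, \code{boundary_values}.
#' @export
qc_smooth <- function(param, faces, f0, boundary = NULL,
                      boundary_values = NULL, s = 0.001, weights = 1,
                      eps_proj = 0.01, eps_boundary = 0.01, max_iter = 100,
                      collar_dist = 0.1, dual = "mixed") {
  u <- as_complex_coords(param)
  f <- as_complex_coords(f0)
  if (count_flipped_param(u, faces) > 0)
    stop("parametric domain has flipped or degenerate faces")
  if (is.null(boundary)) {
    bl <- boundary_loops(faces)
    if (length(bl) != 1L) stop("expected a single boundary loop")
    boundary <- bl[[1]]
  }
  if (is.null(boundary_values)) {
    # infer v_B from the one-ring average-smoothed field: local linear
    # extrapolation from its interior collar, so a wild raw value at a
    # boundary vertex never enters its own initial boundary value
    favg <- baseline_smooth("average", u, faces, f)
    boundary_values <- update_boundary(u, faces, favg, boundary,
                                       favg[boundary], Inf, collar_dist,
                                       fit = "local")
  }
  vB_init <- as_complex_coords(boundary_values)
  vB <- vB_init
  bf0 <- compute_beltrami(u, f, faces)
  if (max(Mod(bf0$mu)) < 1 && count_flipped(u, f, faces)$count == 0L) {
    # already topological: nothing to fix
    return(structure(list(f = f, iterations = 0L,
                          trace = max(Mod(bf0$mu)), flip_trace = 0L,
                          converged = TRUE, boundary = boundary,
                          boundary_values = f[boundary]),
                     class = "qc_smooth"))
  }
  # subproblem 1: smoothing (single pass, boundary pinned at v_B)
  f <- laplacian_smooth(u, faces, f, s = s, weights = weights,
                        boundary = boundary, boundary_values = vB,
                        dual = dual)
  trace <- numeric(0); flip_trace <- integer(0)
  iter <- 0L
  repeat {
    bf <- compute_beltrami(u, f, faces)
    mmax <- max(Mod(bf$mu))
    nflip <- count_flipped(u, f, faces)$count
    trace <- c(trace, mmax); flip_trace <- c(flip_trace, nflip)
    if (mmax < 1 && nflip == 0L) {
      return(structure(list(f = f, iterations = iter, trace = trace,
                            flip_trace = flip_trace, converged = TRUE,
                            boundary = boundary, boundary_values = vB),
                       class = "qc_smooth"))
    }
    if (iter >= max_iter) {
      cond <- simpleError(sprintf(
        "topological smoothing did not converge in %d iterations (max|mu| = %.3g, %d flips)",
        max_iter, mmax, nflip))
      cond$mu_trace <- trace; cond$flip_trace <- flip_trace
      stop(cond)
    }
    iter <- iter + 1L
    # subproblem 2: chop + reconstruct, then boundary refresh
    mu_p <- project_beltrami(bf, eps_proj)$mu
    f <- solve_lbs(u, faces, mu_p, boundary, vB, dual = dual)
    vB <- update_boundary(u, faces, f, boundary, vB, eps_boundary,
                          collar_dist, mode = "clamp", fit = "local")
    f[boundary] <- vB
  }
}

#' @export
print.qc_smooth <- function(x, ...) {
  cat(sprintf("qc_smooth: converged in %d iteration(s); max|mu| %.4g -> %.4g; flips %d -> %d\n",
              x$iterations, x$trace[1], x$trace[length(x$trace)],
              x$flip_trace[1], x$flip_trace[length(x$flip_trace)]))
  invisible(x)
}
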