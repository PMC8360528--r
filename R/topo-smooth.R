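#' Topology-preserving smoothing of a retinotopic map
#'
#' The main fitting function. Takes a flattened cortical patch (or any
#' flip-free 2D parameterization) with per-vertex raw visual-field
#' coordinates and returns smoothed coordinates whose mapping has
#' \eqn{\max|\mu| < 1} and zero flipped triangles, by the iterative
#' chop-reconstruct-smooth loop of [qc_smooth()].
#'
#' Two coordinate codings are available. \code{"cartesian"} smooths the
#' visual-field positions \eqn{x + iy}
#' (\eqn{x = ecc\cos\theta,\ y = ecc\sin\theta}), the natural choice for a
#' single-area (V1) patch. \code{"ecc_extang"} smooths
#' \eqn{ecc + i\,T(\theta)} with \eqn{T} the extended polar angle
#' ([extend_polar()]), which removes phase jumping and the visual-field
#' sign reversals across area borders and is the coding to use for
#' multi-area (V1-V3) patches; it requires per-vertex region labels, and
#' the smoothed output is decoded back to polar angle and region labels.
#'
#' Fidelity weights default to 1; with pRF fits available, pass
#' \code{r2} to weight vertices by \eqn{\max(R^2, 0)/100}.
#'
#' @param x a \code{triangle_mesh} (flattened internally via
#'   [flatten_to_disk()]), a \code{disk_param}, or a per-vertex 2D/complex
#'   coordinate set (then give \code{faces}).
#' @param values optional per-vertex target coordinates (complex or
#'   n x 2) smoothed as-is, bypassing the visual-field codings; used by
#'   the synthetic benchmarks where the mapped quantity is already a
#'   plane coordinate.
#' @param ecc per-vertex eccentricity, degrees.
#' @param ang per-vertex polar angle, radians in \eqn{[0, 2\pi)}.
#' @param faces face matrix, when \code{x} is a raw coordinate set.
#' @param coords coordinate coding, see Details.
#' @param region per-vertex visual-area labels (V1v...V3d), for
#'   \code{coords = "ecc_extang"}.
#' @param hemi \code{"left"} or \code{"right"}.
#' @param weights per-vertex fidelity weights; overrides \code{r2}.
#' @param r2 per-vertex percent variance explained, mapped to weights
#'   \eqn{\max(R^2, 0)/100}.
#' @param s,eps_proj,eps_boundary,max_iter,collar_dist,boundary_values
#'   smoother settings passed to [qc_smooth()] (\code{eps_boundary}
#'   defaults to 0.01; 0.5 degrees is a reasonable tolerance for real
#'   pRF data in Cartesian coding).
#' @param ... further arguments to [qc_smooth()].
#' @return object of class \code{topo_smooth}; see
#'   [coef.topo_smooth()], [fitted.topo_smooth()],
#'   [residuals.topo_smooth()], [plot.topo_smooth()].
#' @examples
#' dat <- gen_log_model(psnr = 10, seed = 7)
#' fit <- topo_smooth(dat$v, faces = dat$mesh$faces,
#'                    values = dat$u_noisy)
#' fit
#' @export
topo_smooth <- function(x, ecc = NULL, ang = NULL, faces = NULL,
                        values = NULL,
                        coords = c("cartesian", "ecc_extang"),
                        region = NULL, hemi = c("left", "right"),
                        weights = NULL, r2 = NULL,
                        boundary_values = NULL, s = 0.001,
                        eps_proj = 0.01, eps_boundary = 0.01,
                        max_iter = 100, collar_dist = 0.1, ...) {
  coords <- match.arg(coords)
  hemi <- match.arg(hemi)
  cl <- match.call()
  if (inherits(x, "triangle_mesh")) {
    dp <- flatten_to_disk(x)
    param <- dp$u; faces <- x$faces
  } else if (inherits(x, "disk_param")) {
    param <- x$u; faces <- x$mesh$faces
  } else {
    if (is.null(faces)) stop("faces must be given with raw coordinates")
    param <- as_complex_coords(x)
  }
  if (!is.null(values)) {
    f0 <- as_complex_coords(values)
    coords <- "raw"
  } else if (coords == "cartesian") {
    if (is.null(ecc) || is.null(ang)) stop("ecc and ang are required")
    f0 <- complex(modulus = ecc, argument = ang)
  } else {
    if (is.null(region)) stop("region labels are required for coords = 'ecc_extang'")
    f0 <- complex(real = ecc, imaginary = extend_polar(ang, region, hemi))
  }
  if (is.null(weights)) weights <- if (is.null(r2)) 1 else pmax(r2, 0) / 100
  fit <- qc_smooth(param, faces, f0, boundary_values = boundary_values,
                   s = s, weights = weights, eps_proj = eps_proj,
                   eps_boundary = eps_boundary, max_iter = max_iter,
                   collar_dist = collar_dist, ...)
  out <- switch(coords,
    raw = list(),
    cartesian = list(ecc = Mod(fit$f), ang = Arg(fit$f) %% (2 * pi)),
    ecc_extang = {
      dec <- invert_extended_polar(Im(fit$f), hemi)
      list(ecc = Re(fit$f), ang = dec$ang, region = dec$region,
           ext_ang = Im(fit$f))
    })
  structure(c(list(call = cl, param = param, faces = faces, input = f0,
                   f = fit$f, fit = fit, coords = coords, hemi = hemi,
                   weights = weights,
                   flips_before = count_flipped(param, f0, faces)$count,
                   flips_after = count_flipped(param, fit$f, faces)$count),
              out),
            class = "topo_smooth")
}

#' @export
print.topo_smooth <- function(x, ...) {
  cat("Topology-preserving retinotopic map smoother\n")
  cat(sprintf("  %d vertices, %d faces, coding: %s\n",
              length(x$param), nrow(x$faces), x$coords))
  cat(sprintf("  converged in %d iteration(s); flipped faces %d -> %d; final max|mu| = %.4f\n",
              x$fit$iterations, x$flips_before, x$flips_after,
              x$fit$trace[length(x$fit$trace)]))
  invisible(x)
}

#' @export
summary.topo_smooth <- function(object, ...) {
  ch <- Mod(object$f - object$input)
  ad <- angle_distortion(object$param, object$f, object$faces)
  structure(list(fit = object, mean_change = mean(ch), max_change = max(ch),
                 angle_mean = ad$mean, trace = object$fit$trace,
                 flip_trace = object$fit$flip_trace),
            class = "summary.topo_smooth")
}

#' @export
print.summary.topo_smooth <- function(x, ...) {
  print(x$fit)
  cat(sprintf("  mean|change| = %.4g, max|change| = %.4g, angle distortion %.2f deg\n",
              x$mean_change, x$max_change, x$angle_mean))
  cat("  max|mu| trace:", paste(sprintf("%.3g", x$trace), collapse = " "), "\n")
  invisible(x)
}

#' Smoothed coordinates of a fitted map
#'
#' @param object a \code{topo_smooth} fit.
#' @param ... unused.
#' @return two-column matrix of the smoothed coordinates in the fitting
#'   coding (plus decoded columns where applicable).
#' @export
coef.topo_smooth <- function(object, ...) {
  switch(object$coords,
    raw = cbind(f1 = Re(object$f), f2 = Im(object$f)),
    cartesian = cbind(ecc = object$ecc, ang = object$ang),
    ecc_extang = cbind(ecc = object$ecc, ang = object$ang,
                       ext_ang = object$ext_ang))
}

#' @export
fitted.topo_smooth <- function(object, ...) object$f

#' @export
residuals.topo_smooth <- function(object, ...) object$input - object$f

#' Plot a smoothed retinotopic map
#'
#' Draws the mapped triangulation before (left) and after (right)
#' smoothing, shading flipped faces.
#'
#' @param x a \code{topo_smooth} fit.
#' @param ... graphical parameters passed on.
#' @export
plot.topo_smooth <- function(x, ...) {
  op <- graphics::par(mfrow = c(1, 2), mar = c(2, 2, 2, 1))
  on.exit(graphics::par(op))
  draw_map <- function(f, main) {
    fl <- count_flipped(x$param, f, x$faces)$flipped
    plot(Re(f), Im(f), type = "n", asp = 1, main = main, xlab = "", ylab = "", ...)
    xs <- matrix(Re(f)[t(x$faces[, c(1, 2, 3, 1)])], nrow = 4)
    ys <- matrix(Im(f)[t(x$faces[, c(1, 2, 3, 1)])], nrow = 4)
    cols <- ifelse(fl, grDevices::adjustcolor("firebrick", 0.6), NA)
    for (k in seq_len(ncol(xs)))
      graphics::polygon(xs[, k], ys[, k], border = "grey40", col = cols[k], lwd = 0.4)
  }
  draw_map(x$input, sprintf("raw (%d flips)", x$flips_before))
  draw_map(x$f, sprintf("smoothed (%d flips)", x$flips_after))
  invisible(x)
}
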