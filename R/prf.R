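#' Canonical double-gamma hemodynamic response function
#'
#' Difference of two gamma densities (response peak near 6 s, undershoot
#' near 16 s, undershoot ratio 1/6), scaled to unit peak.
#'
#' @param t time points in seconds.
#' @param peak,undershoot gamma shape parameters (scale 1 s).
#' @param ratio undershoot amplitude ratio.
#' @return numeric vector of HRF values.
#' @export
hrf_double_gamma <- function(t, peak = 6, undershoot = 16, ratio = 1 / 6) {
  h <- stats::dgamma(t, shape = peak, scale = 1) -
       ratio * stats::dgamma(t, shape = undershoot, scale = 1)
  h / max(h)
}

#' Binary aperture stimulus movies
#'
#' Emulates the standard retinotopic mapping stimuli on a square pixel
#' grid covering \eqn{[-fov, fov]^2} degrees: a rotating wedge (90 degree
#' width), an expanding ring (thickness \eqn{fov/4}), sweeping bars
#' (width \eqn{fov/4}, four orientations), their concatenation
#' (\code{"standard"}, equal thirds), or a constant full-field aperture.
#' The standard schedule covers the full stimulated disk.
#'
#' @param kind aperture type.
#' @param resolution pixels per side.
#' @param fov half-width of the stimulated field, degrees.
#' @param duration total duration in seconds.
#' @param frame_interval seconds per frame; must divide \code{duration}.
#' @param n_cycles sweep/rotation cycles per segment.
#' @return object of class \code{stimulus_movie}: list with \code{frames}
#'   (T x npixel 0/1 matrix), pixel coordinates \code{x}, \code{y}
#'   (degrees), \code{times}, \code{fov}, \code{resolution}.
#' @export
make_stimulus <- function(kind = c("standard", "wedge", "ring", "bar", "full"),
                          resolution = 200, fov = 8, duration = 300,
                          frame_interval = 1, n_cycles = 2) {
  kind <- match.arg(kind)
  if (abs(duration %% frame_interval) > 1e-9)
    stop("duration must be divisible by frame_interval")
  nt <- as.integer(round(duration / frame_interval))
  px <- seq(-fov, fov, length.out = resolution)
  gx <- rep(px, times = resolution)
  gy <- rep(px, each = resolution)
  r <- sqrt(gx^2 + gy^2)
  th <- atan2(gy, gx) %% (2 * pi)
  indisk <- r <= fov

  seg_frames <- function(type, nseg) {
    f <- matrix(0, nseg, length(gx))
    for (t in seq_len(nseg)) {
      ph <- n_cycles * (t - 1) / nseg            # phase in [0, n_cycles)
      frac <- ph %% 1
      on <- switch(type,
        wedge = {
          a0 <- 2 * pi * frac
          dd <- (th - a0) %% (2 * pi)
          indisk & dd <= pi / 2
        },
        ring = {
          r0 <- frac * fov
          indisk & r >= r0 & r <= r0 + fov / 4
        },
        bar = {
          ori <- (floor(ph) %% 4) * pi / 4       # 0, 45, 90, 135 degrees
          off <- (2 * frac - 1) * fov
          dd <- gx * cos(ori) + gy * sin(ori)
          indisk & abs(dd - off) <= fov / 8
        },
        full = indisk)
      f[t, on] <- 1
    }
    f
  }
  frames <- switch(kind,
    full = seg_frames("full", nt),
    wedge = seg_frames("wedge", nt),
    ring = seg_frames("ring", nt),
    bar = seg_frames("bar", nt),
    standard = {
      n3 <- nt %/% 3
      rbind(seg_frames("wedge", n3), seg_frames("ring", n3),
            seg_frames("bar", nt - 2 * n3))
    })
  structure(list(frames = frames, x = gx, y = gy,
                 times = seq_len(nt) * frame_interval, fov = fov,
                 resolution = resolution, frame_interval = frame_interval),
            class = "stimulus_movie")
}

#' @export
print.stimulus_movie <- function(x, ...) {
  cat(sprintf("stimulus_movie: %d frames, %dx%d pixels over [-%g, %g] deg\n",
              nrow(x$frames), x$resolution, x$resolution, x$fov, x$fov))
  invisible(x)
}

#' Fraction of the stimulated disk covered by the union of all frames
#'
#' @param stim a \code{stimulus_movie}.
#' @return fraction in [0, 1].
#' @export
stimulus_coverage <- function(stim) {
  indisk <- sqrt(stim$x^2 + stim$y^2) <= stim$fov
  covered <- colSums(stim$frames) > 0
  sum(covered & indisk) / sum(indisk)
}

# Gaussian pRF evaluated on the stimulus pixel grid (npixel vector)
prf_field <- function(stim, x0, y0, sigma) {
  exp(-((stim$x - x0)^2 + (stim$y - y0)^2) / (2 * sigma^2))
}

# neural drive -> BOLD prediction for given drive time course
drive_to_bold <- function(drive, expt, hrf) {
  y <- drive^expt
  stats::convolve(y, rev(hrf), type = "open")[seq_along(y)]
}

#' Simulate pRF fMRI time series
#'
#' Predicted BOLD signal of a voxel with an isotropic Gaussian population
#' receptive field: \eqn{y = \beta\,(\int r(v'; v, \sigma)\,s(t, v')\,dv')^n * h(t)},
#' i.e. the stimulus-aperture overlap with the Gaussian field, raised to
#' the compressive exponent and convolved with the HRF. The noiseless
#' signal is normalized to unit variance before white Gaussian noise of sd
#' \code{noise_sd} is added.
#'
#' @param params data.frame (or list) with columns \code{x}, \code{y}
#'   (pRF center, degrees), \code{sigma} (size, degrees), \code{gain},
#'   \code{expt} (compressive exponent); one row per voxel.
#' @param stim a \code{stimulus_movie}.
#' @param hrf HRF values sampled at the frame interval (default:
#'   [hrf_double_gamma()] over 0-32 s).
#' @param noise_sd white-noise sd, in units of the unit-variance signal.
#' @param seed RNG seed for the noise.
#' @return T x nvoxel matrix of signals; attribute \code{"clean"} carries
#'   the noiseless (normalized) signals.
#' @export
simulate_prf_signal <- function(params, stim, hrf = NULL, noise_sd = 0,
                                seed = 1) {
  params <- as.data.frame(params)
  if (any(params$sigma <= 0)) stop("sigma must be positive")
  if (is.null(hrf))
    hrf <- hrf_double_gamma(seq(0, 32, by = stim$frame_interval))
  covered <- colSums(stim$frames) > 0
  nt <- nrow(stim$frames)
  Y <- matrix(0, nt, nrow(params))
  uncov <- 0L
  for (i in seq_len(nrow(params))) {
    rf <- prf_field(stim, params$x[i], params$y[i], params$sigma[i])
    if (sum(rf[covered]) / sum(rf) < 1e-6) uncov <- uncov + 1L
    drive <- as.numeric(stim$frames %*% rf)
    Y[, i] <- params$gain[i] * drive_to_bold(drive, params$expt[i], hrf)
  }
  if (uncov > 0L)
    warning(uncov, " pRF center(s) receive (near-)zero stimulus coverage")
  sds <- apply(Y, 2, stats::sd)
  pos <- sds > 0
  Y[, pos] <- sweep(Y[, pos, drop = FALSE], 2, sds[pos], "/")
  clean <- Y
  if (noise_sd > 0) {
    withr_seed(seed)
    Y <- Y + matrix(stats::rnorm(length(Y), 0, noise_sd), nt)
  }
  attr(Y, "clean") <- clean
  Y
}

#' Decode pRF parameters from fMRI time series
#'
#' Grid search over candidate centers, sizes and exponents against a
#' precomputed prediction dictionary (gain by closed-form least squares),
#' optionally followed by Nelder-Mead refinement of center and size.
#' The fit quality is \eqn{R^2 = 100\,(1 - \int(\hat y - y)^2 dt / \int y^2 dt)}.
#' Voxels whose refinement fails keep the grid solution; a voxel whose
#' dictionary scores are all degenerate is flagged with \code{r2 = -Inf}.
#'
#' @param y signal matrix (T x nvoxel) or vector.
#' @param stim a \code{stimulus_movie}.
#' @param hrf HRF values (default as in [simulate_prf_signal()]).
#' @param centers candidate center matrix (2 columns, degrees); default a
#'   \code{center_step}-spaced grid over the stimulated square.
#' @param center_step spacing of the default candidate grid.
#' @param sigma_grid,expt_grid candidate sizes and exponents.
#' @param refine logical: run per-voxel continuous refinement of
#'   (x, y, sigma)?
#' @param chunk dictionary chunk size (columns) to bound memory.
#' @return data.frame with one row per voxel:
#'   \code{x, y, sigma, gain, expt, r2}.
#' @export
fit_prf <- function(y, stim, hrf = NULL, centers = NULL, center_step = 0.5,
                    sigma_grid = c(0.2, 0.4, 0.8), expt_grid = c(0.5, 1),
                    refine = TRUE, chunk = 4000) {
  Y <- if (is.matrix(y)) y else matrix(y, ncol = 1)
  if (!all(is.finite(Y))) stop("non-finite values in the signal")
  if (nrow(Y) != nrow(stim$frames)) stop("signal length does not match the stimulus")
  if (is.null(hrf))
    hrf <- hrf_double_gamma(seq(0, 32, by = stim$frame_interval))
  if (is.null(centers)) {
    cs <- seq(-stim$fov, stim$fov, by = center_step)
    centers <- as.matrix(expand.grid(x = cs, y = cs))
  }
  cand <- as.matrix(expand.grid(ci = seq_len(nrow(centers)),
                                si = seq_along(sigma_grid),
                                ni = seq_along(expt_grid)))
  K <- nrow(cand); V <- ncol(Y)
  best_score <- rep(-Inf, V); best_k <- rep(NA_integer_, V); best_beta <- numeric(V)
  yss <- colSums(Y^2)
  for (start in seq(1, K, by = chunk)) {
    idx <- start:min(start + chunk - 1, K)
    D <- prediction_dictionary(stim, hrf, centers[cand[idx, 1], , drop = FALSE],
                               sigma_grid[cand[idx, 2]], expt_grid[cand[idx, 3]])
    dn <- colSums(D^2)
    ok <- dn > 0
    Ct <- crossprod(D, Y)                        # K' x V
    sc <- Ct^2 / ifelse(dn > 0, dn, Inf)         # residual reduction
    kbest <- max.col(t(sc), ties.method = "first")
    better <- sc[cbind(kbest, seq_len(V))] > best_score & ok[kbest]
    best_score[better] <- sc[cbind(kbest, seq_len(V))][better]
    best_k[better] <- idx[kbest[better]]
    best_beta[better] <- (Ct[cbind(kbest, seq_len(V))] / dn[kbest])[better]
  }
  failed <- !is.finite(best_score) | is.na(best_k) | yss == 0
  best_k[failed] <- 1L
  out <- data.frame(x = centers[cand[best_k, 1], 1],
                    y = centers[cand[best_k, 1], 2],
                    sigma = sigma_grid[cand[best_k, 2]],
                    gain = best_beta,
                    expt = expt_grid[cand[best_k, 3]],
                    r2 = 100 * best_score / yss)
  if (refine) {
    for (v in seq_len(V)) {
      if (failed[v]) next
      obj <- function(p) {
        sg <- exp(p[3])
        d <- drive_to_bold(as.numeric(stim$frames %*% prf_field(stim, p[1], p[2], sg)),
                           out$expt[v], hrf)
        dn <- sum(d^2)
        if (dn <= 0) return(0)
        -sum(d * Y[, v])^2 / dn
      }
      res <- tryCatch(
        stats::optim(c(out$x[v], out$y[v], log(out$sigma[v])), obj,
                     method = "Nelder-Mead",
                     control = list(maxit = 200, reltol = 1e-6)),
        error = function(e) NULL)
      if (!is.null(res) && -res$value >= best_score[v]) {
        d <- drive_to_bold(as.numeric(
          stim$frames %*% prf_field(stim, res$par[1], res$par[2], exp(res$par[3]))),
          out$expt[v], hrf)
        out$x[v] <- res$par[1]; out$y[v] <- res$par[2]
        out$sigma[v] <- exp(res$par[3])
        out$gain[v] <- sum(d * Y[, v]) / sum(d^2)
        out$r2[v] <- 100 * (-res$value) / yss[v]
      }
    }
  }
  out$r2[failed] <- -Inf
  out
}

# HRF-convolved predicted responses for a batch of candidate pRFs
prediction_dictionary <- function(stim, hrf, centers, sigmas, expts) {
  k <- nrow(centers)
  RF <- matrix(0, length(stim$x), k)
  for (j in seq_len(k))
    RF[, j] <- prf_field(stim, centers[j, 1], centers[j, 2], sigmas[j])
  drive <- stim$frames %*% RF
  D <- matrix(0, nrow(drive), k)
  for (j in seq_len(k)) D[, j] <- drive_to_bold(drive[, j], expts[j], hrf)
  D
}
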