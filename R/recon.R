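# Minimal spiral reconstruction: density-compensated Kaiser-Bessel gridding
# with view sharing, plus the noise-ratio metric.

fftshift2 <- function(m) {
  n1 <- nrow(m); n2 <- ncol(m)
  m[c((n1 / 2 + 1):n1, 1:(n1 / 2)), c((n2 / 2 + 1):n2, 1:(n2 / 2))]
}

# Kaiser-Bessel kernel (width W in oversampled grid units) and its analytic
# image-domain transform, used for deapodization.
kb_kernel <- function(d, W, beta) {
  u <- 2 * d / W
  out <- numeric(length(d))
  ok <- abs(u) <= 1
  out[ok] <- besselI(beta * sqrt(1 - u[ok]^2), 0) / besselI(beta, 0)
  out
}

kb_apod <- function(x, W, beta, G2) {
  z2 <- (pi * W * x / G2)^2 - beta^2
  out <- numeric(length(z2))
  pos <- z2 > 0
  out[pos] <- sin(sqrt(z2[pos])) / sqrt(z2[pos])
  out[!pos] <- sinh(sqrt(-z2[!pos])) / pmax(sqrt(-z2[!pos]), 1e-12)
  out[abs(z2) < 1e-12] <- 1
  out
}

#' Density-compensated gridding reconstruction
#'
#' Adjoint gridding with a Kaiser-Bessel interpolation kernel on a 2x
#' oversampled grid, deapodization by the kernel's analytic transform, and
#' root-sum-of-squares combination over imaging coils. Density compensation
#' uses |k| ramp weights, which match the simulator's linear-radius spiral.
#'
#' @param acq A `haptic_acq` with a trajectory.
#' @param lines Line indices to reconstruct (default: all).
#' @param grid Output matrix size.
#' @param osf Grid oversampling factor.
#' @param kernel_width Kernel width in oversampled grid units.
#' @return A `haptic_frame`: `pixels` (non-negative magnitude matrix),
#'   `frame_time`, `grid`.
#' @export
grid_recon <- function(acq, lines = seq_len(n_lines(acq)), grid = 64L,
                       osf = 2, kernel_width = 4L) {
  if (length(lines) == 0) stopf("empty line subset")
  if (is.null(acq$trajectory)) stopf("acquisition has no trajectory")
  kx <- as.vector(acq$trajectory[lines, , 1])
  ky <- as.vector(acq$trajectory[lines, , 2])
  kmax <- max(sqrt(kx^2 + ky^2))
  if (kmax > grid / 2 + 1e-9)
    stopf("trajectory max |k| (%.3g) exceeds the grid Nyquist (%.3g)", kmax,
          grid / 2)
  G2 <- as.integer(round(osf * grid))
  W <- kernel_width
  beta <- pi * sqrt((W / osf)^2 * (osf - 0.5)^2 - 0.8)

  kr <- sqrt(kx^2 + ky^2)
  kmin <- min(kr[kr > 0])
  dcf <- pmax(kr, kmin / 2)

  ux <- kx * osf + G2 / 2 + 1
  uy <- ky * osf + G2 / 2 + 1
  offs <- seq(-ceiling(W / 2), ceiling(W / 2))
  ii <- imaging_idx(acq)
  combined <- matrix(0, grid, grid)
  imgs <- vector("list", length(ii))
  for (jc in seq_along(ii)) {
    val <- as.vector(acq$samples[lines, ii[jc], ]) * dcf
    gre <- matrix(0, G2, G2); gim <- matrix(0, G2, G2)
    for (dx in offs) {
      gxi <- floor(ux) + dx
      wx <- kb_kernel(gxi - ux, W, beta)
      okx <- gxi >= 1 & gxi <= G2 & wx > 0
      if (!any(okx)) next
      for (dy in offs) {
        gyi <- floor(uy) + dy
        wy <- kb_kernel(gyi - uy, W, beta)
        ok <- okx & gyi >= 1 & gyi <= G2 & wy > 0
        if (!any(ok)) next
        w <- wx[ok] * wy[ok]
        idx <- gxi[ok] + (gyi[ok] - 1) * G2
        v <- val[ok] * w
        acc_re <- Matrix::sparseMatrix(i = idx, j = rep(1L, length(idx)),
                                       x = Re(v), dims = c(G2 * G2, 1))
        acc_im <- Matrix::sparseMatrix(i = idx, j = rep(1L, length(idx)),
                                       x = Im(v), dims = c(G2 * G2, 1))
        gre <- gre + matrix(as.vector(acc_re), G2, G2)
        gim <- gim + matrix(as.vector(acc_im), G2, G2)
      }
    }
    gk <- matrix(complex(real = gre, imaginary = gim), G2, G2)
    img_os <- fftshift2(stats::fft(fftshift2(gk), inverse = TRUE)) / (G2 * G2)
    ctr <- (G2 - grid) / 2
    img <- img_os[(ctr + 1):(ctr + grid), (ctr + 1):(ctr + grid)]
    x <- (seq_len(grid) - 1 - grid / 2)
    apod <- kb_apod(x, W, beta, G2)
    img <- img / outer(apod, apod)
    imgs[[jc]] <- img
    combined <- combined + Mod(img)^2
  }
  structure(list(pixels = sqrt(combined),
                 coil_images = imgs,
                 frame_time = stats::median(acq$line_time[lines]),
                 grid = grid), class = "haptic_frame")
}

#' View-sharing frame sequence
#'
#' Frame `j` reconstructs the `footprint_arms` lines starting at
#' `(j - 1) * frame_stride_arms + 1`; its timestamp is the center line time.
#' At TR = 5.32 ms the default 17/55 arms correspond to 90.4 / 292.6 ms.
#'
#' @param acq A `haptic_acq`.
#' @param frame_stride_arms Arms between frame starts.
#' @param footprint_arms Arms per frame (temporal footprint).
#' @param ... Passed to [grid_recon()].
#' @return List of `haptic_frame` objects.
#' @export
view_share_frames <- function(acq, frame_stride_arms = 17L,
                              footprint_arms = 55L, ...) {
  L <- n_lines(acq)
  if (L < footprint_arms)
    stopf("need at least %d lines for one frame, have %d", footprint_arms, L)
  if (frame_stride_arms > footprint_arms)
    warnf("frame stride exceeds the footprint; frames will leave gaps")
  n_frames <- (L - footprint_arms) %/% frame_stride_arms + 1L
  lapply(seq_len(n_frames), function(j) {
    start <- (j - 1L) * frame_stride_arms + 1L
    grid_recon(acq, lines = start:(start + footprint_arms - 1L), ...)
  })
}

#' Noise ratio between two noise-only reconstructions
#'
#' Standard deviation of the magnitude pixels inside a centered circular
#' region of interest, for a test image divided by a reference image
#' reconstructed with no pilot-tone transmission.
#'
#' @param img_test,img_ref `haptic_frame` objects (or plain matrices) on the
#'   same grid.
#' @param roi_diameter_frac ROI diameter as a fraction of the FOV (default
#'   0.53, a 16 cm circle on a 30 cm FOV analog).
#' @return A `haptic_noise_ratio` list: `sd_test`, `sd_ref`, `ratio`,
#'   `n_roi_pixels`.
#' @export
noise_ratio <- function(img_test, img_ref, roi_diameter_frac = 0.53) {
  px_t <- if (inherits(img_test, "haptic_frame")) img_test$pixels else img_test
  px_r <- if (inherits(img_ref, "haptic_frame")) img_ref$pixels else img_ref
  if (!all(dim(px_t) == dim(px_r)))
    stopf("test and reference images must share the same grid")
  g <- nrow(px_t)
  if (roi_diameter_frac <= 0 || roi_diameter_frac > 1)
    stopf("ROI diameter fraction must be in (0, 1]")
  x <- (seq_len(g) - 1 - g / 2) / g
  r2 <- outer(x, x, function(u, v) u^2 + v^2)
  roi <- r2 <= (roi_diameter_frac / 2)^2
  sd_t <- stats::sd(px_t[roi]); sd_r <- stats::sd(px_r[roi])
  structure(list(sd_test = sd_t, sd_ref = sd_r, ratio = sd_t / sd_r,
                 n_roi_pixels = sum(roi)), class = "haptic_noise_ratio")
}
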