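# Separable Gaussian smoothing of a 3D array. sigma_vox in voxel units per
# axis (z, y, x); edges handled by replication. Kernel truncated at 3 sigma.
gauss_smooth3 <- function(arr, sigma_vox) {
  out <- arr
  for (ax in 1:3) {
    s <- sigma_vox[ax]
    if (s <= 0) next
    h <- max(1L, ceiling(3 * s))
    k <- exp(-((-h):h)^2 / (2 * s^2))
    k <- k / sum(k)
    n <- dim(out)[ax]
    acc <- array(0, dim(out))
    for (j in (-h):h) {
      idx <- pmin(pmax(seq_len(n) + j, 1L), n)
      shifted <- switch(ax,
                        out[idx, , , drop = FALSE],
                        out[, idx, , drop = FALSE],
                        out[, , idx, drop = FALSE])
      acc <- acc + k[j + h + 1] * shifted
    }
    out <- acc
  }
  out
}

# Logical array marking strict local maxima over the 26-neighborhood.
local_maxima3 <- function(arr) {
  d <- dim(arr)
  res <- array(TRUE, d)
  for (dz in -1:1) for (dy in -1:1) for (dx in -1:1) {
    if (dz == 0 && dy == 0 && dx == 0) next
    iz <- pmin(pmax(seq_len(d[1]) + dz, 1L), d[1])
    iy <- pmin(pmax(seq_len(d[2]) + dy, 1L), d[2])
    ix <- pmin(pmax(seq_len(d[3]) + dx, 1L), d[3])
    res <- res & (arr >= arr[iz, iy, ix])
  }
  res
}

#' Detect the locus focus in a stack
#'
#' Multiscale blob detection: difference-of-Gaussians responses at scales
#' bracketing the configured PSF (0.8x, 1x, 1.25x), maximum response over
#' scales, candidate peaks as 26-neighborhood local maxima above a robust
#' threshold (median + `threshold_sd` * MAD of the response). The brightest
#' candidate wins; its position is refined to subvoxel precision by an
#' intensity-weighted centroid over the background-subtracted 3x3x3 voxel
#' neighborhood, reported in physical um (voxel-center convention).
#'
#' If no candidate passes the threshold the detection is returned with
#' `found = FALSE` and qc flag `no_focus`; no position is fabricated.
#'
#' @param stack a `nucperi_stack`.
#' @param channel channel to search (default `"locus"`).
#' @param psf_sigma expected PSF sigmas (z, y, x) um.
#' @param threshold_sd robust detection threshold in MAD units (default 5).
#' @return list of class `nucperi_focus`: `found`, `position` (z, y, x um
#'   or NA), `peak_intensity`, `quality` in \[0, 1\] (monotone in peak SNR),
#'   `n_candidates`, `qc`.
#' @export
detect_focus <- function(stack, channel = "locus",
                         psf_sigma = c(0.35, 0.13, 0.13),
                         threshold_sd = 5) {
  img <- stack$channels[[channel]]
  if (is.null(img)) stop("stack has no '", channel, "' channel")
  pitch <- stack$voxel_pitch
  resp <- NULL
  for (f in c(0.8, 1, 1.25)) {
    sv <- f * psf_sigma / pitch
    dog <- gauss_smooth3(img, sv) - gauss_smooth3(img, 1.6 * sv)
    resp <- if (is.null(resp)) dog else pmax(resp, dog)
  }
  med <- stats::median(resp)
  sdr <- stats::mad(resp)
  if (sdr < 1e-12) sdr <- stats::sd(resp)
  if (!is.finite(sdr) || sdr < 1e-12) {
    return(no_focus_result())
  }
  thr <- med + threshold_sd * sdr
  cand <- which(local_maxima3(resp) & resp > thr)
  if (length(cand) == 0) return(no_focus_result())
  d <- dim(img)
  ci <- arrayInd(cand, d)
  # merge candidates within 2 detection sigmas of a stronger one
  ord <- order(resp[cand], decreasing = TRUE)
  ci <- ci[ord, , drop = FALSE]
  cand <- cand[ord]
  min_sep <- pmax(1, 2 * psf_sigma / pitch)
  keep <- rep(TRUE, nrow(ci))
  for (i in seq_len(nrow(ci))[-1]) {
    for (j in seq_len(i - 1)) {
      if (keep[j] && all(abs(ci[i, ] - ci[j, ]) <= min_sep)) {
        keep[i] <- FALSE
        break
      }
    }
  }
  ci <- ci[keep, , drop = FALSE]
  best <- ci[1, ]
  # subvoxel refinement: weighted centroid of the raw 3x3x3 neighborhood
  bg <- stats::median(img)
  iz <- pmin(pmax(best[1] + (-1:1), 1L), d[1])
  iy <- pmin(pmax(best[2] + (-1:1), 1L), d[2])
  ix <- pmin(pmax(best[3] + (-1:1), 1L), d[3])
  nb <- pmax(img[iz, iy, ix] - bg, 0)
  tw <- sum(nb)
  pos_vox <- if (tw > 0) {
    c(sum(nb * array(rep(iz, 9), c(3, 3, 3))),
      sum(nb * array(rep(rep(iy, each = 3), 3), c(3, 3, 3))),
      sum(nb * array(rep(ix, each = 9), c(3, 3, 3)))) / tw
  } else {
    as.numeric(best)
  }
  peak <- img[best[1], best[2], best[3]]
  snr <- (peak - bg) / max(1.4826 * stats::mad(img), 1e-9)
  structure(list(found = TRUE,
                 position = (pos_vox - 0.5) * pitch,
                 peak_intensity = peak,
                 quality = snr / (snr + 5),
                 n_candidates = nrow(ci),
                 qc = character(0)),
            class = "nucperi_focus")
}

no_focus_result <- function() {
  structure(list(found = FALSE, position = rep(NA_real_, 3),
                 peak_intensity = NA_real_, quality = 0,
                 n_candidates = 0L, qc = "no_focus"),
            class = "nucperi_focus")
}

#' @export
print.nucperi_focus <- function(x, ...) {
  if (x$found) {
    cat(sprintf("focus at (%.3f, %.3f, %.3f) um; peak %.1f, quality %.2f, %d candidate(s)\n",
                x$position[1], x$position[2], x$position[3],
                x$peak_intensity, x$quality, x$n_candidates))
  } else {
    cat("no focus found\n")
  }
  invisible(x)
}
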