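#' Shortest 3D distance from a focus to the nuclear periphery
#'
#' Minimal Euclidean distance from the detected focus position to the
#' fitted envelope surface (the shell ridge mid-line), computed on the
#' analytic ellipsoid path ([point_ellipsoid_distance()]). Foci numerically
#' outside the fitted surface return 0 with qc flag
#' `focus_outside_surface` rather than being dropped, so QC is auditable.
#'
#' @param focus a `nucperi_focus` (or numeric (z, y, x) position in um).
#' @param surface a `nucperi_surface` (or list with `center`, `semiaxes`,
#'   `rotation`).
#' @return list: `distance_um` (>= 0), `inside`, `qc` (character vector).
#' @export
distance_to_periphery_3d <- function(focus, surface) {
  pos <- if (inherits(focus, "nucperi_focus")) {
    if (!focus$found) stop("no focus found: cannot measure a distance")
    focus$position
  } else {
    as.numeric(focus)
  }
  rot <- surface$rotation %||% diag(3)
  d <- point_ellipsoid_distance(pos, surface$center, surface$semiaxes, rot)
  qc <- character(0)
  if (!d$inside) qc <- "focus_outside_surface"
  list(distance_um = d$distance, inside = d$inside, qc = qc)
}

#' Shortest 2D middle-section distance from a focus to the periphery
#'
#' The study's 2D mode for regular-shaped nuclei: a maximum-intensity
#' projection of the `k_mid` middle z-slices of the envelope channel, a 2D
#' rim contour extracted by the same radial ridge detection as in 3D, and
#' the in-plane shortest distance from the projected focus to the contour
#' polyline.
#'
#' @param stack a `nucperi_stack`.
#' @param focus a `nucperi_focus` or numeric (z, y, x) um.
#' @param surface optional `nucperi_surface`; its center seeds the ray
#'   origin (otherwise a 2D intensity centroid is used).
#' @param k_mid number of middle sections to project (default 3, the
#'   "two to four middle sections" display convention).
#' @param n_theta contour rays (default 48).
#' @param min_peak_frac minimum ridge prominence as in [segment_envelope()].
#' @return list: `distance_um`, `inside` (focus inside the contour
#'   polygon), `qc`, `contour` (n x 2 matrix, (y, x) um).
#' @export
distance_to_periphery_2d <- function(stack, focus, surface = NULL,
                                     k_mid = 3, n_theta = 48,
                                     min_peak_frac = 0.5) {
  img <- stack$channels$envelope
  d <- dim(img)
  if (k_mid > d[1]) {
    stop("k_mid (", k_mid, ") exceeds the number of z-sections (", d[1], ")")
  }
  if (k_mid < 1) stop("k_mid must be >= 1")
  pos <- if (inherits(focus, "nucperi_focus")) {
    if (!focus$found) stop("no focus found: cannot measure a distance")
    focus$position
  } else {
    as.numeric(focus)
  }
  pitch <- stack$voxel_pitch
  mid <- round(d[1] / 2 + 0.5)
  half <- (k_mid - 1) %/% 2
  ks <- seq(mid - half, length.out = k_mid)
  ks <- ks[ks >= 1 & ks <= d[1]]
  proj <- apply(img[ks, , , drop = FALSE], c(2, 3), max)
  bg <- stats::median(proj)
  w <- pmax(proj - bg, 0)
  yc <- axis_coords(d[2], pitch[2])
  xc <- axis_coords(d[3], pitch[3])
  ctr <- if (!is.null(surface)) {
    surface$center[2:3]
  } else {
    c(sum(apply(w, 1, sum) * yc), sum(apply(w, 2, sum) * xc)) / sum(w)
  }
  robust_max <- stats::quantile(proj, 0.999, names = FALSE)
  if (robust_max - bg <= 0) poor_fit_stop("projected envelope is flat")
  theta <- seq(0, 2 * pi, length.out = n_theta + 1)[-(n_theta + 1)]
  step <- min(pitch[2], pitch[3]) / 2
  r_max <- sqrt((d[2] * pitch[2])^2 + (d[3] * pitch[3])^2) / 2
  r_grid <- seq(step, r_max, by = step)
  contour <- matrix(NA_real_, nrow = n_theta, ncol = 2)
  for (i in seq_along(theta)) {
    th <- theta[i]
    ys <- ctr[1] + r_grid * sin(th)
    xs <- ctr[2] + r_grid * cos(th)
    v <- bilinear(proj, ys / pitch[2] + 0.5, xs / pitch[3] + 0.5)
    ok <- !is.na(v)
    if (!any(ok)) next
    vi <- v[ok]; ri <- r_grid[ok]
    j <- which.max(vi)
    if (vi[j] - bg < min_peak_frac * (robust_max - bg)) next
    r_peak <- ri[j]
    if (j > 1 && j < length(vi)) {
      den <- vi[j - 1] - 2 * vi[j] + vi[j + 1]
      if (den < 0) r_peak <- ri[j] + 0.5 * step * (vi[j - 1] - vi[j + 1]) / den
    }
    contour[i, ] <- ctr + r_peak * c(sin(th), cos(th))
  }
  qc <- character(0)
  good <- stats::complete.cases(contour)
  if (sum(good) < n_theta * 0.75) {
    poor_fit_stop("2D contour is not closed (too many missing rays)")
  }
  if (any(!good)) qc <- c(qc, "partial_contour")
  contour <- contour[good, , drop = FALSE]
  p <- pos[2:3]
  dist <- point_polyline_distance(p, rbind(contour, contour[1, ]))
  inside <- point_in_polygon(p, contour)
  if (!inside) {
    qc <- c(qc, "focus_outside_surface")
    # convention matches 3D mode: outside-contour foci clip to 0
    dist <- 0
  }
  list(distance_um = dist, inside = inside, qc = qc, contour = contour)
}

# Minimum distance from a 2D point to a polyline given as an n x 2 matrix.
point_polyline_distance <- function(p, poly) {
  a <- poly[-nrow(poly), , drop = FALSE]
  b <- poly[-1, , drop = FALSE]
  ab <- b - a
  ap <- cbind(p[1] - a[, 1], p[2] - a[, 2])
  len2 <- rowSums(ab^2)
  t <- pmin(pmax(ifelse(len2 > 0, rowSums(ap * ab) / len2, 0), 0), 1)
  proj <- a + ab * t
  sqrt(min((p[1] - proj[, 1])^2 + (p[2] - proj[, 2])^2))
}

# Ray-crossing point-in-polygon test (polygon rows ordered by angle).
point_in_polygon <- function(p, poly) {
  n <- nrow(poly)
  j <- n
  inside <- FALSE
  for (i in seq_len(n)) {
    yi <- poly[i, 1]; xi <- poly[i, 2]
    yj <- poly[j, 1]; xj <- poly[j, 2]
    if ((yi > p[1]) != (yj > p[1]) &&
        p[2] < (xj - xi) * (p[1] - yi) / (yj - yi) + xi) {
      inside <- !inside
    }
    j <- i
  }
  inside
}

#' Measure focus-to-periphery distances for a dataset
#'
#' Batch form of the per-cell assay: reads every still entry of a manifest,
#' segments the envelope, detects the focus, and measures the distance in
#' the requested mode. Cells failing QC are included with flags set and NA
#' distance; rows are ordered by cell_id so reruns are deterministic.
#'
#' @param manifest a manifest list ([read_manifest()]) or path to one.
#' @param mode `"3d"` or `"2d"`.
#' @param k_mid middle sections for 2D mode.
#' @param psf_sigma PSF sigmas passed to [detect_focus()].
#' @param ... further arguments to [segment_envelope()].
#' @return data.frame of distance records: cell_id, condition, mode,
#'   distance_um, inside, qc_flags (semicolon-joined; empty = usable).
#' @export
measure_dataset <- function(manifest, mode = c("3d", "2d"), k_mid = 3,
                            psf_sigma = c(0.35, 0.13, 0.13), ...) {
  mode <- match.arg(mode)
  if (is.character(manifest)) manifest <- read_manifest(manifest)
  entries <- manifest$entries
  entries <- entries[order(vapply(entries, function(e) e$cell_id, ""))]
  rows <- lapply(entries, function(e) {
    rec <- data.frame(cell_id = e$cell_id,
                      condition = e$condition %||% NA_character_,
                      mode = mode, distance_um = NA_real_, inside = NA,
                      qc_flags = "", stringsAsFactors = FALSE)
    res <- tryCatch({
      stack <- read_stack(manifest$dir, e)
      surface <- segment_envelope(stack, ...)
      focus <- detect_focus(stack, psf_sigma = psf_sigma)
      if (!focus$found) {
        rec$qc_flags <- "no_focus"
        return(rec)
      }
      m <- if (mode == "3d") {
        distance_to_periphery_3d(focus, surface)
      } else {
        distance_to_periphery_2d(stack, focus, surface, k_mid = k_mid)
      }
      rec$distance_um <- m$distance_um
      rec$inside <- m$inside
      rec$qc_flags <- paste(m$qc, collapse = ";")
      rec
    },
    nucperi_poor_envelope_fit = function(e) {
      rec$qc_flags <- "poor_envelope_fit"
      rec
    },
    error = function(e) {
      rec$qc_flags <- paste0("error: ", conditionMessage(e))
      rec
    })
    res
  })
  do.call(rbind, rows)
}

#' Usable distances from a distance-record table
#'
#' QC-flagged cells are excluded from downstream statistics by default;
#' `focus_outside_surface` records (distance clipped to 0) are retained
#' unless `drop_outside = TRUE`.
#'
#' @param records data.frame from [measure_dataset()].
#' @param drop_outside also drop outside-surface records.
#' @return numeric vector of distances in um.
#' @export
usable_distances <- function(records, drop_outside = FALSE) {
  ok <- records$qc_flags == "" |
    (!drop_outside & records$qc_flags == "focus_outside_surface")
  records$distance_um[ok & !is.na(records$distance_um)]
}
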