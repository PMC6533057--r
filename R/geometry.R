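#' Shortest distance from an interior point to an ellipsoid surface
#'
#' Computes the minimal Euclidean distance from a point to the surface of an
#' ellipsoid given by center, semi-axes and rotation. The point is first
#' mapped into the ellipsoid's principal frame; the constrained minimization
#' is then solved via the Lagrange condition, whose stationary parameter is
#' bracketed and found by `uniroot` to a tolerance of 1e-12.
#'
#' Points numerically outside the surface return distance 0 with
#' `inside = FALSE` (callers flag these; the assay never reports negative
#' distances).
#'
#' @param point numeric length-3, physical coordinates (z, y, x) in um.
#' @param center numeric length-3, ellipsoid center (z, y, x) in um.
#' @param semiaxes numeric length-3, strictly positive semi-axes in um
#'   (matching the axis order of `rotation`'s columns).
#' @param rotation 3x3 rotation matrix mapping principal-frame coordinates to
#'   the physical frame (identity for axis-aligned ellipsoids).
#' @return list with `distance` (um, >= 0), `inside` (logical), and
#'   `closest` (the closest surface point, physical frame).
#' @export
point_ellipsoid_distance <- function(point, center, semiaxes,
                                     rotation = diag(3)) {
  stopifnot(length(point) == 3, length(center) == 3, length(semiaxes) == 3)
  if (any(!is.finite(semiaxes)) || any(semiaxes <= 0)) {
    stop("degenerate surface: semi-axes must be finite and positive")
  }
  # principal frame
  q <- drop(t(rotation) %*% (point - center))
  a <- as.numeric(semiaxes)
  m2 <- sum((q / a)^2)
  if (m2 >= 1) {
    # outside or on the surface: the assay clips to 0
    on_surface <- abs(sqrt(m2) - 1) < 1e-9
    closest <- center + drop(rotation %*% (q / max(sqrt(m2), 1)))
    return(list(distance = 0, inside = on_surface, closest = closest))
  }
  if (sum(q^2) < 1e-24) {
    # exact center: nearest surface point lies on the shortest axis
    i <- which.min(a)
    qs <- c(0, 0, 0)
    qs[i] <- a[i]
    return(list(distance = min(a), inside = TRUE,
                closest = center + drop(rotation %*% qs)))
  }
  # Lagrange condition: closest surface point q* has q*_i = q_i a_i^2/(a_i^2+L)
  # with sum((q*_i/a_i)^2) = 1; for interior points L* lies in (-min(a)^2, 0).
  # Coordinates exactly at zero are perturbed infinitesimally so the bracket
  # endpoints keep their signs; the induced distance error is < 1e-9 um.
  qp <- ifelse(abs(q) < 1e-12, 1e-12, q)
  f <- function(L) sum(qp^2 * a^2 / (a^2 + L)^2) - 1
  lo <- -min(a)^2
  eps <- min(a)^2 * 1e-12
  while (f(lo + eps) < 0) eps <- eps * 10  # ensure positive at lower end
  root <- stats::uniroot(f, c(lo + eps, 0), tol = 1e-14,
                         f.lower = f(lo + eps), f.upper = f(0))$root
  qs <- qp * a^2 / (a^2 + root)
  d <- sqrt(sum((qs - qp)^2))
  list(distance = d, inside = TRUE,
       closest = center + drop(rotation %*% qs))
}

#' Sample points on an ellipsoid surface
#'
#' Deterministic quasi-uniform sampling (Fibonacci sphere mapped through the
#' semi-axes). Used as the brute-force cross-check for
#' [point_ellipsoid_distance()] and for rendering diagnostics.
#'
#' @inheritParams point_ellipsoid_distance
#' @param n number of points.
#' @return n x 3 matrix of surface points (z, y, x) in um.
#' @export
sample_ellipsoid_surface <- function(center, semiaxes, rotation = diag(3),
                                     n = 10000) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)               # polar angle
  theta <- pi * (1 + sqrt(5)) * i          # golden-angle azimuth
  u <- cbind(cos(phi),
             sin(phi) * sin(theta),
             sin(phi) * cos(theta))        # unit sphere, (z, y, x)
  p <- sweep(u, 2, semiaxes, `*`) %*% t(rotation)
  sweep(p, 2, center, `+`)
}

#' Brute-force distance to a sampled surface
#'
#' Minimum Euclidean distance from a point to a point cloud; the independent
#' oracle against which the analytic path is verified.
#'
#' @param point numeric length-3 (z, y, x) um.
#' @param points n x 3 matrix of surface points.
#' @return numeric distance in um.
#' @export
point_cloud_distance <- function(point, points) {
  d2 <- (points[, 1] - point[1])^2 + (points[, 2] - point[2])^2 +
    (points[, 3] - point[3])^2
  sqrt(min(d2))
}

# Approximate signed distance to an ellipsoid surface for a grid of points,
# first order: d ~ (m - 1)/|grad m| with m(x) = sqrt(sum(((x-c)/a)^2)) in the
# principal frame. Negative inside. Vectorized; used for shell rendering and
# fast residuals, never for the reported assay distance.
ellipsoid_signed_distance_approx <- function(pts, center, semiaxes,
                                             rotation = diag(3)) {
  q <- sweep(pts, 2, center) %*% rotation   # rows into principal frame
  s <- sweep(q, 2, semiaxes, `/`)
  m <- sqrt(rowSums(s^2))
  g <- sweep(q, 2, semiaxes^2, `/`)
  gn <- sqrt(rowSums(g^2))
  d <- (m - 1) * m / pmax(gn, 1e-12)
  d[m < 1e-12] <- -min(semiaxes)
  d
}

#' Fit an ellipsoid to boundary points
#'
#' Algebraic least-squares fit of the quadric
#' \eqn{x'Mx + b'x = 1} followed by iteratively reweighted refinement with
#' Tukey biweights, so stray ridge points (noise spikes, neighbouring signal)
#' do not drag the surface. Center, semi-axes and principal-axis rotation are
#' recovered from the eigendecomposition of M. The RMS of approximate
#' geometric point-to-surface distances is reported as the fit residual.
#'
#' @param pts n x 3 matrix of boundary points (z, y, x) in um, n >= 9.
#' @param iterations robust reweighting iterations (default 3).
#' @return list: `center`, `semiaxes`, `rotation` (columns = principal axes,
#'   ordered to match `semiaxes`), `residual_um` (RMS), `n_points`.
#' @export
fit_ellipsoid <- function(pts, iterations = 3) {
  pts <- as.matrix(pts)
  if (nrow(pts) < 9) stop("too few boundary points for an ellipsoid fit")
  z <- pts[, 1]; y <- pts[, 2]; x <- pts[, 3]
  D <- cbind(z^2, y^2, x^2, z * y, z * x, y * x, z, y, x)
  w <- rep(1, nrow(D))
  beta <- NULL
  for (it in seq_len(iterations + 1)) {
    Dw <- D * w
    beta <- tryCatch(solve(crossprod(Dw), crossprod(D, w^2)),
                     error = function(e) NULL)
    if (is.null(beta)) stop("ellipsoid fit is singular")
    r <- drop(D %*% beta) - 1
    s <- stats::mad(r, constant = 1.4826)
    if (s < 1e-12) break
    u <- r / (4.685 * s)
    w <- ifelse(abs(u) < 1, (1 - u^2)^2, 0)
    if (sum(w > 0) < 9) {  # degenerate reweighting; fall back to uniform
      w <- rep(1, nrow(D))
      break
    }
  }
  M <- matrix(c(beta[1], beta[4] / 2, beta[5] / 2,
                beta[4] / 2, beta[2], beta[6] / 2,
                beta[5] / 2, beta[6] / 2, beta[3]), 3, 3)
  b <- beta[7:9]
  ctr <- tryCatch(drop(solve(M, -b / 2)), error = function(e) NULL)
  if (is.null(ctr)) stop("ellipsoid fit is singular")
  s0 <- 1 + drop(t(ctr) %*% M %*% ctr)
  eg <- eigen(M, symmetric = TRUE)
  # ellipsoid iff every eigenvalue has the sign of s0 (the quadric's scale
  # flips sign when the center is far from the coordinate origin)
  if (s0 == 0 || any(sign(eg$values) != sign(s0))) {
    stop("fitted quadric is not an ellipsoid")
  }
  semiaxes <- sqrt(s0 / eg$values)
  rot <- eg$vectors
  if (det(rot) < 0) rot[, 3] <- -rot[, 3]  # keep a proper rotation
  res <- ellipsoid_signed_distance_approx(pts, ctr, semiaxes, rot)
  list(center = ctr, semiaxes = semiaxes, rotation = rot,
       residual_um = sqrt(mean(res^2)), n_points = nrow(pts))
}
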