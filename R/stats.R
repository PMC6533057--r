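#' Quartile summary of a distance distribution
#'
#' The five-number summary behind the quartile boxplots of the positioning
#' assay. Quartiles use linear interpolation between order statistics (the
#' common plotting default, R type 7); the convention is configurable since
#' plotting software conventions differ.
#'
#' @param values numeric vector (um for distance data), n >= 1.
#' @param type quantile type passed to [stats::quantile()] (default 7).
#' @return list: n, min, q1, median, q3, max.
#' @export
quartile_summary <- function(values, type = 7) {
  values <- values[!is.na(values)]
  if (length(values) < 1) stop("quartile_summary needs at least one value")
  q <- stats::quantile(values, c(0, 0.25, 0.5, 0.75, 1), type = type,
                       names = FALSE)
  list(n = length(values), min = q[1], q1 = q[2], median = q[3],
       q3 = q[4], max = q[5])
}

#' Two-sample z-test on means
#'
#' The distance-distribution comparison of the positioning assay: an
#' unpooled (Welch-style) two-sample z statistic on means with sample
#' variances,
#' \deqn{z = (\bar a - \bar b) / \sqrt{s_a^2/n_a + s_b^2/n_b},}
#' two-tailed p = 2(1 - Phi(|z|)). Appropriate for the large per-group cell
#' counts of the assay. A pooled-variance variant is provided as an option.
#'
#' @param a,b numeric samples, each n >= 2.
#' @param pooled use a pooled variance estimate (default FALSE).
#' @return list of class `nucperi_test`: method, statistic (z),
#'   p_two_tailed, n_a, n_b, mean_a, mean_b, degenerate (TRUE when the
#'   standard error is zero).
#' @export
two_sample_z_test <- function(a, b, pooled = FALSE) {
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  na <- length(a); nb <- length(b)
  if (na < 2 || nb < 2) stop("both samples need n >= 2")
  va <- stats::var(a); vb <- stats::var(b)
  se <- if (pooled) {
    sp2 <- ((na - 1) * va + (nb - 1) * vb) / (na + nb - 2)
    sqrt(sp2 * (1 / na + 1 / nb))
  } else {
    sqrt(va / na + vb / nb)
  }
  dm <- mean(a) - mean(b)
  degenerate <- se < 1e-300
  z <- if (degenerate) {
    if (abs(dm) < 1e-300) 0 else sign(dm) * Inf
  } else {
    dm / se
  }
  p <- if (is.infinite(z)) 0 else 2 * stats::pnorm(-abs(z))
  structure(list(method = if (pooled) "z_pooled" else "z",
                 statistic = z, p_two_tailed = p, n_a = na, n_b = nb,
                 mean_a = mean(a), mean_b = mean(b),
                 degenerate = degenerate),
            class = "nucperi_test")
}

#' Two-tailed Mann-Whitney U test
#'
#' U computed from rank sums with midranks for ties. Exact two-tailed p by
#' the full permutation null distribution when both groups have <= 12
#' observations and there are no ties (`mode = "auto"`); otherwise the
#' normal approximation with continuity correction and tie-corrected
#' variance. The two-tailed exact p is 2 min(P(U <= u), P(U >= u)), capped
#' at 1.
#'
#' @param a,b numeric samples, non-empty.
#' @param mode `"auto"`, `"exact"` or `"normal"`.
#' @return list of class `nucperi_test`: method, statistic (U of sample a),
#'   p_two_tailed, n_a, n_b.
#' @export
mann_whitney <- function(a, b, mode = c("auto", "exact", "normal")) {
  mode <- match.arg(mode)
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  na <- length(a); nb <- length(b)
  if (na < 1 || nb < 1) stop("both samples must be non-empty")
  r <- rank(c(a, b))                      # midranks for ties
  u <- sum(r[seq_len(na)]) - na * (na + 1) / 2
  ties <- anyDuplicated(c(a, b)) > 0
  use_exact <- switch(mode,
                      auto = na <= 12 && nb <= 12 && !ties,
                      exact = TRUE,
                      normal = FALSE)
  if (use_exact && ties) {
    stop("exact mode is undefined with ties; use mode = 'normal'")
  }
  if (use_exact) {
    # P(U <= u) and P(U >= u) under the exact permutation null
    p_le <- stats::pwilcox(u, na, nb)
    p_ge <- 1 - stats::pwilcox(u - 1, na, nb)
    p <- min(1, 2 * min(p_le, p_ge))
    method <- "mann_whitney_exact"
  } else {
    mu <- na * nb / 2
    n <- na + nb
    tie_tab <- table(c(a, b))
    tie_term <- sum(tie_tab^3 - tie_tab) / (n * (n - 1))
    sigma2 <- na * nb / 12 * (n + 1 - tie_term)
    if (sigma2 <= 0) {
      p <- 1
      z <- 0
    } else {
      z <- (u - mu - sign(u - mu) * 0.5) / sqrt(sigma2)
      if (abs(u - mu) <= 0.5) z <- 0
      p <- min(1, 2 * stats::pnorm(-abs(z)))
    }
    method <- "mann_whitney_normal"
  }
  structure(list(method = method, statistic = u, p_two_tailed = p,
                 n_a = na, n_b = nb),
            class = "nucperi_test")
}

#' @export
print.nucperi_test <- function(x, ...) {
  cat(sprintf("%s: statistic = %g, two-tailed p = %.4g (n = %d vs %d)\n",
              x$method, x$statistic, x$p_two_tailed, x$n_a, x$n_b))
  invisible(x)
}

#' Compare distance distributions between conditions
#'
#' Batch comparison report for a distance-record table: one row per pair of
#' condition labels, with the z-test (default) or Mann-Whitney p, group
#' sizes and medians. No multiple-testing correction is applied by default
#' (per-figure pairwise P values convention); Bonferroni or BH adjustment
#' is available for batch reports.
#'
#' @param records data.frame from [measure_dataset()] with a `condition`
#'   column.
#' @param test `"z"` or `"mann_whitney"`.
#' @param adjust `"none"` (default), `"bonferroni"` or `"BH"`.
#' @return data.frame: condition_a, condition_b, n_a, n_b, median_a,
#'   median_b, statistic, p (adjusted if requested).
#' @export
compare_conditions <- function(records, test = c("z", "mann_whitney"),
                               adjust = c("none", "bonferroni", "BH")) {
  test <- match.arg(test)
  adjust <- match.arg(adjust)
  conds <- sort(unique(records$condition))
  if (length(conds) < 2) stop("need at least two condition labels")
  pairs <- utils::combn(conds, 2)
  rows <- lapply(seq_len(ncol(pairs)), function(i) {
    ca <- pairs[1, i]; cb <- pairs[2, i]
    da <- usable_distances(records[records$condition == ca, ])
    db <- usable_distances(records[records$condition == cb, ])
    tt <- if (test == "z") two_sample_z_test(da, db) else mann_whitney(da, db)
    data.frame(condition_a = ca, condition_b = cb,
               n_a = length(da), n_b = length(db),
               median_a = stats::median(da), median_b = stats::median(db),
               method = tt$method, statistic = tt$statistic,
               p = tt$p_two_tailed, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (adjust != "none") out$p <- stats::p.adjust(out$p, method = adjust)
  out
}
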