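## Circular sliding-window (G+T)/(A+C) ratio profiles, linear trend fitting
## with a shading threshold, replication-origin inference, and the
## comparative skew atlas with per-group covariance ellipses.

## Circular window sums of a numeric vector: window for position p covers
## [p - left, p + right] inclusive, wrapping around the origin.
circular_window_sum <- function(x, left, right) {
  n <- length(x)
  padded <- x[(seq.int(-left, n - 1L + right) %% n) + 1L]
  cs <- c(0, cumsum(padded))
  w <- left + right + 1L
  cs[seq_len(n) + w] - cs[seq_len(n)]
}

#' Sliding-window (G+T)/(A+C) ratio profile
#'
#' For each position p of the main-coding strand the ratio of G+T to A+C
#' counts is computed over a circular window spanning `window_left` positions
#' to the left and `window_right` positions to the right of p (default
#' 149/150, a 300-base window).  Windows whose A+C count is zero are
#' undefined (`NA`).
#'
#' @param genome An [annotated_genome()]; must be circular and at least as
#'   long as the window.
#' @param window_left,window_right Window extent either side of the focal
#'   position.
#' @return A `ratio_profile` object: `values` (one ratio per position, `NA`
#'   where undefined), `window_left`, `window_right`, `n`.
#' @export
ratio_profile <- function(genome, window_left = 149L, window_right = 150L) {
  if (!genome$circular) stop("ratio_profile requires a circular genome")
  n <- genome_length(genome)
  w <- window_left + window_right + 1L
  if (n < w) stop("genome (", n, " bp) shorter than window (", w, " bp)")
  ch <- seq_chars(main_strand_seq(genome))
  gt <- circular_window_sum(as.numeric(ch %in% c("G", "T")),
                            window_left, window_right)
  ac <- circular_window_sum(as.numeric(ch %in% c("A", "C")),
                            window_left, window_right)
  values <- ifelse(ac == 0, NA_real_, gt / ac)
  structure(list(values = values, window_left = as.integer(window_left),
                 window_right = as.integer(window_right), n = n),
            class = "ratio_profile")
}

#' @export
print.ratio_profile <- function(x, ...) {
  cat(sprintf(
    "<ratio_profile> %d positions, window -%d/+%d, %d undefined\n",
    x$n, x$window_left, x$window_right, sum(is.na(x$values))))
  invisible(x)
}

#' Fit a linear trend to a ratio profile and derive a shading mask
#'
#' Ordinary least squares of the defined ratio values against position index.
#' The shading threshold, compared against the raw ratio values, is chosen by
#' `threshold`: `"slope"` uses the fitted slope as the scalar cutoff (the
#' convention of published (G+T)/(A+C) genome maps, where values larger than
#' the reported slope m of a fitted linear model are shaded), `"mean_sd"`
#' uses mean + `k` standard deviations of the defined values, and a numeric
#' `value` gives an explicit cutoff.
#'
#' @param profile A [ratio_profile()].
#' @param threshold `"slope"`, `"mean_sd"`, or `"explicit"`.
#' @param k Multiplier for `"mean_sd"` (default 1).
#' @param value Explicit cutoff for `threshold = "explicit"`.
#' @return A `trend_fit` object: `slope`, `intercept`, `threshold`,
#'   `shading_mask` (logical per position; `FALSE` at undefined positions).
#' @export
fit_trend <- function(profile, threshold = c("slope", "mean_sd", "explicit"),
                      k = 1, value = NULL) {
  threshold <- match.arg(threshold)
  y <- profile$values
  ok <- !is.na(y)
  if (sum(ok) < 2L) stop("fewer than two defined profile positions")
  xs <- seq_along(y)[ok]
  fit <- stats::lm.fit(cbind(1, xs), y[ok])
  slope <- unname(fit$coefficients[2])
  intercept <- unname(fit$coefficients[1])
  thr <- switch(threshold,
                slope = slope,
                mean_sd = mean(y[ok]) + k * stats::sd(y[ok]),
                explicit = {
                  if (is.null(value)) stop("explicit threshold needs 'value'")
                  value
                })
  mask <- !is.na(y) & y > thr
  structure(list(slope = slope, intercept = intercept, threshold = thr,
                 threshold_mode = threshold, shading_mask = mask),
            class = "trend_fit")
}

## Circular moving average ignoring NAs; span is the full window width.
circular_smooth <- function(values, span) {
  half <- max(1L, span %/% 2L)
  ok <- !is.na(values)
  num <- circular_window_sum(ifelse(ok, values, 0), half, half)
  den <- circular_window_sum(as.numeric(ok), half, half)
  ifelse(den == 0, NA_real_, num / den)
}

#' Infer replication origins from a ratio profile
#'
#' Under strand-displacement replication the strand bias is weakest where a
#' region stays single-stranded for the shortest time and strongest where it
#' stays single-stranded longest, so after circular moving-average smoothing
#' the profile minimum marks the light-strand origin (oriL) and the maximum
#' the heavy-strand origin (oriH).  Ties are broken towards the smallest
#' position and flagged.
#'
#' @param profile A [ratio_profile()] computed from `genome`.
#' @param genome The matching [annotated_genome()].
#' @param smooth_span Width of the circular moving-average window
#'   (default 300, one profile window).
#' @details Smoothing operates on the window G+T proportion
#'   `r / (1 + r)`, a monotone transform of the ratio `r` that keeps the
#'   variance of the smoothed curve comparable along the genome (raw ratios
#'   become extremely noisy where A+C counts are small); the reported
#'   smoothed curve is transformed back to the ratio scale.
#'
#'   With `method = "fit"` (the default) the two origins are located by a
#'   least-squares fit of the piecewise-linear single-strandedness gradient
#'   implied by strand-displacement replication: a circular tent running
#'   from -1 at oriL to +1 at oriH along both arcs.  The breakpoints of the
#'   best-fitting tent are the origin calls.  `method = "extremum"` instead
#'   takes the plain argmin/argmax of the smoothed curve; this simpler
#'   estimator is biased towards the shallow arc when the origins are not
#'   antipodal, because a moving-average peak shifts on an asymmetric tent.
#' @param method `"fit"` (tent-model least squares) or `"extremum"`
#'   (argmin/argmax of the smoothed curve).
#' @return An `ori_inference` object: `oriL`, `oriH` (0-based positions),
#'   `oriL_genes`, `oriH_genes` (flanking/containing feature names),
#'   `oriL_cds`, `oriH_cds` (nearest protein-coding genes), `ties`,
#'   `method`, `smoothed` (the smoothed profile values, ratio scale).
#' @export
infer_origins <- function(profile, genome, smooth_span = 300L,
                          method = c("fit", "extremum")) {
  method <- match.arg(method)
  if (profile$n != genome_length(genome)) {
    stop("profile and genome have different lengths")
  }
  smf <- circular_smooth(profile$values / (1 + profile$values), smooth_span)
  sm <- smf / (1 - smf)
  if (all(is.na(sm))) stop("profile is undefined everywhere")
  lo <- which(smf == min(smf, na.rm = TRUE))
  hi <- which(smf == max(smf, na.rm = TRUE))
  oriL <- lo[1] - 1L
  oriH <- hi[1] - 1L
  if (method == "fit") {
    fit <- fit_tent(smf)
    if (!is.null(fit)) {
      oriL <- fit$oriL
      oriH <- fit$oriH
    }
  }
  genome <- orient_main(genome)
  structure(list(
    oriL = oriL, oriH = oriH,
    oriL_genes = flanking_features(genome, oriL),
    oriH_genes = flanking_features(genome, oriH),
    oriL_cds = flanking_features(genome, oriL, kind = "CDS"),
    oriH_cds = flanking_features(genome, oriH, kind = "CDS"),
    ties = c(oriL = length(lo) > 1L, oriH = length(hi) > 1L),
    method = method,
    smooth_span = as.integer(smooth_span), smoothed = sm),
    class = "ori_inference")
}

## Circular tent basis: -1 at breakpoint a, +1 at breakpoint b, linear on
## both arcs (0-based positions on a genome of length n).
tent_basis <- function(p, a, b, n) {
  arc_ab <- (b - a) %% n
  if (arc_ab == 0) return(rep(0, length(p)))
  from_a <- (p - a) %% n
  ifelse(from_a <= arc_ab,
         -1 + 2 * from_a / arc_ab,
         1 - 2 * (from_a - arc_ab) / (n - arc_ab))
}

## Coarse-to-fine least-squares fit of the tent model to a smoothed
## profile; returns the breakpoint pair maximizing the correlation with
## the tent (slope constrained positive: b is the maximum).  NULL when the
## profile is flat or too sparse for a fit.
fit_tent <- function(values, n_eval = 400L) {
  n <- length(values)
  idx <- unique(round(seq(1L, n, length.out = min(n_eval, n))))
  y <- values[idx]
  keep <- !is.na(y)
  if (sum(keep) < 10L || stats::sd(y[keep]) < 1e-12) return(NULL)
  y <- y[keep]
  p <- idx[keep] - 1L
  score <- function(a, b) {
    d <- tent_basis(p, a, b, n)
    if (stats::sd(d) < 1e-12) return(-Inf)
    stats::cor(y, d)
  }
  step <- n / 24
  cand_a <- round(seq(0, n - 1, by = step))
  cand_b <- cand_a
  best <- c(a = 0, b = floor(n / 2), s = -Inf)
  for (a in cand_a) for (b in cand_b) {
    if (a == b) next
    s <- score(a, b)
    if (s > best["s"]) best <- c(a = a, b = b, s = s)
  }
  while (step > 8) {
    step <- step / 3
    grid_a <- round(best["a"] + step * (-3:3)) %% n
    grid_b <- round(best["b"] + step * (-3:3)) %% n
    for (a in grid_a) for (b in grid_b) {
      if (a == b) next
      s <- score(a, b)
      if (s > best["s"]) best <- c(a = a, b = b, s = s)
    }
  }
  list(oriL = unname(best["a"]), oriH = unname(best["b"]),
       cor = unname(best["s"]))
}

## Containing feature, or the nearest feature on each side of a position.
flanking_features <- function(genome, pos, kind = NULL) {
  feats <- if (is.null(kind)) genome$features else
    features_of_kind(genome, kind)
  if (length(feats) == 0L) return(c(NA_character_, NA_character_))
  n <- genome_length(genome)
  for (f in feats) {
    if (coverage_mask(genome, f)[pos + 1L]) {
      return(c(f$name, f$name))
    }
  }
  starts <- vapply(feats, function(f) f$intervals[1, "start"], numeric(1))
  ends <- vapply(feats, function(f) max(f$intervals[, "end"]) %% n,
                 numeric(1))
  names <- vapply(feats, `[[`, character(1), "name")
  before <- names[which.min((pos - ends) %% n)]
  after <- names[which.min((starts - pos) %% n)]
  c(before, after)
}

#' Covariance ellipse of a set of skew points
#'
#' @param points Matrix or data frame with two columns (AT-skew, GC-skew).
#' @param group Optional group label stored on the result.
#' @return A `group_ellipse` object: `group`, `n`, `mean`, `eigenvalues`
#'   (decreasing), `eigenvectors` (columns, major axis first), `min`, `max`,
#'   `degenerate` (`TRUE` when the minor eigenvalue is numerically zero).
#' @export
skew_ellipse <- function(points, group = NA_character_) {
  m <- as.matrix(points)[, 1:2, drop = FALSE]
  if (nrow(m) < 3L) stop("an ellipse needs at least 3 points")
  cv <- stats::cov(m)
  eig <- eigen(cv, symmetric = TRUE)
  structure(list(group = group, n = nrow(m), mean = colMeans(m),
                 eigenvalues = eig$values, eigenvectors = eig$vectors,
                 min = apply(m, 2, min), max = apply(m, 2, max),
                 degenerate = eig$values[2] <= 1e-12 * max(eig$values[1], 1)),
            class = "group_ellipse")
}

#' Comparative skew atlas
#'
#' Main-coding-strand AT- and GC-skews for a set of genomes, with per-group
#' mean, covariance eigen-decomposition (major axis along the leading
#' eigenvector) and min/max cross, mirroring the classic skew-atlas display
#' of bilaterian mitogenomes.
#'
#' @param genomes List of [annotated_genome()] objects.
#' @param grouping Character vector of group labels, one per genome
#'   (default: one group).
#' @return A list with `points` (data frame: `id`, `group`, `at_skew`,
#'   `gc_skew`) and `ellipses` (list of [skew_ellipse()] results for groups
#'   with at least 3 genomes).
#' @export
skew_atlas <- function(genomes, grouping = NULL) {
  grouping <- grouping %||% rep("all", length(genomes))
  stopifnot(length(grouping) == length(genomes))
  points <- do.call(rbind, Map(function(g, grp) {
    cnt <- base_counts(main_strand_seq(g))
    data.frame(id = g$id, group = grp, at_skew = at_skew(cnt),
               gc_skew = gc_skew(cnt))
  }, genomes, grouping))
  rownames(points) <- NULL
  groups <- unique(grouping)
  ellipses <- list()
  for (grp in groups) {
    sub <- points[points$group == grp, c("at_skew", "gc_skew")]
    if (nrow(sub) >= 3L) ellipses[[grp]] <- skew_ellipse(sub, grp)
  }
  list(points = points, ellipses = ellipses)
}
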