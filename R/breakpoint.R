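#' LOWESS smoothing of an effect series
#'
#' Locally weighted scatterplot smoothing (tricube-weighted local linear
#' regression with robustness iterations) of a series of values against the
#' examined-node count, evaluated at the input positions. The default
#' bandwidth — the fraction of points entering each local fit — is 2/3.
#'
#' @param x numeric predictor (ELN counts), strictly increasing after
#'   sorting; at least 5 points.
#' @param y series values at `x`.
#' @param bandwidth smoother span in `(0, 1]`.
#' @param iterations robustness iterations (0 gives plain tricube-weighted
#'   local linear regression); used only on the unweighted path.
#' @param weights optional per-point precision weights (e.g. inverse
#'   variances of the series estimates). When supplied, each local linear
#'   fit uses the product of the tricube neighborhood weight and the
#'   precision weight, so imprecise points influence the curve less;
#'   robustness iterations are not applied on this path.
#' @return a `smoothed_series`: data frame with columns `x`, `raw`,
#'   `fitted`, ordered by `x`, with the bandwidth as an attribute.
#' @export
lowess_fit <- function(x, y, bandwidth = 2/3, iterations = 3L, weights = NULL) {
  if (!is.numeric(bandwidth) || length(bandwidth) != 1 ||
      bandwidth <= 0 || bandwidth > 1) {
    stop("bandwidth must be in (0, 1]", call. = FALSE)
  }
  if (length(x) != length(y)) stop("x and y lengths differ", call. = FALSE)
  if (length(x) < 5) stop("need at least 5 points to smooth", call. = FALSE)
  ord <- order(x)
  if (is.null(weights)) {
    sm <- lowess(x[ord], y[ord], f = bandwidth, iter = iterations, delta = 0)
    fitted <- sm$y
  } else {
    if (length(weights) != length(x)) {
      stop("weights must match the series length", call. = FALSE)
    }
    if (any(weights < 0) || all(weights == 0)) {
      stop("weights must be non-negative with a positive total", call. = FALSE)
    }
    xs <- x[ord]; ys <- y[ord]; ws <- weights[ord]
    n <- length(xs)
    r <- ceiling(bandwidth * n)
    fitted <- vapply(seq_len(n), function(i) {
      d <- abs(xs - xs[i])
      h <- sort(d)[r]
      tw <- (pmax(0, 1 - pmin(d / max(h, 1e-12), 1)^3))^3 * ws
      cf <- stats::lm.wfit(cbind(1, xs), ys, tw)$coefficients
      sum(c(1, xs[i]) * cf)
    }, numeric(1))
  }
  structure(data.frame(x = x[ord], raw = y[ord], fitted = fitted),
            class = c("smoothed_series", "data.frame"),
            bandwidth = bandwidth, iterations = iterations,
            weighted = !is.null(weights))
}

series_xy <- function(series, on = c("fitted", "raw")) {
  on <- match.arg(on)
  if (inherits(series, "smoothed_series")) {
    list(x = series$x, y = if (on == "fitted") series$fitted else series$raw)
  } else if (is.data.frame(series) && all(c("x", "y") %in% names(series))) {
    list(x = series$x, y = series$y)
  } else {
    stop("series must be a smoothed_series or a data frame with columns x, y",
         call. = FALSE)
  }
}

segment_rss <- function(x, y, w) {
  n <- length(x)
  if (n == 0) return(0)
  if (is.null(w)) w <- rep(1, n)
  if (n == 1) return(0)
  fit <- stats::lm.wfit(cbind(1, x), y, w)
  sum(w * fit$residuals^2)
}

#' Chow structural-break scan over an effect series
#'
#' For each candidate break `c`, one line is fit to the points with
#' `x <= c` and another to `x > c`, and the Chow F statistic
#' `F = ((RSS_pooled - RSS1 - RSS2)/2) / ((RSS1 + RSS2)/(n - 4))`
#' compares the two-segment fit to a single pooled line; its reference
#' distribution under no break is F(2, n - 4). The selected break maximizes
#' F over the scan. The reported p-values are nominal fixed-candidate
#' p-values: maximizing over candidates inflates the type-I error of the
#' selected break, which is documented rather than corrected.
#'
#' @param series a `smoothed_series` (from [lowess_fit]) or a data frame
#'   with columns `x` and `y`.
#' @param candidate_range optional numeric length-2 vector restricting the
#'   candidates; by default every observed `x` that leaves `min_segment`
#'   points on each side is a candidate.
#' @param min_segment minimum points per segment (default 3).
#' @param on scan the `"fitted"` (LOWESS) or `"raw"` values of a
#'   `smoothed_series`.
#' @param weights optional per-point weights (e.g. inverse variances) for
#'   the segment regressions; default unweighted.
#' @return a `chow_scan` object: list with `scan` (candidate, f, p,
#'   skipped), `selected_break`, `f_at_break`, `p_at_break`,
#'   `candidate_range`, `n_points`.
#' @export
chow_scan <- function(series, candidate_range = NULL, min_segment = 3,
                      on = c("fitted", "raw"), weights = NULL) {
  xy <- series_xy(series, on)
  x <- xy$x; y <- xy$y
  n <- length(x)
  if (n < 2 * min_segment) {
    stop(sprintf("series has %d points; at least %d needed with min_segment = %d",
                 n, 2 * min_segment, min_segment), call. = FALSE)
  }
  cand <- sort(unique(x))
  cand <- cand[cand < max(x)]  # a break at the last point leaves no right segment
  if (!is.null(candidate_range)) {
    stopifnot(length(candidate_range) == 2)
    cand <- cand[cand >= candidate_range[1] & cand <= candidate_range[2]]
  }
  if (length(cand) == 0) stop("empty candidate set", call. = FALSE)

  rss_pooled <- segment_rss(x, y, weights)
  scan <- data.frame(candidate = cand, f = NA_real_, p = NA_real_,
                     skipped = FALSE, reason = "")
  for (i in seq_along(cand)) {
    left <- x <= cand[i]
    n1 <- sum(left); n2 <- n - n1
    if (n1 < min_segment || n2 < min_segment) {
      scan$skipped[i] <- TRUE
      scan$reason[i] <- sprintf("segment sizes %d/%d below min_segment %d",
                                n1, n2, min_segment)
      next
    }
    rss1 <- segment_rss(x[left], y[left], weights[left])
    rss2 <- segment_rss(x[!left], y[!left], weights[!left])
    rss_seg <- rss1 + rss2
    tol <- 1e-10 * max(rss_pooled, 1)
    if (rss_seg < tol) {
      if (rss_pooled - rss_seg < tol) {        # both fits perfect: no break signal
        scan$f[i] <- 0; scan$p[i] <- 1
      } else {                                  # perfect segment fit, pooled not
        scan$f[i] <- Inf; scan$p[i] <- 0
      }
    } else {
      f <- ((rss_pooled - rss_seg) / 2) / (rss_seg / (n - 4))
      scan$f[i] <- max(f, 0)
      scan$p[i] <- pf(scan$f[i], 2, n - 4, lower.tail = FALSE)
    }
  }
  ok <- !scan$skipped
  if (!any(ok)) stop("every candidate leaves an undersized segment", call. = FALSE)
  # on exact ties (e.g. a noiseless kink point lying on both segment lines)
  # take the largest tied candidate, so the kink itself is selected
  idx <- which(ok)
  best <- idx[max(which(scan$f[idx] == max(scan$f[idx])))]
  structure(list(scan = scan,
                 selected_break = scan$candidate[best],
                 f_at_break = scan$f[best],
                 p_at_break = scan$p[best],
                 candidate_range = range(scan$candidate[ok]),
                 n_points = n),
            class = "chow_scan")
}

#' @export
print.chow_scan <- function(x, ...) {
  cat(sprintf("Chow structural-break scan (%d points, candidates %.4g-%.4g)\n",
              x$n_points, x$candidate_range[1], x$candidate_range[2]))
  cat(sprintf("  selected break at x = %.4g (F = %.4g, nominal p = %.3g)\n",
              x$selected_break, x$f_at_break, x$p_at_break))
  invisible(x)
}

#' Select the ELN cut point from a set of structural-break results
#'
#' Survival drives the choice: the cut point is the break of the survival
#' series, rounded to an integer node count. Breaks from the other series
#' (stage migration, occult probability, mean positive nodes) are reported
#' as a concordance check, with a warning when they spread over more than
#' `max_spread` nodes.
#'
#' @param results named list of [chow_scan] results; must contain an element
#'   named `"survival"`.
#' @param max_spread widest break range regarded as concordant.
#' @return a `cutpoint_selection`: list with `cutpoint` (integer), `breaks`
#'   (named numeric), `range`, `spread`, `concordant`.
#' @export
select_cutpoint <- function(results, max_spread = 6) {
  stopifnot(is.list(results))
  if (!("survival" %in% names(results))) {
    stop("a 'survival' break-point result is required to select the cut point",
         call. = FALSE)
  }
  breaks <- vapply(results, function(r) {
    stopifnot(inherits(r, "chow_scan"))
    r$selected_break
  }, numeric(1))
  spread <- diff(range(breaks))
  if (spread > max_spread) {
    warning(sprintf("break points disagree across series: range %.4g-%.4g (spread %.4g > %g)",
                    min(breaks), max(breaks), spread, max_spread))
  }
  structure(list(cutpoint = as.integer(round(breaks[["survival"]])),
                 breaks = breaks,
                 range = range(breaks),
                 spread = spread,
                 concordant = spread <= max_spread),
            class = "cutpoint_selection")
}

#' @export
print.cutpoint_selection <- function(x, ...) {
  cat(sprintf("Selected ELN cut point: %d (survival break)\n", x$cutpoint))
  cat(sprintf("  all series breaks: %s (range %.4g-%.4g, %s)\n",
              paste(sprintf("%s=%.4g", names(x$breaks), x$breaks), collapse = ", "),
              x$range[1], x$range[2],
              if (x$concordant) "concordant" else "DISCORDANT"))
  invisible(x)
}
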