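#' Wilson score confidence interval for a binomial proportion
#'
#' @param k number of successes.
#' @param n number of trials.
#' @param conf confidence level (default 0.95).
#' @return Named numeric vector `c(lower, upper)`.
#' @examples
#' wilson_ci(90, 100)
#' @export
wilson_ci <- function(k, n, conf = 0.95) {
  stopifnot(n > 0, k >= 0, k <= n)
  z <- qnorm(1 - (1 - conf) / 2)
  p <- k / n
  denom <- 1 + z^2 / n
  centre <- (p + z^2 / (2 * n)) / denom
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / denom
  c(lower = max(0, centre - half), upper = min(1, centre + half))
}

#' Otsu threshold of a numeric vector
#'
#' Splits a (typically log-intensity) distribution at the histogram cut
#' maximising between-class variance.
#'
#' @param x finite numeric vector with non-zero range.
#' @param n_bins number of histogram bins (default 256).
#' @return The threshold value (a bin boundary).
#' @export
otsu_threshold <- function(x, n_bins = 256L) {
  x <- x[is.finite(x)]
  if (length(x) == 0L || diff(range(x)) == 0) {
    stop("cannot threshold constant intensities", call. = FALSE)
  }
  breaks <- seq(min(x), max(x), length.out = n_bins + 1L)
  counts <- tabulate(findInterval(x, breaks, rightmost.closed = TRUE),
                     nbins = n_bins)
  w <- counts / sum(counts)
  mids <- (breaks[-1L] + breaks[-(n_bins + 1L)]) / 2
  omega <- cumsum(w)
  mu <- cumsum(w * mids)
  mu_total <- mu[n_bins]
  between <- (mu_total * omega - mu)^2 / (omega * (1 - omega))
  between[!is.finite(between)] <- -Inf
  breaks[which.max(between) + 1L]
}

#' Derive per-marker baseline intensity thresholds
#'
#' With a negative control, the threshold for each marker is the control
#' mean plus two control SDs. Without a control the threshold is an Otsu
#' split of the log-intensity histogram, mapped back to the linear scale.
#' The method used is recorded in the result.
#'
#' @param intensities numeric matrix or data frame of linear
#'   background-corrected intensities, one column per marker (a bare
#'   vector is treated as a single marker).
#' @param control_intensities optional matrix/data frame of negative
#'   control intensities with the same columns.
#' @return List of class `"threshold_result"`: `thresholds` (named per
#'   marker), `method` (`"control_mean_2sd"` or `"otsu_log"`).
#' @export
derive_thresholds <- function(intensities, control_intensities = NULL) {
  as_mat <- function(z) {
    if (is.null(dim(z))) z <- matrix(as.numeric(z), ncol = 1,
                                     dimnames = list(NULL, "marker"))
    as.matrix(z)
  }
  intensities <- as_mat(intensities)
  if (nrow(intensities) == 0L) stop("empty intensity table", call. = FALSE)
  if (!is.null(control_intensities)) {
    ctl <- as_mat(control_intensities)
    thr <- apply(ctl, 2, function(v) {
      v <- v[is.finite(v)]
      if (length(v) < 2L || sd(v) == 0) {
        stop("cannot threshold constant control intensities", call. = FALSE)
      }
      mean(v) + 2 * sd(v)
    })
    method <- "control_mean_2sd"
  } else {
    thr <- apply(intensities, 2, function(v) {
      v <- v[is.finite(v) & v > 0]
      exp(otsu_threshold(log(v)))
    })
    method <- "otsu_log"
  }
  structure(list(thresholds = thr, method = method),
            class = "threshold_result")
}

#' Quadrant gating and per-quadrant colocalization statistics
#'
#' Assigns each particle to a quadrant of the two-marker intensity plane:
#' Q1 low/low, Q2 low-A/high-B, Q3 high/high (the colocalization
#' quadrant), Q4 high-A/low-B, with ties at the threshold counting as
#' positive (`>=`). Reports the Spearman rank correlation of the two
#' intensities within each quadrant (missing below 3 points), and the Q3
#' proportion with its Wilson 95% CI. By default the Q3 denominator
#' excludes the baseline quadrant Q1 (marker-positive particles only);
#' `denominator = "all"` uses every particle.
#'
#' @param table data frame with columns `intensity_a`, `intensity_b`
#'   (linear scale).
#' @param thresholds length-2 numeric vector (threshold for marker A and
#'   B) or a [derive_thresholds()] result.
#' @param denominator `"non_q1"` (default) or `"all"`.
#' @param conf confidence level for the Wilson interval (default 0.95).
#' @return List of class `"quadrant_result"`: `thresholds`, `quadrant`
#'   (per-particle factor), `counts` (named Q1-Q4), `spearman` (named
#'   per-quadrant rho), `q3_proportion`, `ci` (Wilson bounds),
#'   `denominator`, `n`.
#' @export
assign_and_correlate <- function(table, thresholds,
                                 denominator = c("non_q1", "all"),
                                 conf = 0.95) {
  denominator <- match.arg(denominator)
  if (inherits(thresholds, "threshold_result")) {
    thresholds <- thresholds$thresholds
  }
  thresholds <- as.numeric(thresholds)
  if (length(thresholds) != 2L || any(!is.finite(thresholds))) {
    stop("thresholds must be two finite numbers", call. = FALSE)
  }
  if (nrow(table) == 0L) stop("empty particle table", call. = FALSE)
  stopifnot(all(c("intensity_a", "intensity_b") %in% names(table)))
  a_hi <- table$intensity_a >= thresholds[1]
  b_hi <- table$intensity_b >= thresholds[2]
  quadrant <- factor(ifelse(a_hi & b_hi, "Q3",
                            ifelse(a_hi, "Q4",
                                   ifelse(b_hi, "Q2", "Q1"))),
                     levels = c("Q1", "Q2", "Q3", "Q4"))
  counts <- table(quadrant)
  spearman <- vapply(levels(quadrant), function(q) {
    idx <- quadrant == q
    if (sum(idx) < 3L) return(NA_real_)
    suppressWarnings(cor(table$intensity_a[idx], table$intensity_b[idx],
                         method = "spearman"))
  }, numeric(1))
  denom_n <- if (denominator == "non_q1") sum(counts[c("Q2", "Q3", "Q4")])
             else sum(counts)
  k <- counts[["Q3"]]
  prop <- if (denom_n > 0) k / denom_n else NA_real_
  ci <- if (denom_n > 0) wilson_ci(k, denom_n, conf) else
    c(lower = NA_real_, upper = NA_real_)
  structure(list(thresholds = setNames(thresholds, c("a", "b")),
                 quadrant = quadrant,
                 counts = setNames(as.integer(counts), names(counts)),
                 spearman = spearman,
                 q3_proportion = prop, ci = ci,
                 denominator = denominator, n = nrow(table)),
            class = "quadrant_result")
}

#' Mean fold enrichment across sorting runs
#'
#' Per matched run, the fold enrichment is the sorted percentage divided
#' by the unsorted percentage; the summary is the arithmetic mean across
#' runs. The statistic is scale invariant: multiplying all percentages by
#' a constant leaves it unchanged.
#'
#' @param unsorted_pct,sorted_pct matched positive percentages per run.
#' @return List: `folds` (per run), `mean_fold`.
#' @examples
#' sorting_fold_enrichment(c(7.09, 6.22), c(46.35, 45.56))$mean_fold
#' @export
sorting_fold_enrichment <- function(unsorted_pct, sorted_pct) {
  if (length(unsorted_pct) != length(sorted_pct) ||
      length(unsorted_pct) == 0L) {
    stop("unsorted and sorted percentages must be matched and non-empty",
         call. = FALSE)
  }
  if (any(unsorted_pct <= 0)) {
    stop("unsorted percentages must be positive", call. = FALSE)
  }
  folds <- sorted_pct / unsorted_pct
  list(folds = folds, mean_fold = mean(folds))
}
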