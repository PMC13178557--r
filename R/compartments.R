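#' Collapse synaptic cellular-component terms to one of four locations
#'
#' Maps each protein's raw cellular-component term set to a single
#' synaptic location: any presynaptic term together with any postsynaptic
#' term gives `Both`; only presynaptic terms give `Presynapse`; only
#' postsynaptic terms give `Postsynapse`; terms that are synaptic but
#' neither pre- nor postsynaptic give `Synapse`. Terms are matched by the
#' substrings `"presyn"` / `"postsyn"` (case-insensitive); a term without
#' any recognisable synaptic wording is logged via `message()` and treated
#' as generic synaptic.
#'
#' @param terms a character vector of `sep`-delimited term strings (one
#'   element per protein), or a list of character vectors.
#' @param sep delimiter used when `terms` is a character vector
#'   (default `";"`).
#' @return Character vector with values `Presynapse`, `Postsynapse`,
#'   `Both`, `Synapse` (or `NA` for an empty term set).
#' @examples
#' collapse_location(c("presynaptic active zone",
#'                     "presynapse;postsynaptic density", "synapse"))
#' @export
collapse_location <- function(terms, sep = ";") {
  if (is.character(terms)) terms <- strsplit(terms, sep, fixed = TRUE)
  vapply(terms, function(tt) {
    tt <- tolower(trimws(tt))
    tt <- tt[nzchar(tt) & !is.na(tt)]
    if (length(tt) == 0L) return(NA_character_)
    pre <- grepl("presyn", tt) & !grepl("postsyn", tt)
    post <- grepl("postsyn", tt)
    unknown <- !grepl("synap", tt)
    if (any(unknown)) {
      message("unmappable terms treated as generic synaptic: ",
              paste(tt[unknown], collapse = ", "))
    }
    if (any(pre) && any(post)) "Both"
    else if (any(pre)) "Presynapse"
    else if (any(post)) "Postsynapse"
    else "Synapse"
  }, character(1))
}

#' Pearson chi-square test of independence
#'
#' Plain Pearson chi-square without continuity correction, computed from
#' the closed form `sum((O - E)^2 / E)` with expected counts from the
#' margin products. A warning is issued when any expected count is below
#' 5.
#'
#' @param tab matrix (or table) of non-negative integer counts, at least
#'   2 x 2, e.g. dominance class by synaptic location.
#' @return List of class `"contingency_result"`: `observed`, `expected`,
#'   `statistic`, `df`, `p_value`.
#' @examples
#' chi_square_independence(matrix(c(30, 10, 10, 30), 2))$statistic  # 20
#' @export
chi_square_independence <- function(tab) {
  tab <- as.matrix(tab)
  if (any(tab < 0) || any(tab != round(tab)) || any(!is.finite(tab))) {
    stop("counts must be non-negative integers", call. = FALSE)
  }
  if (nrow(tab) < 2L || ncol(tab) < 2L) {
    stop("need at least a 2 x 2 table", call. = FALSE)
  }
  rs <- rowSums(tab)
  cs <- colSums(tab)
  if (any(rs == 0) || any(cs == 0)) {
    stop("degenerate table: zero row or column margin", call. = FALSE)
  }
  expected <- outer(rs, cs) / sum(tab)
  if (any(expected < 5)) {
    warning("expected counts below 5; chi-square approximation is rough")
  }
  statistic <- sum((tab - expected)^2 / expected)
  df <- (nrow(tab) - 1L) * (ncol(tab) - 1L)
  structure(list(observed = tab, expected = expected,
                 statistic = statistic, df = df,
                 p_value = pchisq(statistic, df, lower.tail = FALSE)),
            class = "contingency_result")
}

#' Two-sample Kolmogorov-Smirnov test
#'
#' Statistic is the supremum absolute difference of the two empirical
#' CDFs; the two-sided p-value uses the asymptotic Kolmogorov
#' distribution. In the dominance analysis `sample1` holds dominance
#' scores of dominant synaptically annotated proteins and `sample2` the
#' control distribution of all quantified proteins. The statistic is the
#' contract; the asymptotic p-value is advisory at small n.
#'
#' @param sample1,sample2 non-empty numeric vectors.
#' @return List of class `"ks_result"`: `statistic`, `p_value`, `n1`,
#'   `n2`.
#' @examples
#' ks_two_sample(1:4, 2:5)$statistic  # 0.25
#' @export
ks_two_sample <- function(sample1, sample2) {
  sample1 <- sample1[is.finite(sample1)]
  sample2 <- sample2[is.finite(sample2)]
  n1 <- length(sample1)
  n2 <- length(sample2)
  if (n1 == 0L || n2 == 0L) stop("empty sample", call. = FALSE)
  grid <- sort(unique(c(sample1, sample2)))
  f1 <- vapply(grid, function(g) mean(sample1 <= g), numeric(1))
  f2 <- vapply(grid, function(g) mean(sample2 <= g), numeric(1))
  d <- max(abs(f1 - f2))
  lambda <- sqrt(n1 * n2 / (n1 + n2)) * d
  j <- 1:100
  p <- min(1, max(0, 2 * sum((-1)^(j - 1) * exp(-2 * j^2 * lambda^2))))
  structure(list(statistic = d, p_value = p, n1 = n1, n2 = n2),
            class = "ks_result")
}

#' Logistic regression of dominance class on synaptic location
#'
#' Models the probability of CFC dominance (outcome: CFC-dominant = 1,
#' CE-dominant = 0) from two location indicators, postsynaptic and
#' presynaptic, with the pooled `{Both, Synapse}` categories as reference.
#' Fit is by maximum likelihood (IRLS, tolerance 1e-10) with Wald 95%
#' confidence intervals, McFadden pseudo-R2 and a likelihood-ratio test
#' against the intercept-only model. Complete (quasi-)separation is
#' detected from degenerate fitted probabilities or exploding
#' coefficients, in which case a Firth-style penalised-likelihood fit is
#' substituted and flagged in the output.
#'
#' @param klass character vector of dominance classes; only
#'   `CFC-dominant` / `CE-dominant` rows are used.
#' @param location synaptic locations (`Presynapse`, `Postsynapse`,
#'   `Both`, `Synapse`), same length as `klass`.
#' @param level confidence level for Wald intervals (default 0.95).
#' @return List of class `"logistic_dominance"`: `coefficients` (data
#'   frame with `term`, `estimate`, `se`, `ci_low`, `ci_high`, `or`,
#'   `or_low`, `or_high`), `pseudo_r2` (McFadden), `p_value`
#'   (likelihood-ratio), `separation`, `method` (`"ml"` or `"firth"`),
#'   `n`.
#' @export
logistic_dominance <- function(klass, location, level = 0.95) {
  keep <- klass %in% c("CFC-dominant", "CE-dominant")
  y <- as.integer(klass[keep] == "CFC-dominant")
  loc <- location[keep]
  if (length(unique(y)) < 2L) {
    stop("need both CFC-dominant and CE-dominant proteins", call. = FALSE)
  }
  X <- cbind("(Intercept)" = 1,
             Postsynapse = as.numeric(loc == "Postsynapse"),
             Presynapse = as.numeric(loc == "Presynapse"))
  # drop indicator columns without variation (location level absent)
  keep_col <- c(TRUE, apply(X[, -1, drop = FALSE], 2,
                            function(v) length(unique(v)) > 1L))
  X <- X[, keep_col, drop = FALSE]
  fit <- glm.fit(X, y, family = binomial(),
                 control = glm.control(epsilon = 1e-10, maxit = 100))
  beta <- fit$coefficients
  p_hat <- fit$fitted.values
  separation <- any(p_hat < 1e-8 | p_hat > 1 - 1e-8) ||
    any(abs(beta) > 15)
  method <- "ml"
  if (separation) {
    ff <- firth_logit(X, y)
    beta <- ff$beta
    vc <- ff$vcov
    method <- "firth"
  } else {
    w <- p_hat * (1 - p_hat)
    vc <- solve(crossprod(X * sqrt(w)))
  }
  se <- sqrt(diag(vc))
  z <- qnorm(1 - (1 - level) / 2)
  loglik <- function(b) {
    eta <- drop(X %*% b)
    sum(y * eta - log1p(exp(eta)))
  }
  ll <- loglik(beta)
  p0 <- mean(y)
  ll0 <- sum(y * log(p0) + (1 - y) * log(1 - p0))
  lr <- 2 * (ll - ll0)
  coefs <- data.frame(term = colnames(X), estimate = unname(beta),
                      se = unname(se),
                      ci_low = unname(beta - z * se),
                      ci_high = unname(beta + z * se),
                      stringsAsFactors = FALSE)
  coefs$or <- exp(coefs$estimate)
  coefs$or_low <- exp(coefs$ci_low)
  coefs$or_high <- exp(coefs$ci_high)
  structure(list(coefficients = coefs,
                 pseudo_r2 = 1 - ll / ll0,
                 p_value = pchisq(lr, df = ncol(X) - 1L,
                                  lower.tail = FALSE),
                 separation = separation, method = method,
                 n = length(y)),
            class = "logistic_dominance")
}

# Firth bias-reduced logistic regression: Newton iterations on the
# Jeffreys-penalised score U*(b) = X'(y - p + h (1/2 - p)), h the hat
# diagonal of the weighted design.
firth_logit <- function(X, y, max_iter = 200L, tol = 1e-8) {
  beta <- rep(0, ncol(X))
  for (i in seq_len(max_iter)) {
    eta <- drop(X %*% beta)
    p <- plogis(eta)
    w <- pmax(p * (1 - p), 1e-12)
    Xw <- X * sqrt(w)
    info <- crossprod(Xw)
    inv <- solve(info)
    h <- rowSums((Xw %*% inv) * Xw)
    score <- crossprod(X, y - p + h * (0.5 - p))
    step <- drop(inv %*% score)
    # dampen very large steps for stability
    if (max(abs(step)) > 5) step <- step * 5 / max(abs(step))
    beta <- beta + step
    if (max(abs(step)) < tol) break
  }
  names(beta) <- colnames(X)
  list(beta = beta, vcov = inv)
}

#' One-sided Fisher/hypergeometric gene-set enrichment
#'
#' Tests over-representation of `genes` in each trait gene set against a
#' fixed background universe, using the exact upper hypergeometric tail
#' (equivalent to a one-sided Fisher's exact test for enrichment).
#' p-values are Benjamini-Hochberg adjusted across trait sets.
#'
#' @param genes character vector of study genes (e.g. proteins enriched
#'   after a condition).
#' @param trait_sets named list of character vectors (trait-associated
#'   gene sets), or a single character vector.
#' @param background size of the gene universe (default 18384, the number
#'   of genes eligible for GWAS prioritisation in the emulated analysis).
#' @return Data frame: `set`, `overlap`, `n_genes`, `n_set`, `background`,
#'   `odds_ratio` (sample cross-product estimate), `p_value`, `q_value`.
#' @examples
#' fisher_enrichment(letters[1:5], list(t = letters[1:5]), background = 10)
#' @export
fisher_enrichment <- function(genes, trait_sets, background = 18384) {
  if (!is.list(trait_sets)) trait_sets <- list(set = trait_sets)
  genes <- unique(genes)
  m <- length(genes)
  if (m > background) {
    stop("background must be at least the study set size", call. = FALSE)
  }
  rows <- lapply(names(trait_sets), function(nm) {
    ts <- unique(trait_sets[[nm]])
    if (length(ts) > background ||
        length(union(ts, genes)) > background) {
      stop("background must cover the union of the gene sets",
           call. = FALSE)
    }
    k <- length(intersect(genes, ts))
    p <- phyper(k - 1, length(ts), background - length(ts), m,
                lower.tail = FALSE)
    a <- k
    b <- m - k
    cc <- length(ts) - k
    d <- background - m - length(ts) + k
    data.frame(set = nm, overlap = k, n_genes = m, n_set = length(ts),
               background = background,
               odds_ratio = (a * d) / (b * cc),
               p_value = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$q_value <- p.adjust(out$p_value, method = "BH")
  rownames(out) <- NULL
  out
}

#' One-tailed hypergeometric test for a higher proportion
#'
#' Tests whether the proportion of flagged genes in a study group
#' (`k1 / n1`) exceeds that of a control group (`k2 / n2`), conditioning
#' on the combined margins: the p-value is the upper hypergeometric tail
#' `P(X >= k1)` for `n1` draws from a population of `population_size`
#' genes containing `population_successes` flagged ones. By default the
#' population is the union of the two groups; both population parameters
#' can be overridden when a wider universe is appropriate.
#'
#' @param k1,n1 flagged count and size of the study group.
#' @param k2,n2 flagged count and size of the control group.
#' @param population_successes,population_size population the draw is
#'   conditioned on (defaults `k1 + k2` and `n1 + n2`).
#' @return List: `p_value`, `proportion1`, `proportion2`.
#' @examples
#' hypergeometric_proportion(23, 60, 28, 100)
#' @export
hypergeometric_proportion <- function(k1, n1, k2, n2,
                                      population_successes = k1 + k2,
                                      population_size = n1 + n2) {
  stopifnot(k1 >= 0, k2 >= 0, k1 <= n1, k2 <= n2,
            population_successes <= population_size,
            n1 <= population_size)
  p <- phyper(k1 - 1, population_successes,
              population_size - population_successes, n1,
              lower.tail = FALSE)
  list(p_value = p, proportion1 = k1 / n1, proportion2 = k2 / n2)
}

#' Gaussian kernel density of dominance scores
#'
#' Gaussian KDE on a fixed grid with the sample median, used to contrast
#' the dominance-score distributions of protein categories against the
#' control distribution of all quantified proteins. For (near-)constant
#' input, where the usual plug-in bandwidth collapses to zero, a small
#' positive floor is substituted and flagged.
#'
#' @param scores numeric vector, length >= 2.
#' @param bandwidth kernel bandwidth; `NULL` (default) uses Silverman's
#'   rule-of-thumb (`stats::bw.nrd0`).
#' @param n_grid number of grid points (default 512).
#' @param from,to grid range (defaults extend the data range by three
#'   bandwidths).
#' @return List of class `"kde_result"`: `x`, `y` (density values),
#'   `bandwidth`, `median`, `n`, `degenerate`.
#' @export
kde_dominance_density <- function(scores, bandwidth = NULL, n_grid = 512L,
                                  from = NULL, to = NULL) {
  scores <- scores[is.finite(scores)]
  if (length(scores) < 2L) stop("need at least 2 points", call. = FALSE)
  degenerate <- sd(scores) == 0
  bw <- bandwidth
  if (is.null(bw)) {
    bw <- if (degenerate) 0
          else tryCatch(stats::bw.nrd0(scores), error = function(e) 0)
  }
  if (!is.finite(bw) || bw <= 0) {
    bw <- max(1e-3, 1e-3 * max(abs(scores)))
    degenerate <- TRUE
  }
  if (is.null(from)) from <- min(scores) - 3 * bw
  if (is.null(to)) to <- max(scores) + 3 * bw
  d <- density(scores, bw = bw, n = n_grid, from = from, to = to)
  structure(list(x = d$x, y = d$y, bandwidth = bw,
                 median = median(scores), n = length(scores),
                 degenerate = degenerate),
            class = "kde_result")
}
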