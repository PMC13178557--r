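test_that("noiseless lines are fitted exactly", {
  x <- seq(-2, 3, length.out = 20)
  fit <- huber_fit(x, 2 * x + 1)
  expect_equal(fit$slope, 2, tolerance = 1e-6)
  expect_equal(fit$intercept, 1, tolerance = 1e-6)
  expect_true(fit$converged)
  expect_equal(huber_fit(x, x)$pearson_r, 1)
  expect_error(huber_fit(rep(1, 5), rnorm(5)), "degenerate design")
  expect_error(huber_fit(1:2, 1:2), "at least 3")
})

test_that("a gross outlier barely moves the Huber slope but drags OLS", {
  set.seed(17)
  x <- runif(50, 0, 10)
  y <- 2 * x + 0.5 + rnorm(50, 0, 0.05)
  x <- c(x, 5)
  y <- c(y, 2 * 5 + 100)  # single gross outlier
  hub <- huber_fit(x, y)
  ols <- ols_oracle(x, y)
  expect_lt(abs(hub$slope - 2), 0.05)
  expect_gt(abs(ols[["slope"]] - 2) + abs(ols[["intercept"]] - 0.5),
            abs(hub$slope - 2) + abs(hub$intercept - 0.5))
})

test_that("Huber fit approaches the OLS closed form as k grows", {
  set.seed(23)
  for (i in 1:10) {
    n <- sample(20:100, 1)
    x <- rnorm(n)
    y <- rnorm(1) + rnorm(1) * x + rnorm(n, 0, 0.5)
    fit <- huber_fit(x, y, k = 1e8)
    ols <- ols_oracle(x, y)
    expect_equal(fit$slope, unname(ols["slope"]), tolerance = 1e-6)
    expect_equal(fit$intercept, unname(ols["intercept"]), tolerance = 1e-6)
  }
})

test_that("Huber fit agrees with an independent robust-regression oracle", {
  skip_if_not_installed("MASS")
  set.seed(31)
  x <- rnorm(200)
  y <- 0.65 * x + 0.06 + rnorm(200, 0, 0.3)
  y[1:5] <- y[1:5] + 8  # contamination
  fit <- huber_fit(x, y)
  ref <- MASS::rlm(y ~ x, k2 = 1.345, maxit = 200)
  # different scale updates (per-iteration MAD here vs rlm's default), so
  # agreement is approximate
  expect_equal(fit$slope, unname(coef(ref)[2]), tolerance = 0.02)
  expect_equal(fit$intercept, unname(coef(ref)[1]), tolerance = 0.02)
})

test_that("bootstrap prediction bands are seeded and collapse when noiseless", {
  x <- seq(0, 1, length.out = 30)
  y <- 0.65 * x + 0.06
  ci <- bootstrap_prediction_ci(x, y, n_boot = 200, seed = 4)
  expect_equal(ci$ci_low, ci$fit, tolerance = 1e-8)
  expect_equal(ci$ci_high, ci$fit, tolerance = 1e-8)

  set.seed(50)
  y2 <- y + rnorm(30, 0, 0.2)
  c1 <- bootstrap_prediction_ci(x, y2, n_boot = 300, seed = 9)
  c2 <- bootstrap_prediction_ci(x, y2, n_boot = 300, seed = 9)
  expect_identical(c1, c2)
  c3 <- bootstrap_prediction_ci(x, y2, n_boot = 300, seed = 10)
  expect_false(identical(c1$ci_low, c3$ci_low))
  expect_true(all(c1$ci_low <= c1$ci_high))
  expect_warning(bootstrap_prediction_ci(x, y2, n_boot = 50, seed = 1),
                 "n_boot")
})

test_that("classification follows the stated dominance rule", {
  line <- huber_fit(c(-2, 0, 2, 4), 0.65 * c(-2, 0, 2, 4) + 0.06)
  eff <- data.frame(
    protein_id = c("cfc_hit", "tie", "ns", "ce_hit", "below_line"),
    effect_cfc = c(1.0, 0.5, 1.0, -1.0, 0.2),
    effect_ce = c(0.2, 0.5, 0.2, 0.5, 0.8),
    q_cfc = c(0.001, 0.001, 0.5, 0.5, 0.5),
    q_ce = c(0.5, 0.001, 0.5, 0.001, 0.001),
    stringsAsFactors = FALSE)
  dom <- classify_dominance(eff, line)
  expect_equal(dom$klass,
               c("CFC-dominant", "none", "none", "CE-dominant",
                 "CE-dominant"))
  # predicted value from the fitted line at the CFC effect size
  expect_equal(dom$predicted_ce[1], 0.65 * 1 + 0.06, tolerance = 1e-9)
  expect_equal(dom$dominance_score, eff$effect_cfc - eff$effect_ce)
  # mutual exclusivity and the score-sign/q invariants
  cfc <- dom$klass == "CFC-dominant"
  ce <- dom$klass == "CE-dominant"
  expect_false(any(cfc & ce))
  expect_true(all(dom$dominance_score[cfc] > 0 & dom$q_cfc[cfc] < 0.01))
  expect_true(all(dom$dominance_score[ce] < 0 & dom$q_ce[ce] < 0.01))
})

test_that("classification is order invariant and honours annotations", {
  set.seed(61)
  n <- 200
  eff <- data.frame(protein_id = sprintf("P%03d", 1:n),
                    effect_cfc = rnorm(n), effect_ce = rnorm(n),
                    q_cfc = runif(n), q_ce = runif(n),
                    stringsAsFactors = FALSE)
  fit <- huber_fit(eff$effect_cfc, eff$effect_ce)
  ann <- data.frame(protein_id = eff$protein_id[1:50],
                    syngo_location = rep(c("Presynapse", "Postsynapse",
                                           "Both", "Synapse"),
                                         length.out = 50),
                    stringsAsFactors = FALSE)
  d1 <- classify_dominance(eff, fit, ann)
  perm <- sample(n)
  d2 <- classify_dominance(eff[perm, ], fit, ann)
  d2 <- d2[match(d1$protein_id, d2$protein_id), ]
  rownames(d2) <- NULL
  expect_equal(d1$klass, d2$klass)
  expect_equal(d1$syngo_location, d2$syngo_location)
  expect_true(all(d1$syngo_location[51:n][match(eff$protein_id[51:n],
                                                d1$protein_id[51:n])]
                  == "None"))
  dd <- dominant_proteins(d1, syngo_only = TRUE)
  expect_true(all(dd$syngo_location != "None"))
  expect_true(all(dd$klass != "none"))
})

test_that("the alternative CE-residual reading differs only in the CFC clause", {
  line <- huber_fit(c(-2, 0, 2, 4), 0.5 * c(-2, 0, 2, 4))
  # CFC effect below the line but CE effect even lower
  eff <- data.frame(protein_id = "p", effect_cfc = 0.4, effect_ce = 0.1,
                    q_cfc = 0.001, q_ce = 0.5, stringsAsFactors = FALSE)
  # prediction at 0.4 is 0.2: observed CFC (0.4) > 0.2 -> dominant either way
  expect_equal(classify_dominance(eff, line)$klass, "CFC-dominant")
  expect_equal(classify_dominance(eff, line, rule = "ce_residual")$klass,
               "CFC-dominant")
  # flat protein right on the line: CE residual zero, not dominant
  eff2 <- data.frame(protein_id = "p", effect_cfc = 0.4, effect_ce = 0.2,
                     q_cfc = 0.001, q_ce = 0.5, stringsAsFactors = FALSE)
  expect_equal(classify_dominance(eff2, line, rule = "ce_residual")$klass,
               "none")
  expect_equal(classify_dominance(eff2, line)$klass, "CFC-dominant")
})

test_that("planted postsynaptic dominance is recovered with few null positives", {
  set.seed(71)
  res <- replicate(15, {
    cfg <- synth_proteome_config(n_proteins = 400, sigma_noise = 0.1,
                                 dominance_shift = 0.5,
                                 seed = sample.int(1e6, 1))
    sim <- generate_paired_abundances(cfg)
    cfc <- dea(sim$abundance, sim$meta, "CFC")
    ce <- dea(sim$abundance, sim$meta, "CE")
    eff <- merge_effect_tables(cfc, ce)
    fit <- huber_fit(eff$effect_cfc, eff$effect_ce)
    truth <- sim$truth[sim$truth$condition == "CFC", ]
    ann <- unique(truth[truth$compartment != "None",
                        c("protein_id", "compartment")])
    names(ann)[2] <- "syngo_location"
    dom <- classify_dominance(eff, fit, ann)
    planted_post <- truth$protein_id[truth$compartment == "Postsynapse"]
    nulls <- truth$protein_id[truth$compartment %in% c("None", "Synapse") &
                                truth$planted_class == "null"]
    sens <- mean(dom$klass[dom$protein_id %in% planted_post] ==
                   "CFC-dominant")
    fpr <- mean(dom$klass[dom$protein_id %in% nulls] != "none")
    c(sens, fpr)
  })
  expect_gte(mean(res[1, ]), 0.8)
  expect_lte(mean(res[2, ]), 0.05)
})

test_that("dominance scores centre on the planted mean shift", {
  # pool the raw log2FC dominance (CFC - CE) of shifted proteins over a
  # few replicates; its mean recovers the planted shift within 3 SEs
  d <- unlist(lapply(81:83, function(s) {
    cfg <- synth_proteome_config(n_proteins = 1000, sigma_noise = 0.1,
                                 frac_enriched = 0, frac_depleted = 0,
                                 dominance_shift = 0.5, seed = s)
    sim <- generate_paired_abundances(cfg)
    cfc <- dea(sim$abundance, sim$meta, "CFC")
    ce <- dea(sim$abundance, sim$meta, "CE")
    eff <- merge_effect_tables(cfc, ce)
    truth <- sim$truth[sim$truth$condition == "CFC", ]
    post <- eff$protein_id %in%
      truth$protein_id[truth$compartment == "Postsynapse"]
    eff$log2fc_cfc[post] - eff$log2fc_ce[post]
  }))
  expect_lt(abs(mean(d) - 0.5), 3 * sd(d) / sqrt(length(d)))
})
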