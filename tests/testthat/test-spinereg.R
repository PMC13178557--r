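test_that("point-to-polyline distance matches hand geometry", {
  seg <- rbind(c(-1, 0, 0), c(1, 0, 0))
  expect_equal(spot_to_filament_distance(c(-1, 0, 0), seg), 0)
  expect_equal(spot_to_filament_distance(c(0, 1, 0), seg), 1)
  expect_equal(spot_to_filament_distance(c(2, 1, 0), seg), sqrt(2))
  # degenerate zero-length segment is skipped
  tri <- rbind(c(0, 0, 0), c(0, 0, 0), c(1, 0, 0))
  expect_equal(spot_to_filament_distance(c(0.5, 2, 0), tri), 2)
  # polyline: nearest of several segments wins
  poly <- rbind(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0))
  expect_equal(spot_to_filament_distance(c(1.2, 0.5, 0), poly), 0.2)
})

test_that("distances are invariant under rigid rotation and translation", {
  set.seed(55)
  verts <- matrix(rnorm(30, sd = 500), 10, 3)
  pts <- matrix(rnorm(60, sd = 800), 20, 3)
  d0 <- vapply(seq_len(20),
               function(i) spot_to_filament_distance(pts[i, ], verts),
               numeric(1))
  for (rep in 1:5) {
    rot <- rotation_matrix(rnorm(3), runif(1, 0, 2 * pi))
    shift <- rnorm(3, sd = 1e4)
    vr <- sweep(verts %*% t(rot), 2, -shift)
    pr <- sweep(pts %*% t(rot), 2, -shift)
    d1 <- vapply(seq_len(20),
                 function(i) spot_to_filament_distance(pr[i, ], vr),
                 numeric(1))
    expect_equal(d1, d0, tolerance = 1e-6)
  }
})

test_that("registration uses strict distance, nearest-wins and id tie-break", {
  spines <- data.frame(spine_id = c("s1", "s2"),
                       x = c(0, 1000), y = 0, z = 0,
                       stringsAsFactors = FALSE)
  spots <- data.frame(spot_id = c("at", "far", "between"),
                      x = c(0, 701, 300), y = c(0, 0, 0), z = 0,
                      stringsAsFactors = FALSE)
  # single spine: exactly at -> assigned; 701 nm -> unassigned (strict <)
  reg1 <- register_spots(spots[1:2, ], spines[1, , drop = FALSE],
                         max_dist_nm = 700)
  expect_true(reg1$assigned[1])
  expect_false(reg1$assigned[2])
  expect_true(is.na(reg1$spine_id[2]))
  # 700 nm exactly is also out
  at700 <- data.frame(spot_id = "edge", x = 700, y = 0, z = 0)
  expect_false(register_spots(at700, spines[1, , drop = FALSE])$assigned)
  # two candidates at 300 and 700: nearest (s1) wins
  reg2 <- register_spots(spots[3, , drop = FALSE], spines)
  expect_equal(reg2$spine_id, "s1")
  # exact tie at 500/500 resolves to the lower spine id
  mid <- data.frame(spot_id = "mid", x = 500, y = 0, z = 0)
  expect_equal(register_spots(mid, spines)$spine_id, "s1")
  expect_equal(register_spots(mid, spines[2:1, ])$spine_id, "s1")
})

test_that("registration count is monotone in the distance cutoff", {
  g <- generate_geometry(synth_geometry_config(n_dendrites = 4,
                                               spines_per_dendrite = 8,
                                               spot_jitter_nm = 400,
                                               seed = 21))
  yfp <- g$spots[g$spots$channel == "YFP", ]
  counts <- vapply(c(100, 300, 500, 700, 1500), function(md) {
    sum(register_spots(yfp, g$spines, max_dist_nm = md)$assigned)
  }, numeric(1))
  expect_true(all(diff(counts) >= 0))
})

test_that("channel pre-filter keeps true spots and drops distant ones", {
  g <- generate_geometry(synth_geometry_config(n_dendrites = 3,
                                               spines_per_dendrite = 10,
                                               spot_jitter_nm = 0,
                                               seed = 22))
  far <- data.frame(spot_id = "bg", channel = "YFP",
                    x = max(g$traces$x) + 1e5, y = 0, z = 0,
                    integrated_intensity = NA_real_,
                    average_intensity = NA_real_, spine_id = NA,
                    stringsAsFactors = FALSE)
  kept <- filter_spots_by_filament(rbind(g$spots, far), g$traces)
  expect_false("bg" %in% kept$spot_id)
  # jitter-free spine terminals sit 50-150 nm from the shaft polyline,
  # inside both the 500 nm (eGRASP) and 200 nm (Grm5) gates
  expect_equal(sum(kept$channel == "YFP"), sum(g$spots$channel == "YFP"))
  expect_equal(sum(kept$channel == "GRM5"), sum(g$spots$channel == "GRM5"))
  expect_error(filter_spots_by_filament(
    data.frame(spot_id = "x", channel = "TDT", x = 0, y = 0, z = 0),
    g$traces), "threshold")
})

test_that("overlap percentages match hand counts and planted fractions", {
  spines <- data.frame(spine_id = sprintf("s%02d", 1:10),
                       dendrite_id = "d1", stringsAsFactors = FALSE)
  assignments <- data.frame(
    spot_id = sprintf("x%02d", 1:16),
    channel = c(rep("YFP", 10), rep("CFP", 6)),
    spine_id = c(sprintf("s%02d", 1:10), sprintf("s%02d", 1:6)),
    distance = 10, assigned = TRUE, stringsAsFactors = FALSE)
  ov <- classify_and_overlap(spines, assignments)
  expect_equal(ov$per_dendrite$pct_cfp_of_yfp, 60)
  expect_equal(ov$per_dendrite$pct_yfp_of_cfp, 100)
  # all dual-labelled -> both percentages 100
  dual <- assignments
  dual$channel <- rep(c("YFP", "CFP"), 8)
  dual$spine_id <- rep(sprintf("s%02d", 1:8), each = 2)
  ov2 <- classify_and_overlap(spines[1:8, ], dual)
  expect_equal(ov2$per_dendrite$pct_cfp_of_yfp, 100)
  expect_equal(ov2$per_dendrite$pct_yfp_of_cfp, 100)
})

test_that("planted CFP fraction is recovered end to end within 2 binomial SEs", {
  g <- generate_geometry(synth_geometry_config(n_dendrites = 100,
                                               spines_per_dendrite = 10,
                                               frac_cfp_positive = 0.6,
                                               seed = 23))
  kept <- filter_spots_by_filament(g$spots, g$traces)
  reg <- register_spots(kept, g$spines)
  ov <- classify_and_overlap(g$spines, reg)
  se_pct <- 100 * sqrt(0.6 * 0.4 / 1000)
  expect_lt(abs(ov$pooled$cfp_of_yfp[["mean"]] - 60), 2 * se_pct)
})

test_that("colocalization OR equals the cross product and the logistic identity", {
  cls <- c(rep("EE", 100), rep("NE", 100))
  pres <- c(rep(TRUE, 60), rep(FALSE, 40), rep(TRUE, 40), rep(FALSE, 60))
  dend <- rep(sprintf("d%d", 1:20), each = 10)
  anim <- rep(sprintf("a%d", 1:5), each = 40)
  or <- colocalization_or(cls, pres, dend, anim, n_boot = 200, seed = 3)
  expect_equal(or$or, (60 * 60) / (40 * 40), tolerance = 1e-12)
  expect_false(or$corrected)
  # logistic single-predictor identity on the same counts
  glmfit <- glm(pres ~ I(cls == "EE"), family = binomial)
  expect_equal(or$or, exp(unname(coef(glmfit)[2])), tolerance = 1e-6)
  # zero cell -> Haldane-Anscombe correction, flagged
  pres0 <- c(rep(TRUE, 100), rep(FALSE, 100))
  or0 <- colocalization_or(cls, pres0, dend, anim, n_boot = 50, seed = 4)
  expect_true(or0$corrected)
  expect_true(is.finite(or0$or))
  # determinism
  or2 <- colocalization_or(cls, pres, dend, anim, n_boot = 200, seed = 3)
  expect_identical(or[c("or", "ci_low", "ci_high")],
                   or2[c("or", "ci_low", "ci_high")])
})

test_that("equal presence probabilities give an OR interval containing 1", {
  set.seed(66)
  n <- 400
  cls <- sample(c("EE", "NE"), n, replace = TRUE)
  pres <- runif(n) < 0.4
  dend <- sample(sprintf("d%d", 1:40), n, replace = TRUE)
  anim <- sprintf("a%d", as.integer(factor(dend)) %% 5 + 1)
  or <- colocalization_or(cls, pres, dend, anim, n_boot = 400, seed = 8)
  expect_true(or$ci_low <= 1 && 1 <= or$ci_high)
})

test_that("puncta intensity summaries follow log identities", {
  spots <- data.frame(spine_class = "EE",
                      integrated_intensity = exp(c(8, 9, 10)),
                      average_intensity = exp(c(1, 1, 1)),
                      stringsAsFactors = FALSE)
  s <- puncta_intensity_summary(spots)
  expect_equal(s$log_median_integrated, 9)
  expect_equal(s$log_iqr_average, 0)
  # scaling all intensities by c shifts the log median by log(c) exactly
  spots2 <- spots
  spots2$integrated_intensity <- spots2$integrated_intensity * 5
  s2 <- puncta_intensity_summary(spots2)
  expect_equal(s2$log_median_integrated - s$log_median_integrated, log(5))
  expect_equal(s2$log_iqr_integrated, s$log_iqr_integrated)
  # empty class skipped with a message
  spots3 <- rbind(spots, data.frame(spine_class = "NE",
                                    integrated_intensity = NA_real_,
                                    average_intensity = NA_real_))
  expect_message(s3 <- puncta_intensity_summary(spots3), "skipped")
  expect_equal(s3$spine_class, "EE")
})

test_that("planted Grm5 odds ratio is recovered by the cluster bootstrap", {
  set.seed(88)
  covered <- replicate(25, {
    g <- generate_geometry(synth_geometry_config(
      n_dendrites = 60, spines_per_dendrite = 10,
      frac_cfp_positive = 0.5, p_grm5_given_EE = 0.6,
      p_grm5_given_NE = 0.4, seed = sample.int(1e6, 1)))
    kept <- filter_spots_by_filament(g$spots, g$traces)
    reg <- register_spots(kept, g$spines)
    ov <- classify_and_overlap(g$spines, reg)
    flags <- ov$spine_flags
    yfp <- flags[flags$yfp, ]
    cls <- ifelse(yfp$cfp, "EE", "NE")
    grm5_hits <- unique(reg$spine_id[reg$assigned & reg$channel == "GRM5"])
    pres <- yfp$spine_id %in% grm5_hits
    anim <- g$spines$animal_id[match(yfp$spine_id, g$spines$spine_id)]
    or <- colocalization_or(cls, pres, yfp$dendrite_id, anim,
                            n_boot = 300, seed = 1)
    or$ci_low <= 2.25 && 2.25 <= or$ci_high
  })
  expect_gte(mean(covered), 0.9)
})
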