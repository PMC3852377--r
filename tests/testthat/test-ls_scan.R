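make_scan_fixture <- function(seed = 50, n = 250, a = 0.8, d = 0.3,
                              step = 2.5, ...) {
  sim <- simulate_cross(sim_config(
    seed = seed, n_offspring = n,
    chromosomes = data.frame(length_cM = 100, n_markers = 21),
    qtl = if (a != 0 || d != 0) list(qtl_spec("chr1", 50, a = a, d = d)) else list(),
    ...))
  probs <- line_origin_probs(sim$cross, step_cM = step)
  list(sim = sim, probs = probs, pred = genetic_predictors(probs))
}

test_that("genetic predictors code the posterior correctly", {
  fx <- make_scan_fixture(n = 60, a = 0)
  ch <- fx$pred$chromosomes$chr1
  p <- fx$probs$chromosomes$chr1$prob
  expect_equal(ch$a, p[, , "AA"] - p[, , "BB"])
  expect_equal(ch$d, p[, , "AB"] + p[, , "BA"])
  expect_true(all(abs(ch$a) + ch$d <= 1 + 1e-9))
  # with dense informative markers the predictors match the truth codes
  tp <- true_predictors(fx$sim$truth, "chr1", 50)
  k <- which(abs(ch$positions - 50) < 1e-9)
  expect_lt(mean(abs(ch$a[tp$id, k] - tp$a)), 0.05)
  # BC: single predictor, no dominance column
  simbc <- simulate_cross(sim_config(seed = 3, n_offspring = 40,
                                     cross_type = "BC",
                                     chromosomes = data.frame(length_cM = 50,
                                                              n_markers = 6)))
  prbc <- line_origin_probs(simbc$cross, step_cM = 10)
  pdbc <- genetic_predictors(prbc)
  expect_null(pdbc$chromosomes$chr1$d)
  expect_equal(pdbc$q, 1L)
})

test_that("noise-free phenotype at an informative position gives a capped perfect fit", {
  fx <- make_scan_fixture(seed = 51, n = 150, a = 0, step = 5)
  cross <- fx$sim$cross
  tp <- true_predictors(fx$sim$truth, "chr1", 50)
  cross$phenotypes$w <- tp$a[match(cross$phenotypes$id, tp$id)]
  probs0 <- line_origin_probs(cross, step_cM = 5, error_rate = 0)
  prof <- scan_one(cross, genetic_predictors(probs0), "w")
  at50 <- prof[abs(prof$position - 50) < 1e-9, ]
  expect_equal(at50$F, 1e12)
  expect_match(at50$note, "perfect_fit")
  expect_equal(at50$alpha, 1, tolerance = 1e-6)
  expect_equal(at50$delta, 0, tolerance = 1e-6)
})

test_that("scan localises a simulated QTL and estimates its effects", {
  fx <- make_scan_fixture(seed = 52, n = 400, a = 0.8, d = 0.4)
  prof <- scan_one(fx$sim$cross, fx$pred, "w", covariates = "sex")
  best <- prof[which.max(prof$F), ]
  expect_lt(abs(best$position - 50), 10)
  at50 <- prof[abs(prof$position - 50) < 1e-9, ]
  expect_lt(abs(at50$alpha - 0.8), 3.5 * at50$se_alpha)
  expect_lt(abs(at50$delta - 0.4), 3.5 * at50$se_delta)
  expect_equal(at50$df1, 2)
})

test_that("F statistic is invariant to affine trait transforms", {
  fx <- make_scan_fixture(seed = 53, n = 120, a = 0.5)
  cross <- fx$sim$cross
  p1 <- scan_one(cross, fx$pred, "w")
  cross$phenotypes$w <- -2.5 * cross$phenotypes$w + 7
  p2 <- scan_one(cross, fx$pred, "w")
  expect_equal(p1$F, p2$F, tolerance = 1e-8)
})

test_that("null-trait F has the central F moments", {
  fs <- c()
  for (s in 1:50) {
    sim <- simulate_cross(sim_config(
      seed = 300 + s, n_offspring = 120,
      chromosomes = data.frame(length_cM = 50, n_markers = 6)))
    probs <- line_origin_probs(sim$cross, positions = list(chr1 = 25))
    pred <- genetic_predictors(probs)
    prof <- scan_one(sim$cross, pred, "w")
    fs <- c(fs, prof$F)
  }
  m <- 120 - 3
  expect_equal(mean(fs), m / (m - 2), tolerance = 0.25)
})

test_that("permutation machinery: determinism, multiset preservation, quantiles", {
  fx <- make_scan_fixture(seed = 54, n = 100, a = 0, step = 10)
  cross <- fx$sim$cross
  pd1 <- permutation_thresholds(cross, fx$pred, "w", n_perm = 50, seed = 9)
  pd2 <- permutation_thresholds(cross, fx$pred, "w", n_perm = 50, seed = 9)
  expect_identical(pd1$max_stats, pd2$max_stats)
  expect_true(all(diff(pd1$thresholds) >= 0))
  expect_equal(unname(pd1$thresholds),
               unname(quantile(pd1$max_stats, pd1$quantiles, type = 7)))
  expect_error(permutation_thresholds(cross, fx$pred, "w", quantiles = 1.2),
               "quantiles")
  # scan_fn route sees exact permutations of the trait values
  seen <- new.env(); seen$ok <- TRUE
  y0 <- sort(lcq:::analysis_design(cross, "w")$y)
  pd3 <- permutation_thresholds(cross, fx$pred, "w", n_perm = 5, seed = 2,
                                scan_fn = function(y) {
                                  if (!isTRUE(all.equal(sort(y), y0))) seen$ok <- FALSE
                                  max(abs(y))
                                })
  expect_true(seen$ok)
  # the fast path agrees with a literal rescan
  pd4 <- permutation_thresholds(cross, fx$pred, "w", n_perm = 8, seed = 5)
  pd5 <- permutation_thresholds(cross, fx$pred, "w", n_perm = 8, seed = 5,
                                scan_fn = function(y) {
                                  cr <- cross
                                  cr$phenotypes$w[match(lcq:::analysis_design(cross, "w")$ids,
                                                        cr$phenotypes$id)] <- y
                                  max(scan_one(cr, fx$pred, "w")$F)
                                })
  expect_equal(pd4$max_stats, pd5$max_stats, tolerance = 1e-8)
})

test_that("epistasis scan: proximity guard, symmetry of the pair grid, recovery", {
  sim <- simulate_cross(sim_config(
    seed = 60, n_offspring = 500,
    chromosomes = data.frame(length_cM = c(60, 60), n_markers = c(7, 7)),
    qtl = list(qtl_spec("chr1", 30, a = 0, d = 0, partner = 2, aa = 1),
               qtl_spec("chr2", 30, a = 0, d = 0))))
  probs <- line_origin_probs(sim$cross, step_cM = 5)
  pred <- genetic_predictors(probs)
  es <- scan_two_epistasis(sim$cross, pred, "w", pair_step_cM = 10)
  same <- es$chromosome1 == es$chromosome2
  expect_true(all(abs(es$position1[same] - es$position2[same]) >= 20))
  best <- es[which.max(es$F), ]
  expect_true(best$chromosome1 != best$chromosome2)
  expect_lt(abs(best$position1 - 30), 15)
  expect_lt(abs(best$position2 - 30), 15)
  expect_equal(best$df1, 4)
  expect_lt(abs(best$aa - 1), 0.3)
  # marginal scan shows no strong peak (pure epistasis)
  prof <- scan_one(sim$cross, pred, "w")
  expect_lt(max(prof$F), max(es$F))
})

test_that("sex-chromosome scan uses only homogametic offspring", {
  map <- data.frame(chromosome = "X", marker = c("x1", "x2"),
                    position_cM = c(0, 10), kind = "sex")
  cross <- toy_cross(f2_geno = list(F2_1 = c(1, 1, 1, 1), F2_2 = c(1, 2, 1, 2),
                                    F2_3 = c(2, 2, 2, 2), F2_4 = c(1, 2, 1, 2),
                                    F2_5 = c(1, 1, 2, 2), F2_6 = c(1, 2, 1, 1)),
                    map = map, sex_chromosome = "X")
  probs <- line_origin_probs(cross, step_cM = 10)
  pred <- genetic_predictors(probs)
  prof <- scan_one(cross, pred, "w")
  # 3 homogametic (female) offspring analysed, intercept + a + d fitted
  expect_equal(unique(prof$df2), 3 - prof$df1[1] - 1)
})
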