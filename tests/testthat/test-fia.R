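test_that("MCIBD converges to the exhaustive enumeration on a toy pedigree", {
  set.seed(1)
  cross <- toy_ibd_cross(3)
  want <- enum_ibd_oracle(list(c(A = "A1", B = "B1"), c(A = "A2", B = "B1")), 3)
  Pi <- mcibd_matrix(cross, "chr1", 5, n_samples = 1500, seed = 7)
  expect_lt(max(abs(unclass(Pi) - want)), 0.04)
  # structure: symmetric, diagonal in [1,2], PSD
  expect_equal(unclass(Pi), t(unclass(Pi)))
  expect_true(all(diag(Pi) >= 1 - 1e-9 & diag(Pi) <= 2 + 1e-9))
  expect_gt(min(eigen(Pi, symmetric = TRUE, only.values = TRUE)$values), -1e-8)
  # shared founder B1: the maternal gametes of two sibs are IBD with
  # probability 1/2, so the oracle off-diagonals must exceed 1/2
  expect_true(all(want[upper.tri(want)] > 0.5))
})

test_that("disjoint families have exactly zero IBD across families", {
  sim <- simulate_cross(sim_config(
    seed = 14, n_offspring = 20, founders_per_line = 4, n_f1 = 4,
    chromosomes = data.frame(length_cM = 40, n_markers = 5)))
  cross <- sim$cross
  ped <- cross$pedigree
  Pi <- mcibd_matrix(cross, "chr1", 20, n_samples = 150, seed = 3)
  fam <- paste(ped$sire[match(rownames(Pi), ped$id)],
               ped$dam[match(rownames(Pi), ped$id)])
  across <- outer(fam, fam, "!=")
  expect_equal(max(abs(Pi[across])), 0)
})

test_that("truth-mode IBD from founder labels matches the MC estimate", {
  sim <- simulate_cross(sim_config(
    seed = 15, n_offspring = 40, allele_model = "founder_unique",
    chromosomes = data.frame(length_cM = 40, n_markers = 9)))
  pos <- 20   # marker position: descent fully observable
  want <- mcibd_truth(sim$truth, "chr1", pos)
  Pi <- mcibd_matrix(sim$cross, "chr1", pos, n_samples = 400, seed = 5)
  expect_lt(max(abs(unclass(Pi) - want[rownames(Pi), colnames(Pi)])), 0.05)
})

test_that("REML variance components: degenerate kinship, scaling, grid oracle", {
  set.seed(2)
  n <- 120
  X <- cbind(1, rnorm(n))
  y <- rnorm(n)
  fit <- fit_variance_components(y, X, diag(n))
  expect_equal(fit$lambda, 0)
  expect_equal(fit$flag, "boundary")
  # a structured Pi with real signal
  sim <- simulate_cross(sim_config(
    seed = 16, n_offspring = n, n_f1 = 6,
    chromosomes = data.frame(length_cM = 40, n_markers = 5)))
  Pi <- mcibd_matrix(sim$cross, "chr1", 20, n_samples = 200, seed = 2)
  L <- chol(unclass(Pi) + 1e-8 * diag(n))
  y2 <- drop(crossprod(L, rnorm(n))) + rnorm(n)
  P <- unclass(Pi)
  f1 <- fit_variance_components(y2, X, P)
  f2 <- fit_variance_components(2 * y2, X, P)
  expect_equal(f2$sigma2_g, 4 * f1$sigma2_g, tolerance = 1e-4)
  expect_equal(f2$sigma2_e, 4 * f1$sigma2_e, tolerance = 1e-6)
  # dense grid search over lambda agrees with the 1-D optimiser
  e <- eigen(P, symmetric = TRUE)
  tU <- t(e$vectors)
  grid <- seq(0, 5, by = 1e-3)
  ll <- vapply(grid, lcq:::reml_loglik_spectral, numeric(1),
               dvals = pmax(e$values, 0), tX = tU %*% X,
               ty = drop(tU %*% y2), n = n, p = 2L)
  expect_lt(abs(f1$lambda - grid[which.max(ll)]), 1e-3 + 1e-4)
  expect_gte(f1$loglik + 1e-8, max(ll) - 1e-6)
})

test_that("REML recovers known variance components on average", {
  set.seed(3)
  sim <- simulate_cross(sim_config(
    seed = 17, n_offspring = 250, n_f1 = 8,
    chromosomes = data.frame(length_cM = 40, n_markers = 5)))
  Pi <- unclass(mcibd_matrix(sim$cross, "chr1", 20, n_samples = 300, seed = 4))
  n <- nrow(Pi)
  L <- chol(Pi + 1e-8 * diag(n))
  X <- matrix(1, n, 1)
  est <- replicate(30, {
    y <- drop(crossprod(L, rnorm(n))) + rnorm(n)
    f <- fit_variance_components(y, X, Pi)
    c(f$sigma2_g, f$sigma2_e)
  })
  expect_lt(abs(median(est[1, ]) - 1), 0.35)
  expect_lt(abs(median(est[2, ]) - 1), 0.25)
})

test_that("score statistic: identity kinship, affine invariance, monotonicity", {
  set.seed(5)
  n <- 100
  X <- cbind(1, rnorm(n))
  y <- rnorm(n)
  expect_equal(fia_score(y, X, diag(n)), 0, tolerance = 1e-10)
  sim <- simulate_cross(sim_config(
    seed = 18, n_offspring = n, n_f1 = 6,
    chromosomes = data.frame(length_cM = 40, n_markers = 5)))
  Pi <- unclass(mcibd_matrix(sim$cross, "chr1", 20, n_samples = 200, seed = 6))
  u1 <- fia_score(y, X, Pi)
  u2 <- fia_score(3 * y - 11, X, Pi)
  expect_equal(u1, u2, tolerance = 1e-8)
  # signal along the leading eigenvector of the projected kinship (the
  # raw leading eigenvector is near-constant and absorbed by the
  # intercept) drives the score up
  M <- diag(n) - X %*% solve(crossprod(X), t(X))
  v1 <- eigen(M %*% Pi %*% M, symmetric = TRUE)$vectors[, 1]
  us <- vapply(c(0, 2, 4, 8), function(c0) fia_score(y + c0 * v1, X, Pi),
               numeric(1))
  expect_true(all(diff(us) > 0))
})

test_that("null score statistic is approximately standardised", {
  set.seed(6)
  sim <- simulate_cross(sim_config(
    seed = 19, n_offspring = 200, n_f1 = 8,
    chromosomes = data.frame(length_cM = 40, n_markers = 5)))
  Pi <- unclass(mcibd_matrix(sim$cross, "chr1", 20, n_samples = 200, seed = 7))
  n <- nrow(Pi)
  X <- matrix(1, n, 1)
  Y <- matrix(rnorm(n * 1000), n, 1000)
  u <- lcq:::fia_score_multi(Y, X, Pi)
  expect_lt(abs(mean(u)), 0.1)
  expect_gt(var(u), 0.7)
  expect_lt(var(u), 1.3)
})

test_that("segregation LR is exactly zero when the matrices coincide", {
  set.seed(8)
  sim <- simulate_cross(sim_config(
    seed = 20, n_offspring = 60,
    chromosomes = data.frame(length_cM = 40, n_markers = 5)))
  des <- lcq:::analysis_design(sim$cross, "w")
  pr <- line_origin_probs(sim$cross, positions = list(chr1 = 20))
  pm <- pr$chromosomes$chr1$prob[des$ids, 1, ]
  Pi_lc <- lcq:::psd_repair(ibd_line_cross(pm))
  sl <- segregation_lr(des$y, des$X, Pi_lc, pm)
  expect_equal(sl$lr, 0, tolerance = 1e-6)
})

test_that("fia_scan co-locates with the least-squares scan for a fixed QTL", {
  hits <- 0L
  for (s in 1:4) {
    sim <- simulate_cross(sim_config(
      seed = 500 + s, n_offspring = 200, n_f1 = 6,
      chromosomes = data.frame(length_cM = 100, n_markers = 21),
      qtl = list(qtl_spec("chr1", 50, a = 1, d = 0))))
    fr <- fia_scan(sim$cross, "w", step_cM = 10, n_samples = 80,
                   seed = s, reml = FALSE)
    probs <- line_origin_probs(sim$cross, step_cM = 10)
    prof <- scan_one(sim$cross, genetic_predictors(probs), "w")
    p_fia <- fr$table$position[which.max(fr$table$score)]
    p_ls <- prof$position[which.max(prof$F)]
    if (abs(p_fia - p_ls) <= 10) hits <- hits + 1L
  }
  expect_gte(hits, 3L)
})

test_that("Pi is seed-stable within Monte-Carlo error", {
  cross <- toy_ibd_cross(4)
  reps <- lapply(1:6, function(s)
    unclass(mcibd_matrix(cross, "chr1", 5, n_samples = 400, seed = s)))
  m <- Reduce(`+`, reps) / length(reps)
  sds <- sqrt(Reduce(`+`, lapply(reps, function(r) (r - m)^2)) / (length(reps) - 1))
  for (r in reps) expect_true(all(abs(r - m) <= 4 * pmax(sds, 0.01)))
})
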