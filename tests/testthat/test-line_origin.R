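test_that("line frequency estimation: counting formula, fallback, positivity", {
  cross <- toy_cross()
  lf <- estimate_line_freqs(cross)
  # 2 line-A founders, all 1/1, alleles {1,2} observed: (4+0.5)/(4+1)
  expect_equal(lf$markers$m1$A[1], 4.5 / 5)
  expect_equal(lf$markers$m1$B[2], 4.5 / 5)
  expect_true(all(unlist(lapply(lf$markers, function(m) c(m$A, m$B))) > 0))
  # founders ungenotyped at a marker -> pooled, then uniform fallback
  g <- cross$genotypes
  g[c("A1", "A2", "B1", "B2"), c("m1_1", "m1_2")] <- 0L
  cross2 <- cross
  cross2$genotypes <- g
  lf2 <- estimate_line_freqs(cross2)
  expect_equal(lf2$markers$m1$A, lf2$markers$m1$B)
  expect_equal(sum(lf2$markers$m1$A), 1)
})

test_that("F1 homolog distributions: forced phase, Bayes weighting, missing data", {
  cross <- toy_cross()
  hd <- infer_f1_homolog_dists(cross)
  H <- hd$H$F1a[[1]]
  expect_equal(unname(H["1", "A"]), 1)   # A-homolog carries allele 1
  expect_equal(unname(H["2", "B"]), 1)
  # ungenotyped parents: posterior odds from line frequencies
  g <- cross$genotypes
  g[c("A1", "B1"), ] <- 0L
  cross2 <- cross
  cross2$genotypes <- g
  lf <- estimate_line_freqs(cross2)
  pa <- lf$markers$m1$A[1]   # freq of allele 1 in line A (from A2 only)
  pb <- lf$markers$m1$B[1]
  hd2 <- infer_f1_homolog_dists(cross2, lf)
  want <- pa * (1 - pb) / (pa * (1 - pb) + (1 - pa) * pb)
  expect_equal(unname(hd2$H$F1a[[1]]["1", "A"]), want, tolerance = 1e-12)
  # F1 genotype missing: unconstrained parental transmission (A1 is 1/1,
  # so the A-homolog distribution is a point mass on allele 1)
  g2 <- cross$genotypes
  g2["F1a", c("m1_1", "m1_2")] <- 0L
  cross3 <- cross
  cross3$genotypes <- g2
  hd3 <- infer_f1_homolog_dists(cross3)
  expect_equal(unname(hd3$H$F1a[[1]][, "A"]), c(1, 0), tolerance = 1e-12)
  # and with the parent also ungenotyped, the line frequencies
  g2[c("A1", "A2"), c("m1_1", "m1_2")] <- 0L
  cross4 <- cross
  cross4$genotypes <- g2
  lf4 <- estimate_line_freqs(cross4)
  hd4 <- infer_f1_homolog_dists(cross4, lf4)
  expect_equal(unname(hd4$H$F1a[[1]][, "A"]), lf4$markers$m1$A, tolerance = 1e-12)
})

test_that("non-Mendelian F1 genotypes produce a finding, not an error", {
  cross <- toy_cross()
  g <- cross$genotypes
  g["F1a", c("m1_1", "m1_2")] <- c(3L, 3L)   # impossible from 1/1 x 2/2
  cross$genotypes <- g
  hd <- infer_f1_homolog_dists(cross)
  expect_true(any(hd$findings$location == "F1a"))
})

test_that("all-missing individual recovers the prior at every grid point", {
  sim <- quick_sim(seed = 21, n = 8)
  cross <- sim$cross
  id <- sim$truth$offspring[1]
  cross$genotypes[id, ] <- 0L
  probs <- line_origin_probs(cross, step_cM = 10)
  p <- probs$chromosomes$chr1$prob[id, , ]
  expect_equal(unname(p), matrix(0.25, nrow(p), 4), tolerance = 1e-12)
})

test_that("fully informative homozygous offspring gives a point-mass posterior", {
  cross <- toy_cross(f2_geno = list(F2_1 = c(1, 1, 1, 1), F2_2 = c(2, 2, 2, 2)))
  probs <- line_origin_probs(cross, step_cM = 5, error_rate = 0)
  p <- probs$chromosomes$chr1$prob
  # point mass where the grid point coincides with an informative marker;
  # between markers a double recombinant retains small probability
  expect_equal(unname(p["F2_1", c(1, 3), "AA"]), c(1, 1), tolerance = 1e-12)
  expect_equal(unname(p["F2_2", c(1, 3), "BB"]), c(1, 1), tolerance = 1e-12)
  expect_gt(p["F2_1", 2, "AA"], 0.98)
})

test_that("forward-backward equals exhaustive enumeration (F2 and BC)", {
  for (i in 1:8) {
    ct <- if (i %% 2 == 0) "BC" else "F2"
    sim <- simulate_cross(sim_config(
      seed = 100 + i, n_offspring = 4, cross_type = ct,
      chromosomes = data.frame(length_cM = 10 * (2 + i %% 4),
                               n_markers = 2 + i %% 4),
      allele_model = "shared", p_A = 0.85, p_B = 0.15,
      epsilon_obs = 0.1))
    cross <- sim$cross
    extra <- c(1.7, 7.3)
    probs <- line_origin_probs(cross, positions = list(chr1 = extra))
    for (id in sim$truth$offspring[1:2]) {
      bf <- brute_force_origin_posterior(cross, id, "chr1", positions = extra)
      expect_equal(unname(probs$chromosomes$chr1$prob[id, , ]), unname(bf),
                   tolerance = 1e-10)
    }
  }
})

test_that("posterior is invariant to chromosome mirroring", {
  sim <- simulate_cross(sim_config(
    seed = 33, n_offspring = 6,
    chromosomes = data.frame(length_cM = 40, n_markers = 5),
    allele_model = "shared", p_A = 0.8, p_B = 0.2))
  cross <- sim$cross
  L <- 40
  grid <- c(0, 13, 27, 40)
  p1 <- line_origin_probs(cross, positions = list(chr1 = grid))
  # mirror: reverse marker order and positions
  map2 <- cross$map
  map2$position_cM <- L - rev(map2$position_cM)
  map2$marker <- rev(map2$marker)
  g2 <- cross$genotypes
  cols <- as.vector(rbind(paste0(map2$marker, "_1"), paste0(map2$marker, "_2")))
  mirrored <- cross_data(cross$pedigree, g2[, cols], map2, cross$phenotypes,
                         cross_type = "F2")
  p2 <- line_origin_probs(mirrored, positions = list(chr1 = L - rev(grid)))
  a1 <- p1$chromosomes$chr1$prob
  a2 <- p2$chromosomes$chr1$prob
  for (k in seq_along(grid)) {
    expect_equal(a1[, k, ], a2[, length(grid) + 1 - k, ], tolerance = 1e-10)
  }
})

test_that("informative markers give higher confidence in the true state", {
  mean_true_prob <- function(model, seed) {
    sim <- simulate_cross(sim_config(
      seed = seed, n_offspring = 60,
      chromosomes = data.frame(length_cM = 50, n_markers = 6),
      allele_model = model, p_A = 0.7, p_B = 0.3))
    probs <- line_origin_probs(sim$cross, positions = list(chr1 = 25))
    p <- probs$chromosomes$chr1$prob[, 1, ]
    o <- truth_origin(sim$truth, "chr1", 25)
    truth_state <- match(paste0(o[, 1], o[, 2]), c("AA", "AB", "BA", "BB"))
    # unordered credit: heterozygous truth accepts AB+BA
    val <- numeric(nrow(p))
    for (i in seq_len(nrow(p))) {
      val[i] <- if (truth_state[i] %in% c(2, 3)) p[i, 2] + p[i, 3]
                else p[i, truth_state[i]]
    }
    mean(val)
  }
  expect_gt(mean_true_prob("line_private", 55), mean_true_prob("shared", 55))
})

test_that("a 1000-marker chromosome stays numerically finite", {
  sim <- simulate_cross(sim_config(
    seed = 77, n_offspring = 4,
    chromosomes = data.frame(length_cM = 100, n_markers = 1000),
    allele_model = "shared", p_A = 0.9, p_B = 0.1))
  probs <- line_origin_probs(sim$cross, step_cM = 20)
  p <- probs$chromosomes$chr1$prob
  expect_true(all(is.finite(p)))
  expect_equal(max(abs(apply(p, c(1, 2), sum) - 1)), 0, tolerance = 1e-9)
})

test_that("path sampler: point-mass, determinism, marginal consistency", {
  cross <- toy_cross(f2_geno = list(F2_1 = c(1, 1, 1, 1), F2_2 = c(1, 2, 1, 2)))
  s1 <- sample_origin_paths(cross, n_samples = 20, seed = 5, error_rate = 0)
  # homozygous-A offspring: every sampled path is all state 1 (AA)
  expect_true(all(s1$chr1$states["F2_1", , ] == 1L))
  s2 <- sample_origin_paths(cross, n_samples = 20, seed = 5, error_rate = 0)
  expect_identical(s1, s2)

  # empirical state frequencies match forward-backward marginals
  sim <- simulate_cross(sim_config(
    seed = 41, n_offspring = 3,
    chromosomes = data.frame(length_cM = 30, n_markers = 3),
    allele_model = "shared", p_A = 0.8, p_B = 0.2))
  n <- 6000
  sp <- sample_origin_paths(sim$cross, n_samples = n, seed = 2)
  probs <- line_origin_probs(sim$cross,
                             positions = list(chr1 = sp$chr1$positions))
  id <- sim$truth$offspring[1]
  for (t in seq_along(sp$chr1$positions)) {
    emp <- tabulate(sp$chr1$states[id, t, ], nbins = 4) / n
    thr <- probs$chromosomes$chr1$prob[id, t, ]
    se <- sqrt(pmax(thr * (1 - thr), 1e-12) / n)
    expect_true(all(abs(emp - thr) <= pmax(3 * se, 5e-3)))
  }
  expect_error(sample_origin_paths(cross, n_samples = 0), "n_samples")
})

test_that("sex-chromosome inference processes only homogametic offspring", {
  map <- data.frame(chromosome = "X", marker = c("x1", "x2"),
                    position_cM = c(0, 10), kind = "sex")
  cross <- toy_cross(f2_geno = list(F2_1 = c(1, 1, 1, 1), F2_2 = c(2, 2, 2, 2)),
                     map = map, sex_chromosome = "X")
  # F2_1 is female (homogametic when males are heterogametic), F2_2 male
  probs <- line_origin_probs(cross, step_cM = 10)
  p <- probs$chromosomes$X$prob
  expect_false(anyNA(p["F2_1", , ]))
  expect_true(all(is.na(p["F2_2", , ])))
})
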