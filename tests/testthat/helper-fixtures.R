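# Hand-built fully informative toy cross: 4 founders, 2 F1, 2 F2,
# 2 markers on one chromosome. Line A carries allele 1, line B allele 2.
toy_cross <- function(f2_geno = list(F2_1 = c(1, 2, 1, 2), F2_2 = c(1, 1, 2, 2)),
                      map = NULL, sex_chromosome = NULL) {
  ped <- data.frame(
    id = c("A1", "A2", "B1", "B2", "F1a", "F1b", names(f2_geno)),
    sire = c(NA, NA, NA, NA, "A1", "A2", rep("F1a", length(f2_geno))),
    dam = c(NA, NA, NA, NA, "B1", "B2", rep("F1b", length(f2_geno))),
    sex = c("male", "male", "female", "female", "male", "female",
            rep(c("female", "male"), length.out = length(f2_geno))),
    stringsAsFactors = FALSE)
  if (is.null(map)) {
    map <- data.frame(chromosome = "chr1", marker = c("m1", "m2"),
                      position_cM = c(0, 10), kind = "autosome")
  }
  nm <- nrow(map)
  g <- rbind(A1 = rep(1L, 2 * nm), A2 = rep(1L, 2 * nm),
             B1 = rep(2L, 2 * nm), B2 = rep(2L, 2 * nm),
             F1a = rep(c(1L, 2L), nm), F1b = rep(c(1L, 2L), nm))
  for (id in names(f2_geno)) {
    g <- rbind(g, matrix(as.integer(f2_geno[[id]]), 1))
    rownames(g)[nrow(g)] <- id
  }
  colnames(g) <- as.vector(rbind(paste0(map$marker, "_1"), paste0(map$marker, "_2")))
  ph <- data.frame(id = names(f2_geno), w = seq_along(f2_geno),
                   stringsAsFactors = FALSE)
  cross_data(pedigree = ped, genotypes = g, map = map, phenotypes = ph,
             cross_type = "F2", sex_chromosome = sex_chromosome)
}

# field-by-field cross equality (used by the round-trip oracles)
expect_cross_equal <- function(a, b) {
  expect_equal(a$pedigree, b$pedigree)
  expect_equal(a$map, b$map)
  expect_identical(a$genotypes, b$genotypes)
  expect_equal(a$phenotypes, b$phenotypes, tolerance = 1e-12)
  expect_identical(a$cross_type, b$cross_type)
  expect_identical(a$heterogametic_sex, b$heterogametic_sex)
  expect_identical(a$sex_chromosome %||% "none", b$sex_chromosome %||% "none")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# small simulated cross for generic use
quick_sim <- function(seed = 1, n = 40, n_markers = 6, length_cM = 50, ...) {
  simulate_cross(sim_config(
    seed = seed, n_offspring = n,
    chromosomes = data.frame(length_cM = length_cM, n_markers = n_markers), ...))
}
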