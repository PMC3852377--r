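#' Haldane map function
#'
#' Converts a genetic distance in centiMorgans to a recombination
#' fraction under the no-interference (Poisson crossover) model:
#' r = (1 - exp(-2 d / 100)) / 2.
#'
#' @param d distance in cM (vectorised, all values >= 0).
#' @return recombination fraction(s) in [0, 0.5).
#' @export
#' @examples
#' haldane_r(c(0, 10, 50))
haldane_r <- function(d) {
  if (any(d < 0)) stop_lcq("map distance must be non-negative")
  (1 - exp(-2 * d / 100)) / 2
}

# ---- piecewise-constant haplotypes ------------------------------------
# A homolog is a data.frame(start, label): segment i carries founder
# homolog `label` on [start_i, start_{i+1}), the last segment to the
# chromosome end. All labels are already resolved to founder homologs.

pw_value <- function(h, pos) {
  h$label[findInterval(pos, h$start)]
}

#' Simulate one meiosis on a chromosome
#'
#' Crossovers are placed as a Poisson process with rate 1 per 100 cM (no
#' interference) and the starting homolog is chosen with probability 1/2,
#' i.e. the Haldane model used throughout the package. Uses the current
#' RNG stream.
#'
#' @param pat,mat the parent's two homologs, each a `data.frame(start,
#'   label)` of founder-homolog segments.
#' @param length_cM chromosome length in cM.
#' @return list with `gamete` (segment data.frame) and `crossovers`
#'   (numeric positions).
#' @export
meiosis <- function(pat, mat, length_cM) {
  ncx <- stats::rpois(1L, length_cM / 100)
  cx <- sort(stats::runif(ncx, 0, length_cM))
  first <- if (stats::runif(1L) < 0.5) 1L else 2L
  starts <- list(pat$start, mat$start)
  labels <- list(pat$label, mat$label)
  bounds <- c(0, cx)
  out_s <- numeric(0)
  out_l <- integer(0)
  cur <- first
  for (i in seq_along(bounds)) {
    s <- bounds[i]
    e <- if (i < length(bounds)) bounds[i + 1L] else length_cM
    hs <- starts[[cur]]; hl <- labels[[cur]]
    inside <- hs > s & hs < e
    out_s <- c(out_s, s, hs[inside])
    out_l <- c(out_l, hl[findInterval(s, hs)], hl[inside])
    cur <- 3L - cur
  }
  keep <- c(TRUE, diff(out_l) != 0)
  list(gamete = data.frame(start = out_s[keep], label = out_l[keep]),
       crossovers = cx)
}

# ---- configuration -----------------------------------------------------

#' QTL specification for the simulator
#'
#' @param chromosome chromosome name.
#' @param position_cM QTL position.
#' @param a additive effect (half the difference between the two
#'   homozygotes for the increasing allele Q: qq = -a, Qq = d, QQ = +a).
#' @param d dominance effect.
#' @param f_A,f_B frequency of the increasing allele among line-A and
#'   line-B founder homologs. `f_A = 1, f_B = 0` is the classical
#'   fixed-lines assumption; intermediate values give within-line
#'   segregation.
#' @param partner index (into the config's `qtl` list) of a partner locus
#'   for pairwise epistasis, or `NULL`.
#' @param aa,ad,da,dd epistatic effects on the additive/dominance coding
#'   with the partner locus (counted once, from this QTL's spec).
#' @return a `qtl_spec` list.
#' @export
qtl_spec <- function(chromosome, position_cM, a = 0, d = 0,
                     f_A = 1, f_B = 0, partner = NULL,
                     aa = 0, ad = 0, da = 0, dd = 0) {
  if (f_A < 0 || f_A > 1 || f_B < 0 || f_B > 1) {
    stop_lcq("QTL allele frequencies must lie in [0,1]")
  }
  structure(list(chromosome = as.character(chromosome),
                 position_cM = position_cM, a = a, d = d,
                 f_A = f_A, f_B = f_B, partner = partner,
                 aa = aa, ad = ad, da = da, dd = dd),
            class = "qtl_spec")
}

#' Simulator configuration
#'
#' Describes a two-line cross to simulate: founders drawn from two lines,
#' F1s from A x B matings, then F2 (F1 x F1) or BC (F1 x founder)
#' offspring via Haldane meiosis.
#'
#' @param seed integer RNG seed; the simulation is deterministic given it.
#' @param chromosomes data.frame with columns `length_cM` and `n_markers`
#'   (>= 2), one row per (autosomal) chromosome; rownames or a `name`
#'   column give chromosome names (default `chr1`, ...). Markers are
#'   placed at regular intervals including both ends.
#' @param founders_per_line number of founders in each line (>= 1).
#' @param n_f1 number of F1 individuals to produce (>= 2 for F2 crosses).
#' @param n_offspring number of mapping-generation offspring (F2 or BC),
#'   allocated round-robin over the F1 couples.
#' @param cross_type `"F2"` or `"BC"`.
#' @param bc_line line to which BC offspring are backcrossed.
#' @param allele_model `"line_private"` (line A founders fixed for allele
#'   1, line B for allele 2: fully informative markers),
#'   `"founder_unique"` (every founder homolog carries a private allele:
#'   descent is fully observable) or `"shared"` (two alleles segregate in
#'   both lines at frequencies `p_A`/`p_B`: partially informative, the
#'   realistic SNP situation).
#' @param p_A,p_B frequency of allele 1 among line-A / line-B founder
#'   homologs under the `"shared"` model.
#' @param qtl list of [qtl_spec()] objects.
#' @param mu trait mean.
#' @param residual_sd residual standard deviation (> 0 unless exactly 0
#'   for noise-free checks).
#' @param sex_effect additive shift applied to males.
#' @param epsilon_obs fraction of observed genotypes replaced by a
#'   uniform draw over the marker's allele pairs (observation error; 0 by
#'   default).
#' @return a `sim_config` list.
#' @export
sim_config <- function(seed = 1L,
                       chromosomes = data.frame(length_cM = 100, n_markers = 20),
                       founders_per_line = 2L,
                       n_f1 = 4L,
                       n_offspring = 200L,
                       cross_type = c("F2", "BC"),
                       bc_line = "A",
                       allele_model = c("line_private", "founder_unique", "shared"),
                       p_A = 0.9, p_B = 0.1,
                       qtl = list(),
                       mu = 0, residual_sd = 1,
                       sex_effect = 0,
                       epsilon_obs = 0) {
  cross_type <- match.arg(cross_type)
  allele_model <- match.arg(allele_model)
  chromosomes <- as.data.frame(chromosomes)
  if (!"name" %in% names(chromosomes)) {
    chromosomes$name <- paste0("chr", seq_len(nrow(chromosomes)))
  }
  if (!"kind" %in% names(chromosomes)) chromosomes$kind <- "autosome"
  if (any(chromosomes$kind != "autosome")) {
    stop_lcq("the simulator supports autosomes only")
  }
  if (any(chromosomes$n_markers < 2L)) stop_lcq("need >= 2 markers per chromosome")
  if (founders_per_line < 1L) stop_lcq("founders_per_line must be >= 1")
  if (cross_type == "F2" && n_f1 < 2L) stop_lcq("F2 cross needs n_f1 >= 2")
  if (residual_sd < 0) stop_lcq("residual_sd must be >= 0")
  if (epsilon_obs < 0 || epsilon_obs > 1) stop_lcq("epsilon_obs must be in [0,1]")
  for (q in qtl) {
    if (!inherits(q, "qtl_spec")) stop_lcq("qtl must be a list of qtl_spec objects")
    if (!q$chromosome %in% chromosomes$name) {
      stop_lcq("QTL chromosome '", q$chromosome, "' not simulated")
    }
  }
  structure(list(seed = as.integer(seed), chromosomes = chromosomes,
                 founders_per_line = as.integer(founders_per_line),
                 n_f1 = as.integer(n_f1),
                 n_offspring = as.integer(n_offspring),
                 cross_type = cross_type, bc_line = bc_line,
                 allele_model = allele_model, p_A = p_A, p_B = p_B,
                 qtl = qtl, mu = mu, residual_sd = residual_sd,
                 sex_effect = sex_effect, epsilon_obs = epsilon_obs),
            class = "sim_config")
}

#' Simulate a two-line cross with recorded descent truth
#'
#' Founder genotypes are drawn from the per-line allele model, F1s are
#' produced from line-A x line-B matings and the mapping generation by
#' Haldane meiosis. Every individual's two homologs are stored as
#' founder-homolog segment lists, so the true line origin, founder label
#' and QTL genotype are known at every position. The phenotype is
#' mu + sex effect + sum of QTL (and epistatic) effects + N(0, sd^2).
#'
#' @param config a [sim_config()] object.
#' @return list with elements `cross` (a [cross_data]) and `truth` (a
#'   `truth_record`).
#' @export
simulate_cross <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$seed, simulate_cross_impl(config))
}

simulate_cross_impl <- function(cfg) {
  chrs <- cfg$chromosomes
  K <- cfg$founders_per_line
  f0_ids <- c(paste0("A", seq_len(K)), paste0("B", seq_len(K)))
  f0_line <- rep(c("A", "B"), each = K)
  n_f0 <- 2L * K
  # founder homolog labels: founder i owns labels 2i-1, 2i
  label_founder <- rep(seq_len(n_f0), each = 2L)
  label_line <- f0_line[label_founder]

  # marker maps
  map <- do.call(rbind, lapply(seq_len(nrow(chrs)), function(ci) {
    nm <- chrs$n_markers[ci]
    data.frame(chromosome = chrs$name[ci],
               marker = paste0(chrs$name[ci], "_m", seq_len(nm)),
               position_cM = seq(0, chrs$length_cM[ci], length.out = nm),
               kind = "autosome", stringsAsFactors = FALSE)
  }))

  # founder marker alleles: matrix [2*n_f0 labels x n_markers]
  nmark <- nrow(map)
  fa <- matrix(0L, nrow = 2L * n_f0, ncol = nmark)
  for (m in seq_len(nmark)) {
    fa[, m] <- switch(cfg$allele_model,
      line_private = ifelse(label_line == "A", 1L, 2L),
      founder_unique = seq_len(2L * n_f0),
      shared = ifelse(stats::runif(2L * n_f0) <
                        ifelse(label_line == "A", cfg$p_A, cfg$p_B), 1L, 2L))
  }

  # founder QTL alleles (1 = increasing Q, 0 = q) per homolog label
  nq <- length(cfg$qtl)
  qa <- matrix(0L, nrow = 2L * n_f0, ncol = max(1L, nq))
  for (j in seq_len(nq)) {
    q <- cfg$qtl[[j]]
    f <- ifelse(label_line == "A", q$f_A, q$f_B)
    qa[, j] <- as.integer(stats::runif(2L * n_f0) < f)
  }

  # haplotypes: haplo[[id]][[chrom]] = list(pat=, mat=) of segment dfs
  one_seg <- function(lab) data.frame(start = 0, label = lab)
  haplo <- list()
  for (i in seq_len(n_f0)) {
    haplo[[f0_ids[i]]] <- lapply(seq_len(nrow(chrs)), function(ci) {
      list(pat = one_seg(2L * i - 1L), mat = one_seg(2L * i))
    })
    names(haplo[[f0_ids[i]]]) <- chrs$name
  }

  make_gamete <- function(parent_id) {
    lapply(seq_len(nrow(chrs)), function(ci) {
      h <- haplo[[parent_id]][[ci]]
      meiosis(h$pat, h$mat, chrs$length_cM[ci])$gamete
    })
  }

  # F1: A_i x B_j matings, cycling over founders
  f1_ids <- paste0("F1_", seq_len(cfg$n_f1))
  f1_sire <- f0_ids[((seq_len(cfg$n_f1) - 1L) %% K) + 1L]          # line A
  f1_dam <- f0_ids[K + ((seq_len(cfg$n_f1) - 1L) %% K) + 1L]       # line B
  for (i in seq_len(cfg$n_f1)) {
    pg <- make_gamete(f1_sire[i])   # line-A-derived homolog
    mg <- make_gamete(f1_dam[i])    # line-B-derived homolog
    haplo[[f1_ids[i]]] <- stats::setNames(
      lapply(seq_len(nrow(chrs)), function(ci) list(pat = pg[[ci]], mat = mg[[ci]])),
      chrs$name)
  }

  # mapping generation
  n_off <- cfg$n_offspring
  off_gen <- if (cfg$cross_type == "F2") "F2" else "BC"
  off_ids <- if (n_off > 0L) paste0(off_gen, "_", seq_len(n_off)) else character(0)
  if (cfg$cross_type == "F2") {
    ncpl <- max(1L, cfg$n_f1 %/% 2L)
    couples <- cbind(f1_ids[2L * seq_len(ncpl) - 1L], f1_ids[2L * seq_len(ncpl)])
  } else {
    bc_f0 <- f0_ids[f0_line == cfg$bc_line]
    ncpl <- cfg$n_f1
    couples <- cbind(f1_ids, bc_f0[((seq_len(ncpl) - 1L) %% length(bc_f0)) + 1L])
  }
  off_sire <- character(n_off); off_dam <- character(n_off)
  for (i in seq_len(n_off)) {
    cpl <- couples[((i - 1L) %% nrow(couples)) + 1L, ]
    off_sire[i] <- cpl[1L]; off_dam[i] <- cpl[2L]
    pg <- make_gamete(cpl[1L])
    mg <- make_gamete(cpl[2L])
    haplo[[off_ids[i]]] <- stats::setNames(
      lapply(seq_len(nrow(chrs)), function(ci) list(pat = pg[[ci]], mat = mg[[ci]])),
      chrs$name)
  }

  # pedigree (sires recorded male, dams female; offspring alternate)
  ped <- data.frame(
    id = c(f0_ids, f1_ids, off_ids),
    sire = c(rep(NA_character_, n_f0), f1_sire, off_sire),
    dam = c(rep(NA_character_, n_f0), f1_dam, off_dam),
    sex = "unknown",
    generation = c(paste0("F0_", f0_line), rep("F1", cfg$n_f1),
                   rep(off_gen, n_off)),
    line = c(f0_line, rep(NA_character_, cfg$n_f1 + n_off)),
    stringsAsFactors = FALSE)
  sx <- stats::setNames(ped$sex, ped$id)
  sx[unique(c(f1_sire, off_sire))] <- "male"
  sx[unique(c(f1_dam, off_dam))] <- "female"
  rest <- names(sx)[sx == "unknown"]
  sx[rest] <- rep(c("male", "female"), length.out = length(rest))
  ped$sex <- unname(sx[ped$id])

  # genotypes from founder labels
  all_ids <- ped$id
  g <- matrix(0L, nrow = length(all_ids), ncol = 2L * nmark,
              dimnames = list(all_ids,
                as.vector(rbind(paste0(map$marker, "_1"), paste0(map$marker, "_2")))))
  for (ci in seq_len(nrow(chrs))) {
    sel <- which(map$chromosome == chrs$name[ci])
    pos <- map$position_cM[sel]
    for (id in all_ids) {
      h <- haplo[[id]][[chrs$name[ci]]]
      lab_p <- pw_value(h$pat, pos)
      lab_m <- pw_value(h$mat, pos)
      g[id, 2L * sel - 1L] <- fa[cbind(lab_p, sel)]
      g[id, 2L * sel] <- fa[cbind(lab_m, sel)]
    }
  }
  if (cfg$epsilon_obs > 0) {
    for (m in seq_len(nmark)) {
      alls <- sort(unique(as.vector(fa[, m])))
      hit <- which(stats::runif(length(all_ids)) < cfg$epsilon_obs)
      for (i in hit) {
        g[i, c(2L * m - 1L, 2L * m)] <- sample(alls, 2L, replace = TRUE)
      }
    }
  }

  # QTL genotypes and phenotype for the mapping generation
  qtl_geno <- matrix(NA_integer_, nrow = n_off, ncol = nq,
                     dimnames = list(off_ids, NULL))
  gval <- numeric(n_off)
  if (nq > 0L && n_off > 0L) {
    wa <- matrix(0, n_off, nq); wd <- matrix(0, n_off, nq)
    for (j in seq_len(nq)) {
      q <- cfg$qtl[[j]]
      for (i in seq_len(n_off)) {
        h <- haplo[[off_ids[i]]][[q$chromosome]]
        cnt <- qa[pw_value(h$pat, q$position_cM), j] +
               qa[pw_value(h$mat, q$position_cM), j]
        qtl_geno[i, j] <- cnt
        wa[i, j] <- cnt - 1L
        wd[i, j] <- as.numeric(cnt == 1L)
      }
      gval <- gval + q$a * wa[, j] + q$d * wd[, j]
    }
    for (j in seq_len(nq)) {
      q <- cfg$qtl[[j]]
      if (!is.null(q$partner)) {
        k <- q$partner
        gval <- gval + q$aa * wa[, j] * wa[, k] + q$ad * wa[, j] * wd[, k] +
                       q$da * wd[, j] * wa[, k] + q$dd * wd[, j] * wd[, k]
      }
    }
  }
  sex_num <- as.numeric(ped$sex[match(off_ids, ped$id)] == "male")
  noise <- if (n_off > 0L) stats::rnorm(n_off, 0, cfg$residual_sd) else numeric(0)
  w <- cfg$mu + cfg$sex_effect * sex_num + gval + noise
  phen <- data.frame(id = off_ids, w = w, sex = sex_num,
                     stringsAsFactors = FALSE)

  cross <- cross_data(pedigree = ped, genotypes = g, map = map,
                      phenotypes = phen, cross_type = cfg$cross_type)
  truth <- structure(
    list(haplo = haplo, label_founder = label_founder,
         label_line = label_line, founder_ids = f0_ids,
         founder_marker_alleles = fa, qtl_alleles = qa,
         qtl_geno = qtl_geno, genetic_value = gval,
         offspring = off_ids, chromosomes = chrs, config = cfg),
    class = "truth_record")
  list(cross = cross, truth = truth)
}

#' True ordered line-origin states at a position
#'
#' @param truth a `truth_record`.
#' @param chromosome chromosome name.
#' @param position position in cM.
#' @param ids individuals (default: all simulated offspring).
#' @return character matrix `ids` x 2 with entries `"A"`/`"B"` for the
#'   paternal and maternal gamete.
#' @export
truth_origin <- function(truth, chromosome, position, ids = truth$offspring) {
  out <- matrix(NA_character_, length(ids), 2L,
                dimnames = list(ids, c("pat", "mat")))
  for (i in seq_along(ids)) {
    h <- truth$haplo[[ids[i]]][[chromosome]]
    out[i, 1L] <- truth$label_line[pw_value(h$pat, position)]
    out[i, 2L] <- truth$label_line[pw_value(h$mat, position)]
  }
  out
}

#' True founder-homolog labels at a position
#'
#' @inheritParams truth_origin
#' @return integer matrix `ids` x 2 of founder homolog labels.
#' @export
truth_labels <- function(truth, chromosome, position, ids = truth$offspring) {
  out <- matrix(NA_integer_, length(ids), 2L,
                dimnames = list(ids, c("pat", "mat")))
  for (i in seq_along(ids)) {
    h <- truth$haplo[[ids[i]]][[chromosome]]
    out[i, 1L] <- pw_value(h$pat, position)
    out[i, 2L] <- pw_value(h$mat, position)
  }
  out
}

#' True additive/dominance line-origin codes at a position
#'
#' Oracle for the least-squares scan: codes the true ordered origin state
#' as a = 1 (AA), 0 (heterozygous), -1 (BB) and d = 1 for heterozygotes.
#'
#' @inheritParams truth_origin
#' @return data.frame with columns `id`, `a`, `d`.
#' @export
true_predictors <- function(truth, chromosome, position, ids = truth$offspring) {
  o <- truth_origin(truth, chromosome, position, ids)
  a <- (o[, 1L] == "A") + (o[, 2L] == "A") - 1
  d <- as.numeric(o[, 1L] != o[, 2L])
  data.frame(id = ids, a = as.numeric(a), d = d, stringsAsFactors = FALSE)
}
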