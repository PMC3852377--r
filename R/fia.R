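# ---- segregation chains -----------------------------------------------
# 2-state chain for a single F1 homolog: which of the two homologs of the
# corresponding F0 parent it copies, along the chromosome. Haldane
# transitions; marker emissions compare the F1 homolog allele
# distribution with the F0 parent's stored allele pair (the pair order
# stands in for the unknown founder phase; exact whenever founder
# genotypes are homozygous or founder alleles are unique). Uniform where
# uninformative.
seg_chain_marginals <- function(cross, freqs, hdists, f1_id, homolog, chrom,
                                loci, eps) {
  map <- cross$map
  sel <- which(map$chromosome == chrom)
  mpos <- map$position_cM[sel]
  ped <- cross$pedigree
  i <- match(f1_id, ped$id)
  par <- c(ped$sire[i], ped$dam[i])
  gen_of <- stats::setNames(ped$generation, ped$id)
  f0p <- par[gen_of[par] %in% paste0("F0_", homolog)][1L]
  locus_marker <- match(round(loci, 9), round(mpos, 9))
  L <- length(loci)
  E <- vector("list", L)
  if (!is.na(f0p) && f0p %in% rownames(cross$genotypes)) {
    for (t in seq_len(L)) {
      mi <- locus_marker[t]
      if (is.na(mi)) next
      m <- sel[mi]
      info <- freqs$markers[[m]]
      H <- hdists$H[[f1_id]][[m]]
      if (is.null(info) || is.null(H)) next
      gp <- cross$genotypes[f0p, c(2L * m - 1L, 2L * m)]
      if (any(gp == 0L)) next
      K <- length(info$alleles)
      h <- H[, homolog]
      e <- vapply(gp, function(a) {
        ia <- match(a, info$alleles)
        (1 - eps) * h[ia] + eps / K
      }, numeric(1L))
      if (sum(e) <= 0) next
      E[[t]] <- e
    }
  }
  a <- c(0.5, 0.5)
  alpha <- matrix(0, L, 2L)
  if (!is.null(E[[1L]])) a <- a * E[[1L]]
  alpha[1L, ] <- a / sum(a)
  d <- diff(loci)
  rs <- haldane_r(d)
  for (t in seq_len(L - 1L)) {
    r <- rs[t]
    a <- c(alpha[t, 1L] * (1 - r) + alpha[t, 2L] * r,
           alpha[t, 1L] * r + alpha[t, 2L] * (1 - r))
    if (!is.null(E[[t + 1L]])) a <- a * E[[t + 1L]]
    alpha[t + 1L, ] <- a / sum(a)
  }
  marg <- matrix(0, L, 2L)
  marg[L, ] <- alpha[L, ]
  b <- c(1, 1)
  if (L > 1L) {
    for (t in (L - 1L):1L) {
      r <- rs[t]
      be <- b
      if (!is.null(E[[t + 1L]])) be <- be * E[[t + 1L]]
      b <- c(be[1L] * (1 - r) + be[2L] * r, be[1L] * r + be[2L] * (1 - r))
      b <- b / sum(b)
      mg <- alpha[t, ] * b
      marg[t, ] <- mg / sum(mg)
    }
  }
  marg
}

# Precompute everything position-independent for Monte-Carlo IBD on one
# chromosome: offspring origin marginals and per-F1-homolog segregation
# marginals at all requested positions, plus founder-label lookup.
mcibd_prepare <- function(cross, chrom, positions, error_rate = 0.001,
                          freqs = NULL, hdists = NULL) {
  assert_valid_cross(cross)
  if (is.null(freqs)) freqs <- estimate_line_freqs(cross)
  if (is.null(hdists)) hdists <- infer_f1_homolog_dists(cross, freqs)
  ped <- cross$pedigree
  ids <- chrom_offspring(cross, chrom)
  probs <- line_origin_probs(cross, error_rate = error_rate,
                             positions = stats::setNames(list(positions), chrom),
                             freqs = freqs, hdists = hdists)
  off_marg <- probs$chromosomes[[chrom]]$prob[ids, , , drop = FALSE]

  f0 <- ped$id[ped$generation %in% c("F0_A", "F0_B")]
  f0_idx <- stats::setNames(seq_along(f0), f0)
  gen_of <- stats::setNames(ped$generation, ped$id)

  f1 <- sort(unique(stats::na.omit(c(
    ped$sire[match(ids, ped$id)], ped$dam[match(ids, ped$id)]))))
  f1 <- f1[gen_of[f1] %in% "F1"]
  f1_idx <- stats::setNames(seq_along(f1), f1)

  mpos <- cross$map$position_cM[cross$map$chromosome == chrom]
  loci <- sort(unique(round(c(mpos, positions), 9)))
  keep <- match(round(positions, 9), loci)
  n_h <- 2L * length(f1)
  seg_marg <- array(NA_real_, dim = c(n_h, length(positions), 2L))
  glab <- array(NA_integer_, dim = c(length(f1), 2L, 2L))  # f1 x homolog x seg
  for (j in seq_along(f1)) {
    i <- match(f1[j], ped$id)
    par <- c(ped$sire[i], ped$dam[i])
    for (h in 1:2) {
      hom <- c("A", "B")[h]
      mg <- seg_chain_marginals(cross, freqs, hdists, f1[j], hom, chrom,
                                loci, error_rate)
      seg_marg[2L * (j - 1L) + h, , ] <- mg[keep, , drop = FALSE]
      f0p <- par[gen_of[par] %in% paste0("F0_", hom)][1L]
      fi <- f0_idx[[f0p]]
      glab[j, h, ] <- c(2L * (fi - 1L) + 1L, 2L * (fi - 1L) + 2L)
    }
  }

  parent_info <- function(pids) {
    isf1 <- gen_of[pids] %in% "F1"
    list(f1 = ifelse(isf1, f1_idx[pids], NA_integer_),
         f0 = ifelse(isf1, NA_integer_, f0_idx[pids]))
  }
  sire <- ped$sire[match(ids, ped$id)]
  dam <- ped$dam[match(ids, ped$id)]
  list(ids = ids, positions = positions, off_marg = off_marg,
       seg_marg = seg_marg, glab = glab,
       sire = parent_info(sire), dam = parent_info(dam),
       n_labels = 2L * length(f0), n_f1 = length(f1))
}

# Monte-Carlo IBD matrix at prepared position k (uses current RNG).
mcibd_at <- function(prep, k, n_samples) {
  ids <- prep$ids
  n <- length(ids)
  nl <- prep$n_labels
  marg <- matrix(prep$off_marg[, k, ], n, 4L)
  states <- row_categorical_many(marg, n_samples)        # ordered state 1..4
  pat_h <- (states - 1L) %/% 2L + 1L                      # father homolog A/B
  mat_h <- (states - 1L) %% 2L + 1L
  n_h <- 2L * prep$n_f1
  seg <- matrix(1L, max(n_h, 1L), n_samples)
  if (n_h > 0L) {
    p2 <- matrix(prep$seg_marg[, k, 2L], n_h, n_samples)
    seg <- 1L + (matrix(stats::runif(n_h * n_samples), n_h, n_samples) < p2)
  }
  gamete_labels <- function(pinfo, hmat) {
    lab <- matrix(NA_integer_, n, n_samples)
    isf1 <- !is.na(pinfo$f1)
    if (any(isf1)) {
      j <- pinfo$f1[isf1]                                 # f1 index per offspring
      hrow <- 2L * (j - 1L)                               # base row in seg
      hm <- hmat[isf1, , drop = FALSE]
      rows <- hrow + hm                                   # n1 x S row in seg
      sflat <- seg[cbind(as.vector(rows),
                         rep(seq_len(n_samples), each = sum(isf1)))]
      lab[isf1, ] <- prep$glab[cbind(rep(j, n_samples), as.vector(hm), sflat)]
    }
    if (any(!isf1)) {
      fi <- pinfo$f0[!isf1]
      u <- 1L + (matrix(stats::runif(sum(!isf1) * n_samples),
                        sum(!isf1), n_samples) > 0.5)
      lab[!isf1, ] <- 2L * (rep(fi, n_samples) - 1L) + u
    }
    lab
  }
  pat_lab <- gamete_labels(prep$sire, pat_h)
  mat_lab <- gamete_labels(prep$dam, mat_h)
  C <- matrix(0, n, n)
  rowi <- seq_len(n)
  for (s in seq_len(n_samples)) {
    Z <- matrix(0, n, nl)
    i1 <- cbind(rowi, pat_lab[, s])
    Z[i1] <- Z[i1] + 1
    i2 <- cbind(rowi, mat_lab[, s])
    Z[i2] <- Z[i2] + 1
    C <- C + tcrossprod(Z)
  }
  Pi <- C / (2 * n_samples)
  dimnames(Pi) <- list(ids, ids)
  Pi
}

psd_repair <- function(Pi) {
  dn <- dimnames(Pi)
  Pi <- (Pi + t(Pi)) / 2
  e <- eigen(Pi, symmetric = TRUE)
  if (min(e$values) < 0) {
    v <- pmax(e$values, 0)
    Pi <- e$vectors %*% (v * t(e$vectors))
    Pi <- (Pi + t(Pi)) / 2
    dimnames(Pi) <- dn
  }
  Pi
}

#' Monte-Carlo IBD matrix at a genome position
#'
#' Estimates the locus-specific additive relationship matrix
#' `Pi[i, j] = E[number of IBD pairs among the four allele pairs] / 2`
#' over the mapping-generation offspring, by Monte Carlo: each iteration
#' samples every offspring's ordered line-origin state from its posterior
#' marginal, samples each F1 homolog's founder-of-origin from a 2-state
#' segregation chain conditioned on marker data, propagates unique
#' founder-homolog labels, and counts label sharing. The average is
#' symmetrised and negative eigenvalues are clipped at zero.
#'
#' @param cross a validated [cross_data] object.
#' @param chromosome chromosome name.
#' @param position position in cM.
#' @param n_samples Monte-Carlo iterations (default 200).
#' @param seed integer RNG seed.
#' @param error_rate genotyping-error mixture weight for the underlying
#'   chains.
#' @return an `ibd_matrix`: symmetric PSD matrix with diagonal in
#'   `[1, 2]`, attributes `n_samples`, `seed`, `chromosome`, `position`.
#' @export
mcibd_matrix <- function(cross, chromosome, position, n_samples = 200L,
                         seed = 1L, error_rate = 0.001) {
  if (n_samples < 1L) stop_lcq("n_samples must be >= 1")
  mpos <- cross$map$position_cM[cross$map$chromosome == chromosome]
  if (!length(mpos)) stop_lcq("unknown chromosome '", chromosome, "'")
  if (position < 0 || position > max(mpos)) stop_lcq("position off the map")
  prep <- mcibd_prepare(cross, chromosome, position, error_rate)
  Pi <- with_seed(seed, mcibd_at(prep, 1L, n_samples))
  Pi <- psd_repair(Pi)
  structure(Pi, n_samples = n_samples, seed = seed,
            chromosome = chromosome, position = position,
            class = c("ibd_matrix", "matrix"))
}

#' Exact IBD matrix from simulator truth
#'
#' Computes the realised locus IBD matrix directly from the founder
#' homolog labels recorded by [simulate_cross()].
#'
#' @param truth a `truth_record`.
#' @param chromosome,position locus.
#' @param ids individuals (default: all simulated offspring).
#' @return symmetric matrix on the additive-relationship scale.
#' @export
mcibd_truth <- function(truth, chromosome, position, ids = truth$offspring) {
  lab <- truth_labels(truth, chromosome, position, ids)
  nl <- length(truth$label_founder)
  Z <- matrix(0, length(ids), nl)
  i1 <- cbind(seq_along(ids), lab[, 1L])
  Z[i1] <- Z[i1] + 1
  i2 <- cbind(seq_along(ids), lab[, 2L])
  Z[i2] <- Z[i2] + 1
  Pi <- tcrossprod(Z) / 2
  dimnames(Pi) <- list(ids, ids)
  Pi
}

# ---- variance components ----------------------------------------------

reml_loglik_spectral <- function(lambda, dvals, tX, ty, n, p) {
  w <- 1 / (1 + lambda * dvals)
  A <- crossprod(tX, w * tX)
  b <- crossprod(tX, w * ty)
  beta <- solve(A, b)
  resid <- ty - tX %*% beta
  Q <- sum(w * resid^2)
  -0.5 * ((n - p) * log(Q) + sum(log1p(lambda * dvals)) +
            as.numeric(determinant(A, logarithm = TRUE)$modulus))
}

#' REML fit of the one-component locus variance model
#'
#' Fits `y = X beta + g + e` with `g ~ N(0, sigma2_g * Pi)` and
#' `e ~ N(0, sigma2_e * I)` by restricted maximum likelihood, profiling
#' over the ratio `lambda = sigma2_g / sigma2_e` with a one-dimensional
#' search on the spectral decomposition of `Pi`. The boundary
#' `lambda = 0` is allowed; a flat profile (e.g. `Pi` proportional to the
#' identity) returns the boundary with a flag.
#'
#' @param y numeric response.
#' @param X fixed-effect design matrix (full column rank after dropping
#'   collinear columns).
#' @param Pi symmetric PSD relationship matrix.
#' @param lambda_max upper bound of the ratio search.
#' @param tol search tolerance in lambda.
#' @return list with `sigma2_g`, `sigma2_e`, `lambda`, `loglik` (REML, up
#'   to a constant) and `flag` (`""` or `"boundary"`).
#' @export
fit_variance_components <- function(y, X, Pi, lambda_max = 1e4, tol = 1e-6) {
  X <- as.matrix(X)
  qx <- qr(X)
  if (qx$rank < ncol(X)) X <- X[, qx$pivot[seq_len(qx$rank)], drop = FALSE]
  n <- length(y)
  p <- ncol(X)
  if (n <= p) stop_lcq("more fixed effects than observations")
  e <- eigen(Pi, symmetric = TRUE)
  if (min(e$values) < -1e-8) stop_lcq("Pi is not positive semidefinite")
  dvals <- pmax(e$values, 0)
  tU <- t(e$vectors)
  ty <- drop(tU %*% y)
  tX <- tU %*% X
  f <- function(l) reml_loglik_spectral(l, dvals, tX, ty, n, p)
  opt <- stats::optimize(f, c(0, lambda_max), maximum = TRUE, tol = tol)
  l0 <- f(0)
  flag <- ""
  if (opt$objective <= l0 + 1e-6) {
    lambda <- 0; ll <- l0; flag <- "boundary"
  } else {
    lambda <- opt$maximum; ll <- opt$objective
  }
  w <- 1 / (1 + lambda * dvals)
  A <- crossprod(tX, w * tX)
  beta <- solve(A, crossprod(tX, w * ty))
  Q <- sum(w * (ty - tX %*% beta)^2)
  s2e <- Q / (n - p)
  list(sigma2_g = lambda * s2e, sigma2_e = s2e, lambda = lambda,
       loglik = ll, beta = drop(beta), flag = flag)
}

#' Standardised score statistic for locus genetic variance
#'
#' With null residuals `r = (I - P_X) y` and `s2 = r'r / (n - p)`,
#' computes `U = (r' Pi r / s2 - tr(M Pi)) / sqrt(2 tr((M Pi)^2))` where
#' `M = I - P_X`. Large positive values indicate genetic variance
#' attributable to the locus; inference is by permutation (the analytic
#' standardisation is a convenience, not a p-value).
#'
#' @param y numeric response.
#' @param X fixed-effect design matrix.
#' @param Pi relationship matrix.
#' @return the scalar score statistic.
#' @export
fia_score <- function(y, X, Pi) {
  drop(fia_score_multi(matrix(y, ncol = 1L), X, Pi))
}

# vectorised over columns of Y; shares the projection and trace terms.
fia_score_multi <- function(Y, X, Pi) {
  X <- as.matrix(X)
  qx <- qr(X)
  p <- qx$rank
  n <- nrow(Y)
  Q <- qr.Q(qx)[, seq_len(p), drop = FALSE]
  MY <- Y - Q %*% crossprod(Q, Y)                  # residuals per column
  MPi <- Pi - Q %*% crossprod(Q, Pi)               # M Pi
  MPiM <- MPi - (MPi %*% Q) %*% t(Q)               # M Pi M
  tr1 <- sum(diag(MPiM))                           # tr(M Pi) since M idempotent
  tr2 <- sum(MPiM * t(MPiM))
  num <- colSums(MY * (Pi %*% MY))
  s2 <- colSums(MY^2) / (n - p)
  (num / s2 - tr1) / sqrt(2 * tr2)
}

#' Line-cross IBD matrix under the fixation assumption
#'
#' Builds the relationship matrix implied by assuming alternative QTL
#' alleles fixed in the founder lines (all line-A alleles mutually IBD,
#' likewise line B), from the ordered origin posterior at a position:
#' off-diagonal entries use per-gamete line-origin marginals with
#' independence across individuals; the diagonal is
#' `1 + P(AA) + P(BB)`.
#'
#' @param probs_pos individuals x 4 matrix of ordered state
#'   probabilities (AA, AB, BA, BB) at the position.
#' @return symmetric matrix on the additive-relationship scale.
#' @export
ibd_line_cross <- function(probs_pos) {
  s <- 2 * probs_pos[, 1L] + probs_pos[, 2L] + probs_pos[, 3L]  # E[# A alleles]
  Pi <- 0.5 * (outer(s, s) + outer(2 - s, 2 - s))
  diag(Pi) <- 1 + probs_pos[, 1L] + probs_pos[, 4L]
  rownames(Pi) <- colnames(Pi) <- rownames(probs_pos)
  Pi
}

#' Fixed-versus-segregating log-likelihood ratio
#'
#' Compares the REML log-likelihood of the variance model under the full
#' Monte-Carlo IBD matrix with the line-cross matrix that assumes QTL
#' alleles fixed in the founder lines:
#' `LR = 2 * (loglik(Pi_full) - loglik(Pi_LC))`. Positive values favour
#' within-line segregation.
#'
#' @param y,X as in [fit_variance_components()].
#' @param Pi_full Monte-Carlo IBD matrix at the position.
#' @param probs_pos ordered origin posterior at the position
#'   (individuals x 4), as in [ibd_line_cross()].
#' @return list with `lr`, `fit_full`, `fit_lc`.
#' @export
segregation_lr <- function(y, X, Pi_full, probs_pos) {
  fit_full <- fit_variance_components(y, X, Pi_full)
  fit_lc <- fit_variance_components(y, X, psd_repair(ibd_line_cross(probs_pos)))
  list(lr = 2 * (fit_full$loglik - fit_lc$loglik),
       fit_full = fit_full, fit_lc = fit_lc)
}

#' Flexible intercross analysis genome scan
#'
#' At every grid position estimates the Monte-Carlo IBD matrix, computes
#' the variance-component score statistic and (optionally) the REML fits
#' under the full and fixation-constrained relationship matrices with
#' their log-likelihood ratio. Genome-wide significance thresholds come
#' from permuting trait values and recording the maximum score.
#'
#' @param cross a validated [cross_data] object.
#' @param trait,covariates as in [scan_one()].
#' @param step_cM grid step.
#' @param n_samples Monte-Carlo iterations per position.
#' @param n_perm number of permutations (0 to skip).
#' @param quantiles threshold quantiles.
#' @param seed integer RNG seed (drives MCIBD and permutations).
#' @param reml compute REML fits and segregation LR per position?
#' @param error_rate genotyping-error mixture weight.
#' @return a `fia_result`: `table` (per-position data.frame with
#'   `chromosome`, `position`, `score`, `sigma2_g`, `sigma2_e`,
#'   `loglik_full`, `loglik_lc`, `seg_lr`), `perm` (a `perm_dist` or
#'   `NULL`), and the call parameters.
#' @export
fia_scan <- function(cross, trait, covariates = NULL, step_cM = 5,
                     n_samples = 200L, n_perm = 0L,
                     quantiles = c(0.95, 0.99), seed = 1L, reml = TRUE,
                     error_rate = 0.001) {
  des <- analysis_design(cross, trait, covariates)
  map <- cross$map
  chroms <- unique(map$chromosome)
  rows <- list()
  Pis <- list()
  with_seed(seed, {
    for (chrom in chroms) {
      mpos <- map$position_cM[map$chromosome == chrom]
      grid <- grid_positions(max(mpos), step_cM)
      prep <- mcibd_prepare(cross, chrom, grid, error_rate)
      use <- match(intersect(prep$ids, des$ids), prep$ids)
      yidx <- match(prep$ids[use], des$ids)
      y <- des$y[yidx]
      X <- des$X[yidx, , drop = FALSE]
      for (k in seq_along(grid)) {
        Pi <- psd_repair(mcibd_at(prep, k, n_samples)[use, use, drop = FALSE])
        sc <- fia_score(y, X, Pi)
        if (reml) {
          pm <- matrix(prep$off_marg[use, k, ], length(use), 4L,
                       dimnames = list(prep$ids[use], NULL))
          # the fixation hypothesis is a mean effect: absorb the
          # line-cross predictors so the LR isolates within-line variance
          Xg <- cbind(X, a = pm[, 1L] - pm[, 4L], d = pm[, 2L] + pm[, 3L])
          sl <- segregation_lr(y, Xg, Pi, pm)
          rows[[length(rows) + 1L]] <- data.frame(
            chromosome = chrom, position = grid[k], score = sc,
            sigma2_g = sl$fit_full$sigma2_g, sigma2_e = sl$fit_full$sigma2_e,
            loglik_full = sl$fit_full$loglik, loglik_lc = sl$fit_lc$loglik,
            seg_lr = sl$lr, stringsAsFactors = FALSE)
        } else {
          rows[[length(rows) + 1L]] <- data.frame(
            chromosome = chrom, position = grid[k], score = sc,
            sigma2_g = NA_real_, sigma2_e = NA_real_,
            loglik_full = NA_real_, loglik_lc = NA_real_,
            seg_lr = NA_real_, stringsAsFactors = FALSE)
        }
        Pis[[length(Pis) + 1L]] <- list(Pi = Pi, y = y, X = X)
      }
    }
    tab <- do.call(rbind, rows)
    perm <- NULL
    if (n_perm > 0L) {
      n <- length(Pis[[1L]]$y)
      Y <- vapply(seq_len(n_perm), function(i) Pis[[1L]]$y[sample.int(n)],
                  numeric(n))
      best <- rep(-Inf, n_perm)
      for (ps in Pis) {
        best <- pmax(best, fia_score_multi(Y, ps$X, ps$Pi))
      }
      perm <- structure(list(max_stats = best,
                             thresholds = stats::quantile(best, quantiles, type = 7),
                             quantiles = quantiles, n_perm = n_perm, seed = seed),
                        class = "perm_dist")
    }
    structure(list(table = tab, perm = perm, trait = trait,
                   covariates = covariates, step_cM = step_cM,
                   n_samples = n_samples, seed = seed),
              class = "fia_result")
  })
}

#' @export
print.fia_result <- function(x, ...) {
  cat(sprintf("fia_result: trait %s, %d positions, %d MC samples\n",
              x$trait, nrow(x$table), x$n_samples))
  top <- x$table[which.max(x$table$score), ]
  cat(sprintf("  max score %.3f at %s:%g\n", top$score, top$chromosome,
              top$position))
  if (!is.null(x$perm)) print(x$perm)
  invisible(x)
}
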