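#' Additive/dominance predictors from origin probabilities
#'
#' Haley-Knott coding of the line-origin posterior: for an F2,
#' a = P(AA) - P(BB) and d = P(AB) + P(BA); for a backcross a single
#' regressor x = P(heterozygous) - P(homozygous line-origin genotype).
#'
#' @param probs an `origin_prob_table` from [line_origin_probs()].
#' @param cross_type `"F2"` or `"BC"`; must match the table.
#' @return a `genetic_predictors` object: per chromosome `positions`, an
#'   `a` matrix (individuals x positions) and, for F2, a `d` matrix.
#' @export
genetic_predictors <- function(probs, cross_type = probs$cross_type) {
  if (!identical(cross_type, probs$cross_type)) {
    stop_lcq("cross_type does not match the probability table")
  }
  f2 <- cross_type == "F2"
  out <- lapply(probs$chromosomes, function(ch) {
    p <- ch$prob
    a <- p[, , "AA", drop = FALSE][, , 1L] - p[, , "BB", drop = FALSE][, , 1L]
    het <- p[, , "AB", drop = FALSE][, , 1L] + p[, , "BA", drop = FALSE][, , 1L]
    a <- matrix(a, dim(p)[1L], dim(p)[2L], dimnames = dimnames(p)[1:2])
    het <- matrix(het, dim(p)[1L], dim(p)[2L], dimnames = dimnames(p)[1:2])
    if (f2) {
      list(positions = ch$positions, a = a, d = het)
    } else {
      list(positions = ch$positions, a = 2 * het - 1, d = NULL)
    }
  })
  structure(list(chromosomes = out, individuals = probs$individuals,
                 cross_type = cross_type, q = if (f2) 2L else 1L),
            class = "genetic_predictors")
}

# analysis design: trait vector and fixed-effect matrix with listwise
# deletion over the mapping-generation offspring.
analysis_design <- function(cross, trait, covariates = NULL) {
  ph <- cross$phenotypes
  if (!trait %in% names(ph)) stop_lcq("trait '", trait, "' not in phenotypes")
  ids <- intersect(offspring_ids(cross), ph$id)
  rows <- match(ids, ph$id)
  y <- ph[[trait]][rows]
  X <- matrix(1, length(ids), 1L, dimnames = list(NULL, "(Intercept)"))
  for (cv in covariates) {
    if (!cv %in% names(ph)) stop_lcq("covariate '", cv, "' not in phenotypes")
    v <- ph[[cv]][rows]
    if (is.character(v) || is.factor(v)) {
      mm <- stats::model.matrix(~f, data.frame(f = factor(v)))[, -1L, drop = FALSE]
      colnames(mm) <- paste0(cv, colnames(mm))
      X <- cbind(X, mm)
    } else {
      X <- cbind(X, as.numeric(v))
      colnames(X)[ncol(X)] <- cv
    }
  }
  keep <- !is.na(y) & stats::complete.cases(X)
  list(ids = ids[keep], y = y[keep], X = X[keep, , drop = FALSE])
}

# least-squares F test of predictor block P against the X0-only null.
# Returns stats and effect estimates; rank-deficient blocks are reduced
# with a note. F is capped at 1e12 on a perfect fit.
ls_block_test <- function(y, X0, P, rss0 = NULL) {
  n <- length(y)
  q0 <- qr(X0)
  if (is.null(rss0)) rss0 <- sum(qr.resid(q0, y)^2)
  X1 <- cbind(X0, P)
  q1 <- qr(X1)
  r1 <- q1$rank
  res1 <- qr.resid(q1, y)
  rss1 <- sum(res1^2)
  q_eff <- r1 - q0$rank
  df2 <- n - r1
  note <- ""
  if (q_eff < ncol(P)) note <- "rank_deficient"
  cf <- qr.coef(q1, y)
  pn <- colnames(P) %||% paste0("P", seq_len(ncol(P)))
  est <- stats::setNames(cf[(ncol(X0) + 1L):(ncol(X0) + ncol(P))], pn)
  sigma2 <- if (df2 > 0) rss1 / df2 else NA_real_
  se <- rep(NA_real_, ncol(P)); names(se) <- pn
  kept <- q1$pivot[seq_len(r1)]
  if (df2 > 0 && r1 == ncol(X1)) {
    R <- qr.R(q1)[seq_len(r1), seq_len(r1), drop = FALSE]
    xtxinv <- chol2inv(R)[order(q1$pivot), order(q1$pivot), drop = FALSE]
    se <- sqrt(sigma2 * diag(xtxinv))[(ncol(X0) + 1L):(ncol(X1))]
    names(se) <- pn
  }
  if (q_eff <= 0 || df2 <= 0) {
    f <- NA_real_
  } else if (rss1 <= 1e-12 * max(rss0, 1e-300)) {
    f <- 1e12
    note <- paste0(note, if (nzchar(note)) ";", "perfect_fit")
  } else {
    f <- ((rss0 - rss1) / q_eff) / (rss1 / df2)
  }
  list(F = f, df1 = q_eff, df2 = df2, est = est, se = se,
       sigma2 = sigma2, note = note)
}

#' Single-locus least-squares genome scan
#'
#' At every grid position fits `y = mu + covariates + a*alpha + d*delta +
#' e` by least squares and tests the genetic block against the
#' covariates-only null with an F statistic (2 numerator df for F2, 1
#' for BC). Individuals with missing trait or covariates are dropped
#' listwise; sex-chromosome positions use only homogametic-sex
#' offspring.
#'
#' @param cross a validated [cross_data] object.
#' @param predictors a [genetic_predictors()] object.
#' @param trait phenotype column to analyse.
#' @param covariates character vector of phenotype columns used as fixed
#'   effects.
#' @return a `scan_profile` data.frame: `chromosome`, `position`, `F`,
#'   `df1`, `df2`, `alpha`, `se_alpha`, `delta`, `se_delta`, `sigma2`,
#'   `note`.
#' @export
scan_one <- function(cross, predictors, trait, covariates = NULL) {
  des <- analysis_design(cross, trait, covariates)
  rows <- list()
  for (chrom in names(predictors$chromosomes)) {
    ch <- predictors$chromosomes[[chrom]]
    for (k in seq_along(ch$positions)) {
      a <- ch$a[des$ids, k]
      ok <- !is.na(a)
      P <- cbind(alpha = a)
      if (!is.null(ch$d)) P <- cbind(P, delta = ch$d[des$ids, k])
      r <- ls_block_test(des$y[ok], des$X[ok, , drop = FALSE],
                         P[ok, , drop = FALSE])
      rows[[length(rows) + 1L]] <- data.frame(
        chromosome = chrom, position = ch$positions[k],
        F = r$F, df1 = r$df1, df2 = r$df2,
        alpha = unname(r$est["alpha"]),
        se_alpha = unname(r$se["alpha"]),
        delta = if ("delta" %in% names(r$est)) unname(r$est["delta"]) else NA_real_,
        se_delta = if ("delta" %in% names(r$se)) unname(r$se["delta"]) else NA_real_,
        sigma2 = r$sigma2, note = r$note,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "trait") <- trait
  attr(out, "covariates") <- covariates
  class(out) <- c("scan_profile", "data.frame")
  out
}

# Fast genome-wide max-F over the columns of a trait matrix Y
# (individuals x replicates), sharing the per-position projections.
# Returns a numeric vector of genome-wide maxima.
max_f_multi <- function(cross, predictors, Y, des) {
  best <- rep(-Inf, ncol(Y))
  for (chrom in names(predictors$chromosomes)) {
    ch <- predictors$chromosomes[[chrom]]
    a1 <- ch$a[des$ids, 1L]
    ok <- !is.na(a1)
    Ys <- Y[ok, , drop = FALSE]
    X0 <- des$X[ok, , drop = FALSE]
    q0 <- qr(X0)
    Q0 <- qr.Q(q0)[, seq_len(q0$rank), drop = FALSE]
    cy2 <- colSums(Ys^2)
    rss0 <- cy2 - colSums((crossprod(Q0, Ys))^2)
    n <- sum(ok)
    for (k in seq_along(ch$positions)) {
      P <- cbind(ch$a[des$ids, k][ok])
      if (!is.null(ch$d)) P <- cbind(P, ch$d[des$ids, k][ok])
      X1 <- cbind(X0, P)
      q1 <- qr(X1)
      r1 <- q1$rank
      q_eff <- r1 - q0$rank
      df2 <- n - r1
      if (q_eff <= 0 || df2 <= 0) next
      Q1 <- qr.Q(q1)[, seq_len(r1), drop = FALSE]
      rss1 <- pmax(cy2 - colSums((crossprod(Q1, Ys))^2), 0)
      f <- ((rss0 - rss1) / q_eff) / (rss1 / df2)
      f[rss1 <= 1e-12 * pmax(rss0, 1e-300)] <- 1e12
      best <- pmax(best, f)
    }
  }
  best
}

#' Permutation-based genome-wide significance thresholds
#'
#' Permutes trait values across the analysed individuals (predictors
#' fixed), records the genome-wide maximum statistic of each permuted
#' dataset and returns empirical quantile thresholds (type-7
#' interpolation). Deterministic given `seed`.
#'
#' @param cross,predictors,trait,covariates as in [scan_one()].
#' @param n_perm number of permutations.
#' @param quantiles quantile levels in (0, 1).
#' @param seed integer RNG seed.
#' @param scan_fn optional function(y) -> genome-wide max statistic, for
#'   scans other than the built-in fast single-locus F scan.
#' @return a `perm_dist` object: `max_stats`, named `thresholds`, `seed`.
#' @export
permutation_thresholds <- function(cross, predictors, trait, covariates = NULL,
                                   n_perm = 1000L, quantiles = c(0.95, 0.99),
                                   seed = 1L, scan_fn = NULL) {
  if (any(quantiles <= 0 | quantiles >= 1)) stop_lcq("quantiles must lie in (0,1)")
  des <- analysis_design(cross, trait, covariates)
  n <- length(des$y)
  with_seed(seed, {
    if (is.null(scan_fn)) {
      Y <- vapply(seq_len(n_perm), function(i) des$y[sample.int(n)], numeric(n))
      mx <- max_f_multi(cross, predictors, Y, des)
    } else {
      mx <- vapply(seq_len(n_perm), function(i) scan_fn(des$y[sample.int(n)]),
                   numeric(1L))
    }
    structure(list(max_stats = mx,
                   thresholds = stats::quantile(mx, quantiles, type = 7),
                   quantiles = quantiles, n_perm = n_perm, seed = seed),
              class = "perm_dist")
  })
}

#' @export
print.perm_dist <- function(x, ...) {
  cat(sprintf("perm_dist: %d permutations (seed %d)\n", x$n_perm, x$seed))
  print(x$thresholds)
  invisible(x)
}

#' Two-locus epistasis scan
#'
#' For every pair of grid positions (subsampled to `pair_step_cM`; pairs
#' closer than `min_dist_cM` on the same chromosome are excluded as a
#' collinearity guard) tests the four epistatic interaction terms
#' (aa, ad, da, dd) against the two-locus additive+dominance model with a
#' 4-df F test.
#'
#' @inheritParams scan_one
#' @param pair_step_cM step of the pair grid (coarser than the scan grid).
#' @param min_dist_cM minimum same-chromosome distance between the loci
#'   of a pair.
#' @return an `epistasis_scan` data.frame: `chromosome1`, `position1`,
#'   `chromosome2`, `position2`, `F`, `df1`, `df2`, `aa`, `ad`, `da`,
#'   `dd`, `note`.
#' @export
scan_two_epistasis <- function(cross, predictors, trait, covariates = NULL,
                               pair_step_cM = 5, min_dist_cM = 20) {
  des <- analysis_design(cross, trait, covariates)
  # coarse pair grid
  sites <- list()
  for (chrom in names(predictors$chromosomes)) {
    ch <- predictors$chromosomes[[chrom]]
    pos <- ch$positions
    keep <- c(TRUE, diff(floor(pos / pair_step_cM + 1e-9)) > 0)
    for (k in which(keep)) {
      sites[[length(sites) + 1L]] <- list(chrom = chrom, k = k, pos = pos[k])
    }
  }
  rows <- list()
  for (i in seq_along(sites)) {
    for (j in seq_along(sites)) {
      if (j <= i) next
      s1 <- sites[[i]]; s2 <- sites[[j]]
      if (s1$chrom == s2$chrom && abs(s1$pos - s2$pos) < min_dist_cM) next
      ch1 <- predictors$chromosomes[[s1$chrom]]
      ch2 <- predictors$chromosomes[[s2$chrom]]
      a1 <- ch1$a[des$ids, s1$k]; a2 <- ch2$a[des$ids, s2$k]
      d1 <- if (!is.null(ch1$d)) ch1$d[des$ids, s1$k] else NULL
      d2 <- if (!is.null(ch2$d)) ch2$d[des$ids, s2$k] else NULL
      ok <- !is.na(a1) & !is.na(a2)
      X0 <- cbind(des$X, a1 = a1, a2 = a2)
      if (!is.null(d1)) X0 <- cbind(X0, d1 = d1, d2 = d2)
      P <- cbind(aa = a1 * a2)
      if (!is.null(d1)) {
        P <- cbind(P, ad = a1 * d2, da = d1 * a2, dd = d1 * d2)
      }
      r <- ls_block_test(des$y[ok], X0[ok, , drop = FALSE], P[ok, , drop = FALSE])
      g <- function(nm) if (nm %in% names(r$est)) unname(r$est[nm]) else NA_real_
      rows[[length(rows) + 1L]] <- data.frame(
        chromosome1 = s1$chrom, position1 = s1$pos,
        chromosome2 = s2$chrom, position2 = s2$pos,
        F = r$F, df1 = r$df1, df2 = r$df2,
        aa = g("aa"), ad = g("ad"), da = g("da"), dd = g("dd"),
        note = r$note, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "trait") <- trait
  class(out) <- c("epistasis_scan", "data.frame")
  out
}
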