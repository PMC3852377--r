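#' NOIA design matrix for arbitrary genotype frequencies
#'
#' Builds the 3x3 statistical-formulation design matrix S of the natural
#' and orthogonal interactions (NOIA) model for one biallelic locus with
#' genotype frequencies `p = (p11, p12, p22)` (2, 1, 0 copies of the
#' line-A / increasing allele). Columns are the mean, additive and
#' dominance scales; the frequency-weighted column inner products vanish,
#' which is what makes effect estimates orthogonal. When
#' `D = p11 + p22 - (p11 - p22)^2` is zero (fewer than three genotype
#' classes present) the dominance scale is undefined and is dropped,
#' leaving a 3x2 design flagged `degenerate`.
#'
#' @param p numeric length-3 genotype frequency vector summing to 1.
#' @return a `noia_design`: matrix with rows `g11, g12, g22` and columns
#'   `mean, a, d` (or `mean, a`), with attributes `freqs` and
#'   `degenerate`.
#' @export
#' @examples
#' noia_design(c(0.25, 0.5, 0.25))   # F2: a = (-1,0,1), d = (-1/2,1/2,-1/2)
noia_design <- function(p) {
  if (length(p) != 3L || any(p < -1e-12) || abs(sum(p) - 1) > 1e-8) {
    stop_lcq("genotype frequencies must be 3 nonnegative numbers summing to 1")
  }
  p <- pmax(p, 0); p <- p / sum(p)
  p11 <- p[1L]; p12 <- p[2L]; p22 <- p[3L]
  s_a <- c(-p12 - 2 * p22, 1 - p12 - 2 * p22, 2 - p12 - 2 * p22)
  D <- p11 + p22 - (p11 - p22)^2
  degenerate <- abs(D) < 1e-12
  if (!degenerate) {
    s_d <- c(-2 * p12 * p22, 4 * p11 * p22, -2 * p11 * p12) / D
    S <- cbind(mean = 1, a = s_a, d = s_d)
  } else {
    S <- cbind(mean = 1, a = s_a)
  }
  rownames(S) <- c("g11", "g12", "g22")
  structure(S, freqs = p, degenerate = degenerate, class = c("noia_design", "matrix"))
}

#' Estimate NOIA genetic effects at a genome position
#'
#' Collapses the ordered origin posterior at a grid position to genotype
#' probabilities (p11 = P(AA), p12 = P(AB) + P(BA), p22 = P(BB)),
#' evaluates each individual's expected additive and dominance scale
#' values under the NOIA design at the reference frequencies, and
#' estimates `(R, alpha, delta)` by least squares.
#'
#' @param cross a validated [cross_data] object.
#' @param probs an `origin_prob_table`.
#' @param chromosome,position grid position to analyse.
#' @param trait,covariates as in [scan_one()].
#' @param reference `"sample"` (mean genotype probabilities of the
#'   analysed individuals; the default, under which orthogonality holds),
#'   `"F2"` for the ideal (1/4, 1/2, 1/4), or a numeric length-3 vector.
#' @return a `noia_effects` object: `effects` and `se` (named `R`,
#'   `alpha`, `delta`), the `design`, the reference `freqs` and fit
#'   metadata.
#' @export
estimate_effects_noia <- function(cross, probs, chromosome, position, trait,
                                  covariates = NULL, reference = "sample") {
  ch <- probs$chromosomes[[chromosome]]
  if (is.null(ch)) stop_lcq("chromosome '", chromosome, "' not in probability table")
  k <- which(abs(ch$positions - position) < 1e-9)
  if (!length(k)) stop_lcq("position ", position, " not on the probability grid")
  des <- analysis_design(cross, trait, covariates)
  p3 <- cbind(ch$prob[des$ids, k, "AA"],
              ch$prob[des$ids, k, "AB"] + ch$prob[des$ids, k, "BA"],
              ch$prob[des$ids, k, "BB"])
  ok <- stats::complete.cases(p3)
  p3 <- p3[ok, , drop = FALSE]
  y <- des$y[ok]
  X0 <- des$X[ok, , drop = FALSE]
  ref <- if (identical(reference, "sample")) colMeans(p3)
         else if (identical(reference, "F2")) c(0.25, 0.5, 0.25)
         else reference
  S <- noia_design(ref)
  Z <- p3 %*% S[, -1L, drop = FALSE]   # expected scale values per individual
  X <- cbind(X0, Z)
  fit <- stats::lm.fit(X, y)
  r1 <- fit$rank
  df2 <- length(y) - r1
  sigma2 <- sum(fit$residuals^2) / max(df2, 1L)
  cf <- fit$coefficients
  XtXinv <- tryCatch(chol2inv(chol(crossprod(X))), error = function(e) NULL)
  se_all <- if (!is.null(XtXinv)) sqrt(sigma2 * diag(XtXinv)) else rep(NA_real_, ncol(X))
  nm <- c("R", "alpha", if (!attr(S, "degenerate")) "delta")
  eff <- stats::setNames(c(cf[1L], cf[(ncol(X0) + 1L):ncol(X)]), nm)
  se <- stats::setNames(c(se_all[1L], se_all[(ncol(X0) + 1L):ncol(X)]), nm)
  structure(list(effects = eff, se = se, design = S, freqs = attr(S, "freqs"),
                 n = length(y), sigma2 = sigma2, trait = trait,
                 chromosome = chromosome, position = position),
            class = "noia_effects")
}

#' @export
print.noia_effects <- function(x, ...) {
  cat(sprintf("NOIA effects at %s:%g (trait %s, n = %d)\n",
              x$chromosome, x$position, x$trait, x$n))
  print(cbind(estimate = x$effects, se = x$se))
  invisible(x)
}

#' Translate NOIA effects to another reference population
#'
#' Re-expresses a locus effect vector in the NOIA design of a different
#' set of genotype frequencies: `E2 = solve(S2) %*% S1 %*% E1`. The
#' genotypic values `S %*% E` are exactly preserved.
#'
#' @param effects a `noia_effects` object (non-degenerate design).
#' @param to_freqs target genotype frequencies (length 3, sum 1).
#' @return a `noia_effects` object in the new reference (standard errors
#'   are dropped: they do not transform componentwise).
#' @export
transform_reference <- function(effects, to_freqs) {
  S1 <- effects$design
  if (attr(S1, "degenerate")) stop_lcq("source design is degenerate")
  S2 <- noia_design(to_freqs)
  if (attr(S2, "degenerate")) stop_lcq("target design is degenerate")
  e1 <- effects$effects
  e2 <- drop(solve(S2, S1 %*% e1))
  names(e2) <- c("R", "alpha", "delta")
  out <- effects
  out$effects <- e2
  out$se <- stats::setNames(rep(NA_real_, 3L), names(e2))
  out$design <- S2
  out$freqs <- attr(S2, "freqs")
  out
}

#' Multi-locus NOIA genotype-phenotype map
#'
#' Builds the Kronecker-product design over up to four loci (assuming
#' linkage equilibrium between them) and maps a multi-locus effect
#' vector to genotypic values for all 3^L genotypes. Effect entries are
#' indexed by per-locus scale labels (`m`, `a`, `d`), so e.g. `"aa"` is
#' additive-by-additive epistasis between loci 1 and 2.
#'
#' @param designs list of `noia_design` matrices (all non-degenerate).
#' @param effects named or unnamed numeric vector of length `3^L` in the
#'   Kronecker order of the design columns.
#' @return list with `design` (3^L x 3^L), `labels`, and `values`, the
#'   genotypic value vector named by multi-locus genotypes.
#' @export
multilocus_gp_map <- function(designs, effects) {
  L <- length(designs)
  if (L < 1L || L > 4L) stop_lcq("between 1 and 4 loci supported")
  for (S in designs) {
    if (attr(S, "degenerate")) stop_lcq("degenerate locus design in multi-locus map")
  }
  S <- designs[[1L]]
  labs <- c("m", "a", "d")
  glabs <- rownames(designs[[1L]])
  clabs <- labs
  for (j in seq_len(L)[-1L]) {
    S <- S %x% designs[[j]]
    clabs <- as.vector(t(outer(clabs, labs, paste0)))
    glabs <- as.vector(t(outer(glabs, rownames(designs[[j]]), paste, sep = ":")))
  }
  if (length(effects) != 3^L) stop_lcq("effects must have length 3^L")
  v <- drop(S %*% effects)
  names(v) <- glabs
  dimnames(S) <- list(glabs, clabs)
  list(design = S, labels = clabs, values = v)
}
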