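#' Estimate per-line marker allele frequencies from founders
#'
#' Counting estimator over the genotyped founders of each line with a
#' pseudocount of 0.5 per allele observed anywhere at the marker, so no
#' emission probability is ever exactly zero. Markers with no founder
#' genotypes in a line fall back to the pooled founder counts, and to a
#' uniform distribution over the alleles seen in the population when no
#' founder is genotyped at all.
#'
#' @param cross a [cross_data] object.
#' @return a `line_freqs` object: per marker a list with `alleles`
#'   (sorted allele codes) and frequency vectors `A` and `B`.
#' @export
estimate_line_freqs <- function(cross) {
  ped <- cross$pedigree
  g <- cross$genotypes
  markers <- cross$map$marker
  f0A <- ped$id[ped$generation %in% "F0_A"]
  f0B <- ped$id[ped$generation %in% "F0_B"]
  out <- vector("list", length(markers))
  names(out) <- markers
  for (m in seq_along(markers)) {
    cols <- c(2L * m - 1L, 2L * m)
    obs <- as.vector(g[, cols])
    alleles <- sort(unique(obs[obs > 0L]))
    if (!length(alleles)) { out[m] <- list(NULL); next }
    cnt_line <- function(ids) {
      v <- as.vector(g[intersect(ids, rownames(g)), cols])
      v <- v[v > 0L]
      tabulate(match(v, alleles), nbins = length(alleles))
    }
    ca <- cnt_line(f0A); cb <- cnt_line(f0B)
    pooled <- ca + cb
    freq_of <- function(cnt) {
      if (sum(cnt) == 0L) {
        if (sum(pooled) == 0L) return(rep(1 / length(alleles), length(alleles)))
        cnt <- pooled
      }
      (cnt + 0.5) / (sum(cnt) + 0.5 * length(alleles))
    }
    out[[m]] <- list(alleles = alleles, A = freq_of(ca), B = freq_of(cb))
  }
  structure(list(markers = out), class = "line_freqs")
}

# transmission distribution of a parent at marker index m over the
# marker's allele support; falls back to the parent's line frequencies
# when the parent is not genotyped at the marker.
transmission_dist <- function(cross, freqs, parent_id, m, line) {
  info <- freqs$markers[[m]]
  if (is.null(info)) return(NULL)
  alleles <- info$alleles
  gp <- if (parent_id %in% rownames(cross$genotypes)) {
    cross$genotypes[parent_id, c(2L * m - 1L, 2L * m)]
  } else c(0L, 0L)
  if (all(gp > 0L)) {
    t0 <- numeric(length(alleles))
    i1 <- match(gp[1L], alleles); i2 <- match(gp[2L], alleles)
    t0[i1] <- t0[i1] + 0.5
    t0[i2] <- t0[i2] + 0.5
    t0
  } else {
    info[[line]]
  }
}

#' Posterior allele distributions of F1 homologs
#'
#' For every F1 individual and marker, infers the allele carried on its
#' line-A-derived and line-B-derived homolog. Parental genotypes force
#' the phase where possible; otherwise the distribution is the
#' parent-conditional transmission distribution (falling back to line
#' allele frequencies for ungenotyped parents), renormalised over the
#' phase assignments consistent with the observed F1 genotype. A
#' non-Mendelian F1 genotype yields a finding and the marker is treated
#' as missing for that F1.
#'
#' @param cross a [cross_data] object.
#' @param freqs a [estimate_line_freqs()] result (computed if `NULL`).
#' @return an `f1_homolog_dists` object: `H[[f1_id]][[m]]` is an
#'   (alleles x 2) matrix with columns `A`, `B`; `findings` collects
#'   Mendelian conflicts.
#' @export
infer_f1_homolog_dists <- function(cross, freqs = NULL) {
  if (is.null(freqs)) freqs <- estimate_line_freqs(cross)
  ped <- cross$pedigree
  f1 <- ped$id[ped$generation %in% "F1"]
  markers <- cross$map$marker
  gen_of <- stats::setNames(ped$generation, ped$id)
  H <- vector("list", length(f1)); names(H) <- f1
  findings <- list()
  for (id in f1) {
    i <- match(id, ped$id)
    par <- c(ped$sire[i], ped$dam[i])
    pa <- par[gen_of[par] %in% "F0_A"][1L]
    pb <- par[gen_of[par] %in% "F0_B"][1L]
    Hi <- vector("list", length(markers))
    gobs <- cross$genotypes[id, , drop = TRUE]
    for (m in seq_along(markers)) {
      info <- freqs$markers[[m]]
      if (is.null(info)) { Hi[m] <- list(NULL); next }
      alleles <- info$alleles
      Ta <- transmission_dist(cross, freqs, pa, m, "A")
      Tb <- transmission_dist(cross, freqs, pb, m, "B")
      gm <- gobs[c(2L * m - 1L, 2L * m)]
      Hm <- matrix(0, length(alleles), 2L,
                   dimnames = list(as.character(alleles), c("A", "B")))
      if (any(gm == 0L)) {                 # F1 genotype missing: unconstrained
        Hm[, 1L] <- Ta; Hm[, 2L] <- Tb
      } else {
        x <- match(gm[1L], alleles); y <- match(gm[2L], alleles)
        w_xy <- Ta[x] * Tb[y]              # A-homolog = x, B-homolog = y
        w_yx <- if (x == y) 0 else Ta[y] * Tb[x]
        tot <- w_xy + w_yx
        if (x == y) tot <- w_xy
        if (tot <= 0) {
          findings[[length(findings) + 1L]] <- data.frame(
            severity = "warning",
            message = paste0("non-Mendelian genotype at marker '", markers[m], "'"),
            location = id, stringsAsFactors = FALSE)
          Hm[, 1L] <- Ta; Hm[, 2L] <- Tb
        } else if (x == y) {
          Hm[x, 1L] <- 1; Hm[x, 2L] <- 1
        } else {
          Hm[x, 1L] <- w_xy / tot; Hm[y, 1L] <- w_yx / tot
          Hm[y, 2L] <- w_xy / tot; Hm[x, 2L] <- w_yx / tot
        }
      }
      Hi[[m]] <- Hm
    }
    H[[id]] <- Hi
  }
  structure(list(H = H,
                 findings = if (length(findings)) do.call(rbind, findings) else
                   data.frame(severity = character(0), message = character(0),
                              location = character(0))),
            class = "f1_homolog_dists")
}

# ---- family chains -----------------------------------------------------
# Internal representation of the per-family hidden Markov chain on a
# chromosome: ns states (4 ordered (pat,mat) origins for F2; 2 for the F1
# gamete in BC), locus positions (markers plus requested silent
# positions), transition matrices between consecutive loci and emission
# matrices (n_offspring x ns; NULL at silent loci).

family_chain <- function(cross, freqs, hdists, chrom, off_ids, loci, eps) {
  map <- cross$map
  sel <- which(map$chromosome == chrom)
  mpos <- map$position_cM[sel]
  ped <- cross$pedigree
  gen_of <- stats::setNames(ped$generation, ped$id)
  i1 <- match(off_ids[1L], ped$id)
  sire <- ped$sire[i1]; dam <- ped$dam[i1]
  f2 <- cross$cross_type == "F2"

  if (f2) {
    ns <- 4L
    Hs <- hdists$H[[sire]]; Hm <- hdists$H[[dam]]
  } else {
    ns <- 2L
    f1_is_sire <- identical(gen_of[[sire]], "F1")
    f1p <- if (f1_is_sire) sire else dam
    f0p <- if (f1_is_sire) dam else sire
    f0_line <- if (identical(gen_of[[f0p]], "F0_A")) "A" else "B"
    Hf1 <- hdists$H[[f1p]]
  }

  nm <- length(sel)
  locus_marker <- match(round(loci, 9), round(mpos, 9))
  E <- vector("list", length(loci))
  g <- cross$genotypes
  for (t in seq_along(loci)) {
    mi <- locus_marker[t]
    if (is.na(mi)) next
    m <- sel[mi]
    info <- freqs$markers[[m]]
    if (is.null(info)) next
    alleles <- info$alleles
    ngeno <- length(alleles) * (length(alleles) + 1) / 2
    g1 <- g[off_ids, 2L * m - 1L]
    g2 <- g[off_ids, 2L * m]
    obs <- g1 > 0L & g2 > 0L
    if (!any(obs)) next
    x <- match(g1, c(alleles, NA)); y <- match(g2, c(alleles, NA))
    Em <- matrix(1, length(off_ids), ns)
    if (f2) {
      HA_s <- Hs[[m]]; HA_m <- Hm[[m]]
      for (s in seq_len(ns)) {
        p <- (s - 1L) %/% 2L + 1L   # paternal gamete origin (1=A,2=B)
        q <- (s - 1L) %% 2L + 1L    # maternal gamete origin
        val <- ifelse(g1 == g2,
                      HA_s[x, p] * HA_m[y, q],
                      HA_s[x, p] * HA_m[y, q] + HA_s[y, p] * HA_m[x, q])
        Em[, s] <- (1 - eps) * val + eps / ngeno
      }
    } else {
      Hf <- Hf1[[m]]
      T0 <- transmission_dist(cross, freqs, f0p, m, f0_line)
      for (s in seq_len(ns)) {
        val <- ifelse(g1 == g2,
                      Hf[x, s] * T0[y],
                      Hf[x, s] * T0[y] + Hf[y, s] * T0[x])
        Em[, s] <- (1 - eps) * val + eps / ngeno
      }
    }
    Em[!obs, ] <- 1
    E[[t]] <- Em
  }

  d <- diff(loci)
  Tm <- lapply(d, function(dd) {
    r <- haldane_r(dd)
    t2 <- matrix(c(1 - r, r, r, 1 - r), 2L, 2L)
    if (f2) t2 %x% t2 else t2
  })

  expand <- if (f2) {
    function(p) p
  } else {
    l0 <- if (f0_line == "A") 1L else 2L
    if (f1_is_sire) {
      function(p) {  # pat = F1 gamete, mat = fixed line
        out <- matrix(0, nrow(p), 4L)
        out[, 2L * (1L - 1L) + l0] <- p[, 1L]   # pat A
        out[, 2L * (2L - 1L) + l0] <- p[, 2L]   # pat B
        out
      }
    } else {
      function(p) {  # mat = F1 gamete, pat = fixed line
        out <- matrix(0, nrow(p), 4L)
        out[, 2L * (l0 - 1L) + 1L] <- p[, 1L]
        out[, 2L * (l0 - 1L) + 2L] <- p[, 2L]
        out
      }
    }
  }

  list(ns = ns, loci = loci, E = E, Tm = Tm, off = off_ids, expand = expand)
}

# forward-backward over a family chain; returns list(alpha, marg) where
# both are lists of n_off x ns matrices, rows normalised.
chain_fb <- function(ch) {
  L <- length(ch$loci)
  n <- length(ch$off)
  ns <- ch$ns
  init <- matrix(1 / ns, n, ns)
  alpha <- vector("list", L)
  a <- init
  if (!is.null(ch$E[[1L]])) a <- a * ch$E[[1L]]
  a <- a / rowSums(a)
  alpha[[1L]] <- a
  for (t in seq_len(L - 1L)) {
    a <- alpha[[t]] %*% ch$Tm[[t]]
    if (!is.null(ch$E[[t + 1L]])) a <- a * ch$E[[t + 1L]]
    a <- a / rowSums(a)
    alpha[[t + 1L]] <- a
  }
  marg <- vector("list", L)
  b <- matrix(1, n, ns)
  marg[[L]] <- alpha[[L]]
  if (L > 1L) {
    for (t in (L - 1L):1L) {
      be <- b
      if (!is.null(ch$E[[t + 1L]])) be <- be * ch$E[[t + 1L]]
      b <- be %*% t(ch$Tm[[t]])
      b <- b / rowSums(b)
      mg <- alpha[[t]] * b
      marg[[t]] <- mg / rowSums(mg)
    }
  }
  list(alpha = alpha, marg = marg)
}

grid_positions <- function(end, step) {
  g <- seq(0, end, by = step)
  if (abs(g[length(g)] - end) > 1e-9) g <- c(g, end)
  g
}

offspring_ids <- function(cross) {
  gen <- if (cross$cross_type == "F2") "F2" else "BC"
  cross$pedigree$id[cross$pedigree$generation %in% gen]
}

# offspring analyzable on a chromosome: all of them on autosomes, only
# the homogametic sex on the sex chromosome.
chrom_offspring <- function(cross, chrom) {
  ids <- offspring_ids(cross)
  kind <- cross$map$kind[match(chrom, cross$map$chromosome)]
  if (identical(kind, "sex")) {
    homo <- if (cross$heterogametic_sex == "male") "female" else "male"
    sex <- cross$pedigree$sex[match(ids, cross$pedigree$id)]
    ids <- ids[sex == homo]
  }
  ids
}

#' Posterior line-origin probabilities on a position grid
#'
#' Runs the forward-backward algorithm of the line-origin hidden Markov
#' model for every mapping-generation offspring. Hidden states are the
#' ordered pairs of founder-line origins of the paternal and maternal
#' gamete (AA, AB, BA, BB); for a backcross the gamete from the founder
#' parent has a fixed origin, leaving an effective 2-state chain.
#' Transitions between loci use the Haldane map function independently
#' per gamete; marker emissions marginalise the transmitting parents'
#' homolog allele distributions and are mixed with a uniform
#' genotyping-error component `(1 - error_rate) * P + error_rate * U`.
#' Grid positions between markers are silent states. On the sex
#' chromosome only homogametic-sex offspring are processed; others get
#' `NA` rows.
#'
#' @param cross a validated [cross_data] object.
#' @param step_cM grid step in cM (> 0); the chromosome end is always
#'   included.
#' @param error_rate genotyping-error mixture weight (default 0.001).
#' @param positions optional named list (chromosome -> numeric vector)
#'   overriding the grid.
#' @param freqs,hdists optional precomputed [estimate_line_freqs()] /
#'   [infer_f1_homolog_dists()] results.
#' @return an `origin_prob_table`: per chromosome a list with
#'   `positions` and `prob`, an individuals x positions x 4 array with
#'   state order `AA, AB, BA, BB` (paternal origin first).
#' @export
line_origin_probs <- function(cross, step_cM = 1, error_rate = 0.001,
                              positions = NULL, freqs = NULL, hdists = NULL) {
  if (step_cM <= 0) stop_lcq("step_cM must be > 0")
  assert_valid_cross(cross)
  if (is.null(freqs)) freqs <- estimate_line_freqs(cross)
  if (is.null(hdists)) hdists <- infer_f1_homolog_dists(cross, freqs)
  map <- cross$map
  chroms <- unique(map$chromosome)
  all_off <- offspring_ids(cross)
  out <- vector("list", length(chroms)); names(out) <- chroms
  states <- c("AA", "AB", "BA", "BB")
  for (chrom in chroms) {
    mpos <- map$position_cM[map$chromosome == chrom]
    want <- if (!is.null(positions) && !is.null(positions[[chrom]])) {
      sort(unique(positions[[chrom]]))
    } else {
      grid_positions(max(mpos), step_cM)
    }
    loci <- sort(unique(round(c(mpos, want), 9)))
    keep <- match(round(want, 9), loci)
    ids <- chrom_offspring(cross, chrom)
    prob <- array(NA_real_, dim = c(length(all_off), length(want), 4L),
                  dimnames = list(all_off, NULL, states))
    ped <- cross$pedigree
    fam <- split(ids, paste(ped$sire[match(ids, ped$id)],
                            ped$dam[match(ids, ped$id)]))
    for (off in fam) {
      ch <- family_chain(cross, freqs, hdists, chrom, off, loci, error_rate)
      fb <- chain_fb(ch)
      for (k in seq_along(keep)) {
        prob[off, k, ] <- ch$expand(fb$marg[[keep[k]]])
      }
    }
    out[[chrom]] <- list(positions = want, prob = prob)
  }
  structure(list(chromosomes = out, individuals = all_off,
                 cross_type = cross$cross_type, step_cM = step_cM,
                 error_rate = error_rate),
            class = "origin_prob_table")
}

#' Exhaustive-enumeration line-origin posterior (test oracle)
#'
#' Computes the posterior origin marginals for one offspring on one
#' chromosome by summing the joint probability over all ordered origin
#' sequences, using the same transition and emission terms as
#' [line_origin_probs()]. Exponential in the number of loci; refuses more
#' than 6 markers.
#'
#' @param cross a validated [cross_data] object.
#' @param individual offspring id.
#' @param chromosome chromosome name.
#' @param error_rate genotyping-error mixture weight.
#' @param positions optional extra (silent) positions to report.
#' @return matrix positions x 4 of marginals (states AA, AB, BA, BB).
#' @export
brute_force_origin_posterior <- function(cross, individual, chromosome,
                                         error_rate = 0.001, positions = NULL) {
  map <- cross$map
  mpos <- map$position_cM[map$chromosome == chromosome]
  if (length(mpos) > 6L) stop_lcq("brute force limited to <= 6 markers")
  freqs <- estimate_line_freqs(cross)
  hdists <- infer_f1_homolog_dists(cross, freqs)
  loci <- sort(unique(round(c(mpos, positions), 9)))
  ch <- family_chain(cross, freqs, hdists, chromosome, individual, loci,
                     error_rate)
  L <- length(loci); ns <- ch$ns
  marg <- matrix(0, L, ns)
  states <- rep(1L, L)
  repeat {
    w <- 1 / ns
    if (!is.null(ch$E[[1L]])) w <- w * ch$E[[1L]][1L, states[1L]]
    if (L > 1L) {
      for (t in seq_len(L - 1L)) {
        w <- w * ch$Tm[[t]][states[t], states[t + 1L]]
        if (!is.null(ch$E[[t + 1L]])) w <- w * ch$E[[t + 1L]][1L, states[t + 1L]]
      }
    }
    for (t in seq_len(L)) marg[t, states[t]] <- marg[t, states[t]] + w
    # next state vector (odometer)
    t <- 1L
    while (t <= L) {
      states[t] <- states[t] + 1L
      if (states[t] <= ns) break
      states[t] <- 1L
      t <- t + 1L
    }
    if (t > L) break
  }
  marg <- marg / rowSums(marg)
  out <- ch$expand(marg)
  rownames(out) <- format(loci)
  colnames(out) <- c("AA", "AB", "BA", "BB")
  idx <- if (is.null(positions)) seq_len(L) else match(round(positions, 9), loci)
  out[idx, , drop = FALSE]
}

#' Sample joint line-origin paths
#'
#' Draws joint origin paths for every offspring by forward
#' filtering-backward sampling from the exact chain posterior, at the
#' marker loci plus any requested positions. Deterministic given `seed`.
#'
#' @param cross a validated [cross_data] object.
#' @param n_samples number of paths per offspring (>= 1).
#' @param seed integer RNG seed.
#' @param error_rate genotyping-error mixture weight.
#' @param positions optional named list (chromosome -> numeric) of extra
#'   positions to include as silent loci.
#' @param freqs,hdists optional precomputed helper objects.
#' @return list per chromosome: `positions` and `states`, an individuals
#'   x loci x n_samples integer array of ordered states (1 = AA, 2 = AB,
#'   3 = BA, 4 = BB).
#' @export
sample_origin_paths <- function(cross, n_samples, seed = 1L,
                                error_rate = 0.001, positions = NULL,
                                freqs = NULL, hdists = NULL) {
  if (n_samples < 1L) stop_lcq("n_samples must be >= 1")
  if (is.null(freqs)) freqs <- estimate_line_freqs(cross)
  if (is.null(hdists)) hdists <- infer_f1_homolog_dists(cross, freqs)
  map <- cross$map
  chroms <- unique(map$chromosome)
  all_off <- offspring_ids(cross)
  with_seed(seed, {
    out <- vector("list", length(chroms)); names(out) <- chroms
    for (chrom in chroms) {
      mpos <- map$position_cM[map$chromosome == chrom]
      loci <- sort(unique(round(c(mpos, positions[[chrom]]), 9)))
      ids <- chrom_offspring(cross, chrom)
      st <- array(NA_integer_,
                  dim = c(length(all_off), length(loci), n_samples),
                  dimnames = list(all_off, NULL, NULL))
      ped <- cross$pedigree
      fam <- split(ids, paste(ped$sire[match(ids, ped$id)],
                              ped$dam[match(ids, ped$id)]))
      for (off in fam) {
        ch <- family_chain(cross, freqs, hdists, chrom, off, loci, error_rate)
        fb <- chain_fb(ch)
        L <- length(loci)
        for (k in seq_len(n_samples)) {
          s <- matrix(NA_integer_, length(off), L)
          s[, L] <- row_categorical(fb$alpha[[L]])
          if (L > 1L) {
            for (t in (L - 1L):1L) {
              w <- fb$alpha[[t]] * t(ch$Tm[[t]])[s[, t + 1L], , drop = FALSE]
              s[, t] <- row_categorical(w)
            }
          }
          if (ch$ns == 2L) {
            # expand the 2-state BC chain to ordered 4-state codes
            e1 <- which(ch$expand(matrix(c(1, 0), 1L))[1L, ] > 0)
            e2 <- which(ch$expand(matrix(c(0, 1), 1L))[1L, ] > 0)
            s <- matrix(c(e1, e2)[s], nrow(s), ncol(s))
          }
          st[off, , k] <- s
        }
      }
      out[[chrom]] <- list(positions = loci, states = st)
    }
    out
  })
}
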