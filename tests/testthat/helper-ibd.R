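# Exhaustive-enumeration IBD oracle for a no-marker-data toy pedigree:
# two F1 parents (possibly sharing founders) and a set of F2 offspring.
# Enumerates the 2^(#F1 homologs) segregation indicators and 4^n_off
# ordered origin states, all uniform, and returns the exact expected Pi.
enum_ibd_oracle <- function(f1_parents, n_off) {
  # f1_parents: list of two elements, each c(A = founderA_id, B = founderB_id)
  founders <- unique(unlist(f1_parents))
  lab_of <- function(founder, seg) 2L * (match(founder, founders) - 1L) + seg
  nlab <- 2L * length(founders)
  segs <- expand.grid(rep(list(1:2), 4L))   # (F1_1 A, F1_1 B, F1_2 A, F1_2 B)
  states <- expand.grid(rep(list(1:4), n_off))
  Pi <- matrix(0, n_off, n_off)
  for (si in seq_len(nrow(segs))) {
    sg <- as.integer(segs[si, ])
    glab <- rbind(c(lab_of(f1_parents[[1]]["A"], sg[1]),
                    lab_of(f1_parents[[1]]["B"], sg[2])),
                  c(lab_of(f1_parents[[2]]["A"], sg[3]),
                    lab_of(f1_parents[[2]]["B"], sg[4])))
    for (oi in seq_len(nrow(states))) {
      st <- as.integer(states[oi, ])
      pat_h <- (st - 1L) %/% 2L + 1L
      mat_h <- (st - 1L) %% 2L + 1L
      Z <- matrix(0, n_off, nlab)
      for (i in seq_len(n_off)) {
        Z[i, glab[1L, pat_h[i]]] <- Z[i, glab[1L, pat_h[i]]] + 1
        Z[i, glab[2L, mat_h[i]]] <- Z[i, glab[2L, mat_h[i]]] + 1
      }
      Pi <- Pi + tcrossprod(Z) / 2
    }
  }
  Pi / (nrow(segs) * nrow(states))
}

# toy cross matching the oracle: F1_1 = A1 x B1, F1_2 = A2 x B1 (shared
# founder B1 creates inbreeding), all genotypes missing.
toy_ibd_cross <- function(n_off = 3) {
  off <- paste0("F2_", seq_len(n_off))
  ped <- data.frame(
    id = c("A1", "A2", "B1", "F1_1", "F1_2", off),
    sire = c(NA, NA, NA, "A1", "A2", rep("F1_1", n_off)),
    dam = c(NA, NA, NA, "B1", "B1", rep("F1_2", n_off)),
    sex = c("male", "male", "female", "male", "female",
            rep("unknown", n_off)),
    line = c("A", "A", "B", NA, NA, rep(NA, n_off)),
    stringsAsFactors = FALSE)
  map <- data.frame(chromosome = "chr1", marker = c("m1", "m2"),
                    position_cM = c(0, 10), kind = "autosome")
  g <- matrix(0L, nrow(ped), 4, dimnames = list(ped$id, c("m1_1", "m1_2", "m2_1", "m2_2")))
  cross_data(ped, g, map, data.frame(id = off, w = rnorm(n_off)),
             cross_type = "F2")
}

# independent piecewise lookup used by the meiosis calibration test
pw_value_test <- function(h, pos) h$label[findInterval(pos, h$start)]
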