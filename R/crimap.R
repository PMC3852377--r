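#' Read a simplified CRI-MAP-style .gen file
#'
#' The dialect (a documented approximation of the classic linkage-format
#' `.gen` file, not a bit-exact clone): line 1 holds the number of
#' families; each family block is a family-name line, a member-count line,
#' then per member the record `id dam sire sex` followed by one
#' whitespace-separated allele pair per mapped locus, in map order. Sex is
#' coded 1 = male, 0 = female, anything else = unknown; the allele pair
#' `0 0` means missing. Family blocks are concatenated into a single
#' pedigree. Tokens may be broken across lines arbitrarily.
#'
#' @param gen_path path to the `.gen` file.
#' @param map_path path to the map TSV (`chromosome marker position_cM kind`).
#' @param ... cross attributes forwarded to [cross_data()]
#'   (e.g. `cross_type`).
#' @return a validated [cross_data] object.
#' @export
read_crimap_gen <- function(gen_path, map_path, ...) {
  if (!file.exists(gen_path)) stop_lcq(gen_path, ": file not found")
  map <- normalize_map(read_tsv_checked(map_path))
  markers <- map$marker
  nloc <- length(markers)
  tok <- scan(gen_path, what = character(), quiet = TRUE)
  pos <- 1L
  take <- function(n, what) {
    if (pos + n - 1L > length(tok)) {
      stop_lcq(gen_path, ": unexpected end of file while reading ", what)
    }
    out <- tok[pos:(pos + n - 1L)]
    pos <<- pos + n
    out
  }
  nfam <- suppressWarnings(as.integer(take(1L, "family count")))
  if (is.na(nfam) || nfam < 1L) stop_lcq(gen_path, ": bad family count")
  recs <- list()
  for (f in seq_len(nfam)) {
    fam <- take(1L, "family name")
    nmem <- suppressWarnings(as.integer(take(1L, paste0("member count of family '", fam, "'"))))
    if (is.na(nmem) || nmem < 1L) {
      stop_lcq(gen_path, ": bad member count in family '", fam, "'")
    }
    for (m in seq_len(nmem)) {
      hdr <- take(4L, paste0("member record in family '", fam, "'"))
      alle <- suppressWarnings(as.integer(take(2L * nloc,
                paste0("genotypes of '", hdr[1L], "' in family '", fam, "'"))))
      if (anyNA(alle)) {
        stop_lcq(gen_path, ": non-integer allele for '", hdr[1L],
                 "' in family '", fam, "'")
      }
      recs[[length(recs) + 1L]] <- list(id = hdr[1L], dam = hdr[2L],
                                        sire = hdr[3L], sex = hdr[4L],
                                        alleles = alle)
    }
  }
  if (pos <= length(tok)) {
    stop_lcq(gen_path, ": ", length(tok) - pos + 1L,
             " trailing token(s); declared counts disagree with records")
  }
  ids <- vapply(recs, `[[`, "", "id")
  ped <- data.frame(id = ids,
                    sire = vapply(recs, `[[`, "", "sire"),
                    dam = vapply(recs, `[[`, "", "dam"),
                    sex = ifelse(vapply(recs, `[[`, "", "sex") == "1", "male",
                          ifelse(vapply(recs, `[[`, "", "sex") == "0", "female",
                                 "unknown")),
                    stringsAsFactors = FALSE)
  g <- do.call(rbind, lapply(recs, `[[`, "alleles"))
  rownames(g) <- ids
  colnames(g) <- as.vector(rbind(paste0(markers, "_1"), paste0(markers, "_2")))
  cross <- cross_data(pedigree = ped, genotypes = g, map = map, ...)
  assert_valid_cross(cross)
  cross
}

#' Write a cross in the simplified .gen dialect
#'
#' Exports the genotypes and pedigree of a cross as a single family block
#' in the dialect read by [read_crimap_gen()]. Phenotypes, generation
#' labels and line assignments are not representable in the dialect and
#' are dropped.
#'
#' @param cross a [cross_data] object.
#' @param gen_path output path.
#' @param family family-name token (default `"fam1"`).
#' @return invisibly, `gen_path`.
#' @export
write_crimap_gen <- function(cross, gen_path, family = "fam1") {
  ped <- cross$pedigree
  g <- cross$genotypes
  con <- file(gen_path, "w")
  on.exit(close(con))
  writeLines(c("1", family, as.character(nrow(ped))), con)
  sex_code <- c(male = "1", female = "0", unknown = "9")
  for (i in seq_len(nrow(ped))) {
    id <- ped$id[i]
    dam <- if (is.na(ped$dam[i])) "0" else ped$dam[i]
    sire <- if (is.na(ped$sire[i])) "0" else ped$sire[i]
    writeLines(paste(id, dam, sire, sex_code[[ped$sex[i]]]), con)
    # one allele pair per locus, map order
    writeLines(paste(g[id, ], collapse = " "), con)
  }
  invisible(gen_path)
}
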