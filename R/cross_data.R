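#' Cross data container for two-line QTL experiments
#'
#' A `cross_data` object bundles everything a line-cross QTL analysis
#' needs: a pedigree, marker genotypes, a genetic map, phenotypes and the
#' cross-level attributes (cross type, heterogametic sex, sex chromosome).
#' Analysis functions append their output to the `results` element.
#'
#' @section Components:
#' \describe{
#'   \item{pedigree}{data.frame with columns `id`, `sire`, `dam`, `sex`
#'     (`"female"`, `"male"` or `"unknown"`), `generation` (one of
#'     `"F0_A"`, `"F0_B"`, `"F1"`, `"F2"`, `"BC"`) and `line` (`"A"`,
#'     `"B"` or `NA`). Ordered so parents precede offspring.}
#'   \item{genotypes}{integer matrix, one row per individual (rownames are
#'     ids), two columns per marker named `<marker>_1` / `<marker>_2`;
#'     allele codes are positive integers, 0 means missing.}
#'   \item{map}{data.frame `chromosome`, `marker`, `position_cM`, `kind`
#'     (`"autosome"` or `"sex"`); positions strictly increasing within a
#'     chromosome.}
#'   \item{phenotypes}{data.frame with an `id` column followed by trait
#'     and covariate columns; `NA` marks missing values.}
#'   \item{cross_type}{`"F2"` or `"BC"`.}
#'   \item{heterogametic_sex}{`"male"` or `"female"`; individuals of this
#'     sex are excluded from sex-chromosome analyses.}
#'   \item{sex_chromosome}{chromosome name, or `NULL` when the map has no
#'     sex chromosome.}
#' }
#'
#' @param pedigree,genotypes,map,phenotypes see Components.
#' @param cross_type `"F2"` or `"BC"`.
#' @param heterogametic_sex `"male"` (default) or `"female"`.
#' @param sex_chromosome chromosome name or `NULL`.
#' @return an object of class `cross_data`.
#' @export
cross_data <- function(pedigree, genotypes, map, phenotypes = NULL,
                       cross_type = c("F2", "BC"),
                       heterogametic_sex = c("male", "female"),
                       sex_chromosome = NULL) {
  cross_type <- match.arg(cross_type)
  heterogametic_sex <- match.arg(heterogametic_sex)

  pedigree <- normalize_pedigree(pedigree)
  pedigree <- toposort_pedigree(pedigree)
  pedigree <- infer_lines(pedigree)
  pedigree <- infer_generations(pedigree)

  map <- normalize_map(map)
  genotypes <- normalize_genotypes(genotypes, map)

  if (is.null(phenotypes)) {
    phenotypes <- data.frame(id = character(0), stringsAsFactors = FALSE)
  }
  if (!"id" %in% names(phenotypes)) {
    stop_lcq("phenotype table must have an 'id' column")
  }
  phenotypes$id <- as.character(phenotypes$id)

  obj <- structure(
    list(pedigree = pedigree, genotypes = genotypes, map = map,
         phenotypes = phenotypes,
         cross_type = cross_type,
         heterogametic_sex = heterogametic_sex,
         sex_chromosome = sex_chromosome,
         results = list()),
    class = "cross_data")
  obj
}

#' @export
print.cross_data <- function(x, ...) {
  nmark <- nrow(x$map)
  cat(sprintf("cross_data: %s cross, %d individuals, %d markers on %d chromosome(s)\n",
              x$cross_type, nrow(x$pedigree), nmark,
              length(unique(x$map$chromosome))))
  gen <- table(x$pedigree$generation, useNA = "ifany")
  cat("  generations:", paste(sprintf("%s=%d", names(gen), gen), collapse = ", "), "\n")
  traits <- setdiff(names(x$phenotypes), "id")
  if (length(traits)) cat("  phenotype columns:", paste(traits, collapse = ", "), "\n")
  if (!is.null(x$sex_chromosome))
    cat("  sex chromosome:", x$sex_chromosome,
        sprintf("(heterogametic sex: %s)\n", x$heterogametic_sex))
  if (length(x$results)) cat("  results:", paste(names(x$results), collapse = ", "), "\n")
  invisible(x)
}

normalize_pedigree <- function(ped) {
  ped <- as.data.frame(ped, stringsAsFactors = FALSE)
  need <- c("id", "sire", "dam")
  if (!all(need %in% names(ped))) {
    stop_lcq("pedigree needs columns id, sire, dam")
  }
  ped$id <- as.character(ped$id)
  if (anyDuplicated(ped$id)) {
    stop_lcq("duplicated pedigree id: ",
             paste(unique(ped$id[duplicated(ped$id)]), collapse = ", "))
  }
  blank <- function(x) {
    x <- as.character(x)
    x[is.na(x) | x %in% c("", "0", "NA")] <- NA_character_
    x
  }
  ped$sire <- blank(ped$sire)
  ped$dam <- blank(ped$dam)
  if (!"sex" %in% names(ped)) ped$sex <- "unknown"
  sx <- tolower(as.character(ped$sex))
  sx[sx %in% c("f", "female", "2")] <- "female"
  sx[sx %in% c("m", "male", "1")] <- "male"
  sx[!sx %in% c("female", "male")] <- "unknown"
  ped$sex <- sx
  if (!"generation" %in% names(ped)) ped$generation <- NA_character_
  ped$generation <- blank(ped$generation)
  if (!"line" %in% names(ped)) ped$line <- NA_character_
  ped$line <- blank(ped$line)
  bad <- setdiff(stats::na.omit(c(ped$sire, ped$dam)), ped$id)
  if (length(bad)) {
    stop_lcq("pedigree references unknown parent id(s): ",
             paste(bad, collapse = ", "))
  }
  rownames(ped) <- NULL
  ped[c("id", "sire", "dam", "sex", "generation", "line")]
}

# Kahn topological sort so that parents always precede offspring; stable
# for already-sorted input.
toposort_pedigree <- function(ped) {
  n <- nrow(ped)
  idx <- stats::setNames(seq_len(n), ped$id)
  indeg <- integer(n)
  children <- vector("list", n)
  for (i in seq_len(n)) {
    for (p in c(ped$sire[i], ped$dam[i])) {
      if (!is.na(p)) {
        j <- idx[[p]]
        indeg[i] <- indeg[i] + 1L
        children[[j]] <- c(children[[j]], i)
      }
    }
  }
  queue <- which(indeg == 0L)
  out <- integer(0)
  while (length(queue)) {
    i <- queue[1L]; queue <- queue[-1L]
    out <- c(out, i)
    for (ch in children[[i]]) {
      indeg[ch] <- indeg[ch] - 1L
      if (indeg[ch] == 0L) queue <- sort(c(queue, ch))
    }
  }
  if (length(out) != n) stop_lcq("pedigree contains a cycle")
  ped[out, , drop = FALSE]
}

# Assign founders to lines A/B by two-colouring the founder mating graph:
# the two founder parents of any individual must come from opposite lines.
# Components with an explicit `line` entry are anchored on it; otherwise
# the first-listed founder of the component is put in line A.
infer_lines <- function(ped) {
  is_f0 <- is.na(ped$sire) & is.na(ped$dam)
  f0 <- ped$id[is_f0]
  if (!length(f0)) return(ped)
  nbr <- stats::setNames(vector("list", length(f0)), f0)
  for (i in seq_len(nrow(ped))) {
    s <- ped$sire[i]; d <- ped$dam[i]
    if (!is.na(s) && !is.na(d) && s %in% f0 && d %in% f0) {
      nbr[[s]] <- union(nbr[[s]], d)
      nbr[[d]] <- union(nbr[[d]], s)
    }
  }
  line <- stats::setNames(ped$line[is_f0], f0)
  gen <- stats::setNames(ped$generation[is_f0], f0)
  line[is.na(line) & gen %in% "F0_A"] <- "A"
  line[is.na(line) & gen %in% "F0_B"] <- "B"
  seen <- stats::setNames(rep(FALSE, length(f0)), f0)
  for (start in f0) {
    if (seen[[start]]) next
    # collect component
    comp <- character(0); queue <- start
    while (length(queue)) {
      v <- queue[1L]; queue <- queue[-1L]
      if (seen[[v]]) next
      seen[[v]] <- TRUE
      comp <- c(comp, v)
      queue <- c(queue, setdiff(nbr[[v]], comp))
    }
    anchored <- comp[!is.na(line[comp])]
    anchor <- if (length(anchored)) anchored[1L] else comp[1L]
    if (is.na(line[[anchor]])) line[[anchor]] <- "A"
    queue <- anchor
    while (length(queue)) {
      v <- queue[1L]; queue <- queue[-1L]
      opp <- if (line[[v]] == "A") "B" else "A"
      for (w in nbr[[v]]) {
        if (is.na(line[[w]])) {
          line[[w]] <- opp
          queue <- c(queue, w)
        }
      }
    }
  }
  ped$line[is_f0] <- line[ped$id[is_f0]]
  ped
}

# Structural generation inference: no parents -> F0_A/F0_B (by line),
# F0xF0 across lines -> F1, F1xF1 -> F2, F1xF0 -> BC. An explicit
# generation column wins; conflicts surface in validate_cross().
infer_generations <- function(ped) {
  gen <- stats::setNames(ped$generation, ped$id)
  line <- stats::setNames(ped$line, ped$id)
  for (i in seq_len(nrow(ped))) {
    id <- ped$id[i]
    if (!is.na(gen[[id]])) next
    s <- ped$sire[i]; d <- ped$dam[i]
    if (is.na(s) && is.na(d)) {
      gen[[id]] <- if (!is.na(line[[id]])) paste0("F0_", line[[id]]) else NA_character_
      next
    }
    if (is.na(s) || is.na(d)) next   # half-known parentage: leave NA
    gs <- gen[[s]]; gd <- gen[[d]]
    f0s <- !is.na(gs) && startsWith(gs, "F0")
    f0d <- !is.na(gd) && startsWith(gd, "F0")
    if (f0s && f0d && !is.na(gs) && !is.na(gd) && gs != gd) gen[[id]] <- "F1"
    else if (identical(gs, "F1") && identical(gd, "F1")) gen[[id]] <- "F2"
    else if ((identical(gs, "F1") && f0d) || (f0s && identical(gd, "F1"))) gen[[id]] <- "BC"
  }
  ped$generation <- unname(gen[ped$id])
  ped
}

normalize_map <- function(map) {
  map <- as.data.frame(map, stringsAsFactors = FALSE)
  need <- c("chromosome", "marker", "position_cM")
  if (!all(need %in% names(map))) {
    stop_lcq("map needs columns chromosome, marker, position_cM")
  }
  if (!"kind" %in% names(map)) map$kind <- "autosome"
  map$chromosome <- as.character(map$chromosome)
  map$marker <- as.character(map$marker)
  map$position_cM <- as.numeric(map$position_cM)
  if (anyDuplicated(map$marker)) stop_lcq("duplicated marker names in map")
  map <- map[order(match(map$chromosome, unique(map$chromosome)), map$position_cM), ]
  rownames(map) <- NULL
  map[c("chromosome", "marker", "position_cM", "kind")]
}

normalize_genotypes <- function(g, map) {
  g <- as.matrix(g)
  storage.mode(g) <- "integer"
  g[is.na(g)] <- 0L
  expect <- as.vector(rbind(paste0(map$marker, "_1"), paste0(map$marker, "_2")))
  if (is.null(colnames(g)) && ncol(g) == length(expect)) colnames(g) <- expect
  missing_cols <- setdiff(expect, colnames(g))
  if (length(missing_cols)) {
    stop_lcq("genotype table lacks columns for marker(s): ",
             paste(unique(sub("_[12]$", "", missing_cols)), collapse = ", "))
  }
  g[, expect, drop = FALSE]
}

#' Validate a cross_data object
#'
#' Runs structural consistency checks and returns a data.frame of findings
#' (`severity` in `info`/`warning`/`error`, `message`, `location`); an
#' empty data.frame means the object is clean. The input is never
#' modified.
#'
#' @param cross a [cross_data] object.
#' @return data.frame with columns `severity`, `message`, `location`.
#' @export
validate_cross <- function(cross) {
  f <- list()
  add <- function(severity, message, location = "") {
    f[[length(f) + 1L]] <<- data.frame(severity = severity, message = message,
                                       location = location,
                                       stringsAsFactors = FALSE)
  }
  ped <- cross$pedigree
  idx <- stats::setNames(seq_len(nrow(ped)), ped$id)

  for (i in seq_len(nrow(ped))) {
    for (p in c(ped$sire[i], ped$dam[i])) {
      if (!is.na(p)) {
        if (!p %in% ped$id) {
          add("error", paste0("unknown parent id '", p, "'"), ped$id[i])
        } else if (idx[[p]] > i) {
          add("error", paste0("parent '", p, "' listed after offspring"), ped$id[i])
        }
      }
    }
  }

  pgen <- function(p) if (is.na(p) || !p %in% ped$id) NA_character_ else
    ped$generation[idx[[p]]]
  for (i in seq_len(nrow(ped))) {
    g <- ped$generation[i]
    if (is.na(g)) {
      add("error", "generation could not be inferred", ped$id[i])
      next
    }
    gs <- pgen(ped$sire[i]); gd <- pgen(ped$dam[i])
    both_f0 <- function() !is.na(gs) && !is.na(gd) &&
      startsWith(gs, "F0") && startsWith(gd, "F0")
    ok <- switch(g,
      F0_A = , F0_B = is.na(ped$sire[i]) && is.na(ped$dam[i]),
      F1 = both_f0() && gs != gd,
      F2 = identical(gs, "F1") && identical(gd, "F1"),
      BC = (identical(gs, "F1") && !is.na(gd) && startsWith(gd, "F0")) ||
           (identical(gd, "F1") && !is.na(gs) && startsWith(gs, "F0")),
      FALSE)
    if (!isTRUE(ok)) {
      add("error", paste0("generation '", g, "' inconsistent with parents"),
          ped$id[i])
    }
  }

  map <- cross$map
  for (chr in unique(map$chromosome)) {
    pos <- map$position_cM[map$chromosome == chr]
    mk <- map$marker[map$chromosome == chr]
    if (any(pos < 0)) add("error", "negative map position", chr)
    bad <- which(diff(pos) <= 0)
    for (b in bad) {
      add("error", paste0("non-increasing position at marker '", mk[b + 1L], "'"), chr)
    }
  }
  sex_chr <- unique(map$chromosome[map$kind == "sex"])
  if (length(sex_chr) > 1L) {
    add("error", "more than one sex chromosome in map", paste(sex_chr, collapse = ","))
  }
  if (length(sex_chr) == 1L && is.null(cross$sex_chromosome)) {
    add("error", "map has a sex chromosome but sex_chromosome attribute unset", sex_chr)
  }
  if (!is.null(cross$sex_chromosome) && !cross$sex_chromosome %in% sex_chr) {
    add("error", "sex_chromosome attribute does not match map", cross$sex_chromosome)
  }

  g <- cross$genotypes
  unknown <- setdiff(rownames(g), ped$id)
  for (u in unknown) add("error", paste0("genotyped individual '", u, "' not in pedigree"), u)
  if (any(g < 0L, na.rm = TRUE)) add("error", "negative allele code in genotypes", "")

  unknown_ph <- setdiff(cross$phenotypes$id, ped$id)
  for (u in unknown_ph) add("error", paste0("phenotyped individual '", u, "' not in pedigree"), u)
  if (anyDuplicated(names(cross$phenotypes))) {
    add("error", "duplicated phenotype column name", "")
  }

  off_gen <- if (cross$cross_type == "F2") "F2" else "BC"
  if (!any(ped$generation %in% off_gen)) {
    add("warning", paste0("no ", off_gen, " individuals for a ", cross$cross_type, " cross"), "")
  }
  if (length(f)) do.call(rbind, f) else
    data.frame(severity = character(0), message = character(0),
               location = character(0), stringsAsFactors = FALSE)
}

#' Stop unless a cross validates cleanly
#' @keywords internal
assert_valid_cross <- function(cross) {
  if (!inherits(cross, "cross_data")) stop_lcq("not a cross_data object")
  v <- validate_cross(cross)
  if (any(v$severity == "error")) {
    stop_lcq("cross_data fails validation: ",
             paste(utils::head(v$message[v$severity == "error"], 3L), collapse = "; "))
  }
  invisible(TRUE)
}

#' Read a cross from its tabular file set
#'
#' Reads the five plain-text files written by [write_cross()]: a pedigree
#' TSV (`id sire dam sex [generation] [line]`), a genotype TSV (an `id`
#' column then `<marker>_1`/`<marker>_2` integer columns, 0 = missing), a
#' map TSV (`chromosome marker position_cM kind`), a phenotype TSV (`id`
#' then trait/covariate columns) and a `key=value` attributes file.
#'
#' @param pedigree_path,genotype_path,map_path,phenotype_path file paths;
#'   `phenotype_path` may be `NULL`.
#' @param attributes_path path to the attributes file, or `NULL` to use
#'   the defaults in `...`.
#' @param ... cross attributes passed to [cross_data()] when no attributes
#'   file is given.
#' @return a validated [cross_data] object.
#' @export
read_cross <- function(pedigree_path, genotype_path, map_path,
                       phenotype_path = NULL, attributes_path = NULL, ...) {
  ped <- read_tsv_checked(pedigree_path)
  map <- read_tsv_checked(map_path)
  gt <- read_tsv_checked(genotype_path)
  if (!"id" %in% names(gt)) stop_lcq(genotype_path, ": genotype file needs an 'id' column")
  ids <- as.character(gt$id)
  g <- as.matrix(gt[setdiff(names(gt), "id")])
  rownames(g) <- ids
  ph <- NULL
  if (!is.null(phenotype_path)) {
    ph <- read_tsv_checked(phenotype_path)
  }
  args <- list(...)
  if (!is.null(attributes_path)) {
    args <- utils::modifyList(args, read_attributes(attributes_path))
  }
  cross <- do.call(cross_data,
                   c(list(pedigree = ped, genotypes = g, map = map, phenotypes = ph),
                     args))
  assert_valid_cross(cross)
  cross
}

read_tsv_checked <- function(path) {
  if (!file.exists(path)) stop_lcq(path, ": file not found")
  out <- tryCatch(
    utils::read.delim(path, header = TRUE, sep = "\t",
                      stringsAsFactors = FALSE, check.names = FALSE),
    error = function(e) stop_lcq(path, ": parse error: ", conditionMessage(e)))
  out
}

read_attributes <- function(path) {
  if (!file.exists(path)) stop_lcq(path, ": file not found")
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  kv <- strsplit(lines, "=", fixed = TRUE)
  bad <- which(lengths(kv) != 2L)
  if (length(bad)) stop_lcq(path, ": malformed line ", bad[1L], ": '", lines[bad[1L]], "'")
  out <- stats::setNames(lapply(kv, function(x) trimws(x[2L])), trimws(vapply(kv, `[[`, "", 1L)))
  keep <- intersect(names(out), c("cross_type", "heterogametic_sex", "sex_chromosome"))
  out <- out[keep]
  if (!is.null(out$sex_chromosome) && out$sex_chromosome %in% c("", "NA", "none")) {
    out$sex_chromosome <- NULL
  }
  out
}

#' Write a cross to a directory of tabular files
#'
#' Emits `pedigree.tsv`, `genotypes.tsv`, `map.tsv`, `phenotypes.tsv` and
#' `attributes.txt`; [read_cross()] on the directory reproduces the
#' object. Refuses to overwrite existing files unless `force = TRUE`.
#'
#' @param cross a [cross_data] object.
#' @param directory output directory (created if absent).
#' @param force overwrite existing files?
#' @return invisibly, the vector of written paths.
#' @export
write_cross <- function(cross, directory, force = FALSE) {
  if (!dir.exists(directory)) dir.create(directory, recursive = TRUE)
  files <- file.path(directory, c("pedigree.tsv", "genotypes.tsv", "map.tsv",
                                  "phenotypes.tsv", "attributes.txt"))
  existing <- files[file.exists(files)]
  if (length(existing) && !force) {
    stop_lcq("refusing to overwrite ", existing[1L], " (use force = TRUE)")
  }
  wt <- function(df, path) {
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  ped <- cross$pedigree
  ped$sire[is.na(ped$sire)] <- "0"
  ped$dam[is.na(ped$dam)] <- "0"
  wt(ped, files[1L])
  gdf <- data.frame(id = rownames(cross$genotypes), cross$genotypes,
                    check.names = FALSE, stringsAsFactors = FALSE)
  wt(gdf, files[2L])
  wt(cross$map, files[3L])
  wt(cross$phenotypes, files[4L])
  at <- c(paste0("cross_type=", cross$cross_type),
          paste0("heterogametic_sex=", cross$heterogametic_sex),
          if (!is.null(cross$sex_chromosome))
            paste0("sex_chromosome=", cross$sex_chromosome))
  writeLines(at, files[5L])
  invisible(files)
}

#' Read a cross directory written by write_cross
#' @param directory directory containing the five tabular files.
#' @return a validated [cross_data] object.
#' @export
read_cross_dir <- function(directory) {
  ph <- file.path(directory, "phenotypes.tsv")
  read_cross(file.path(directory, "pedigree.tsv"),
             file.path(directory, "genotypes.tsv"),
             file.path(directory, "map.tsv"),
             phenotype_path = if (file.exists(ph)) ph else NULL,
             attributes_path = file.path(directory, "attributes.txt"))
}
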