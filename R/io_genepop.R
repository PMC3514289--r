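#' Construct a diploid multi-allelic genotype matrix
#'
#' The container used throughout the population-genetic side of the
#' pipeline: individuals x loci, alleles as positive integer labels,
#' one population assignment per individual. Missing calls are a pair of
#' `NA`s; half-missing calls are rejected (diploidy invariant).
#'
#' @param ids Character vector of individual identifiers.
#' @param pop Character vector (or factor) of population labels, one per
#'   individual.
#' @param loci Character vector of locus names.
#' @param a1,a2 Integer matrices (individuals x loci) with the two allele
#'   labels of each call; allele order within a call is irrelevant.
#' @return An object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(ids, pop, loci, a1, a2) {
  ids <- as.character(ids)
  pop <- as.character(pop)
  loci <- as.character(loci)
  a1 <- as.matrix(a1); a2 <- as.matrix(a2)
  storage.mode(a1) <- "integer"; storage.mode(a2) <- "integer"
  n <- length(ids)
  if (length(pop) != n) stop("pop must have one label per individual")
  if (anyNA(pop)) stop("every individual must map to exactly one population")
  if (!all(dim(a1) == c(n, length(loci))) || !all(dim(a2) == dim(a1)))
    stop("allele matrices must be individuals x loci")
  if (anyDuplicated(ids)) stop("duplicated individual ids")
  if (length(loci) < 1) stop("at least one locus required")
  if (any(xor(is.na(a1), is.na(a2))))
    stop("half-missing genotype call: calls must carry 0 or 2 alleles")
  if (any(a1 < 1, na.rm = TRUE) || any(a2 < 1, na.rm = TRUE))
    stop("allele labels must be positive integers")
  dimnames(a1) <- dimnames(a2) <- list(ids, loci)
  structure(list(ids = ids, pop = pop, loci = loci, a1 = a1, a2 = a2),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat("genotype_matrix:", length(x$ids), "individuals,", length(x$loci),
      "loci,", length(unique(x$pop)), "populations\n")
  cat("  loci:", paste(x$loci, collapse = ", "), "\n")
  tab <- table(factor(x$pop, levels = unique(x$pop)))
  cat("  populations:",
      paste(sprintf("%s (n=%d)", names(tab), as.integer(tab)),
            collapse = ", "), "\n")
  invisible(x)
}

#' Number of populations / individuals helpers
#' @param g A `genotype_matrix`.
#' @return Character vector of population labels in order of first
#'   appearance.
#' @export
populations <- function(g) unique(g$pop)

#' Read a GENEPOP genotype file
#'
#' Standard GENEPOP layout: a title line, one locus name per line (or a
#' single comma-separated line), `POP` separators, and one individual per
#' line as `id , a1a2 a1a2 ...` with fixed-width allele codes. The code
#' `000` (or `00`) denotes a missing call.
#'
#' @param path Path to a GENEPOP file.
#' @param digits Allele-code width: 3 (default) or 2; `NULL` infers the
#'   width from the first genotype field.
#' @param pop_names `"auto"` labels blocks `POP_1..POP_k`; `"last_id"`
#'   uses the id of the last individual in each block (the common GENEPOP
#'   convention of naming blocks by their final sample).
#' @return A [genotype_matrix()].
#' @export
read_genepop <- function(path, digits = 3, pop_names = c("auto", "last_id")) {
  pop_names <- match.arg(pop_names)
  if (!file.exists(path)) stop("GENEPOP file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) < 3) stop("GENEPOP file too short")
  is_pop <- toupper(trimws(lines)) == "POP"
  first_pop <- which(is_pop)[1]
  if (is.na(first_pop)) stop("GENEPOP file has no POP separator")
  if (first_pop < 3) stop("GENEPOP file declares zero loci")
  locus_lines <- trimws(lines[2:(first_pop - 1)])
  loci <- unlist(strsplit(locus_lines, "\\s*,\\s*"))
  loci <- loci[nzchar(loci)]
  if (length(loci) == 0) stop("GENEPOP file declares zero loci")

  ids <- character(); pops <- character()
  a1 <- NULL; a2 <- NULL
  block <- 0L
  block_rows <- integer(0)
  for (i in seq(first_pop, length(lines))) {
    line <- trimws(lines[i])
    if (toupper(line) == "POP") {
      block <- block + 1L
      next
    }
    parts <- strsplit(line, ",")[[1]]
    if (length(parts) != 2)
      stop("GENEPOP parse error (expected 'id , genotypes'): ", line)
    id <- trimws(parts[1])
    fields <- strsplit(trimws(parts[2]), "\\s+")[[1]]
    if (length(fields) != length(loci))
      stop("individual '", id, "' has ", length(fields),
           " genotype fields for ", length(loci), " loci")
    if (is.null(digits)) {
      w <- nchar(fields[1])
      if (!w %in% c(4, 6)) stop("cannot infer allele-code width from '",
                                fields[1], "'")
      digits <- w / 2
    }
    if (any(nchar(fields) != 2 * digits))
      stop("individual '", id, "': genotype field of odd/unexpected width (",
           paste(unique(fields[nchar(fields) != 2 * digits]), collapse = ", "),
           "); expected ", 2 * digits, " characters")
    al1 <- as.integer(substr(fields, 1, digits))
    al2 <- as.integer(substr(fields, digits + 1, 2 * digits))
    if (anyNA(al1) || anyNA(al2))
      stop("individual '", id, "': non-numeric allele code")
    miss <- al1 == 0 | al2 == 0
    al1[miss] <- NA_integer_; al2[miss] <- NA_integer_
    ids <- c(ids, id)
    pops <- c(pops, sprintf("POP_%d", block))
    block_rows <- c(block_rows, block)
    a1 <- rbind(a1, al1); a2 <- rbind(a2, al2)
  }
  if (length(ids) == 0) stop("GENEPOP file contains no individuals")
  if (pop_names == "last_id") {
    for (b in unique(block_rows)) {
      rows <- which(block_rows == b)
      pops[rows] <- ids[rows[length(rows)]]
    }
  }
  genotype_matrix(ids, pops, loci, a1, a2)
}

#' Write a genotype matrix as a GENEPOP file
#'
#' Deterministic: populations in stored order of first appearance,
#' individuals in stored order. The output re-reads losslessly with
#' [read_genepop()].
#'
#' @param g A [genotype_matrix()].
#' @param path Output file path.
#' @param digits Allele-code width (3 by default; all labels must fit).
#' @param title Title line for the file.
#' @return `path`, invisibly.
#' @export
write_genepop <- function(g, path, digits = 3,
                          title = "lakestream genotype export") {
  if (length(g$ids) == 0) stop("cannot write an empty genotype matrix")
  max_allele <- max(c(g$a1, g$a2), na.rm = TRUE)
  if (max_allele > 10^digits - 1)
    stop("allele label ", max_allele, " not representable in ", digits,
         " digits")
  fmt <- function(x) {
    x[is.na(x)] <- 0L
    formatC(x, width = digits, flag = "0")
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(title, con)
  writeLines(g$loci, con)
  for (p in unique(g$pop)) {
    writeLines("POP", con)
    rows <- which(g$pop == p)
    for (r in rows) {
      geno <- paste0(fmt(g$a1[r, ]), fmt(g$a2[r, ]))
      writeLines(paste0(g$ids[r], " ,  ", paste(geno, collapse = " ")), con)
    }
  }
  invisible(path)
}
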