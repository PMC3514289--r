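#' Construct an aligned sequence set with population assignments
#'
#' @param seqs Named character vector of equal-length sequences over
#'   `A,C,G,T,N,-` (case-insensitive; stored upper case).
#' @param pop Optional named character vector mapping sequence ids to
#'   population labels; ids absent from the map get `"unassigned"`.
#' @return An object of class `dloop_alignment` with elements `seqs`,
#'   `length` and `pop`.
#' @export
alignment <- function(seqs, pop = NULL) {
  if (length(seqs) == 0) stop("empty alignment")
  if (is.null(names(seqs)) || any(!nzchar(names(seqs))))
    stop("all sequences must be named")
  seqs <- toupper(seqs)
  lens <- nchar(seqs)
  if (length(unique(lens)) != 1)
    stop("sequences differ in length: ",
         paste(names(seqs)[lens != lens[1]], collapse = ", "))
  bad <- grepl("[^ACGTN-]", seqs)
  if (any(bad))
    stop("non-ACGTN- characters in: ", paste(names(seqs)[bad], collapse = ", "))
  p <- rep("unassigned", length(seqs))
  names(p) <- names(seqs)
  if (!is.null(pop)) {
    hit <- intersect(names(seqs), names(pop))
    p[hit] <- pop[hit]
  }
  structure(list(seqs = seqs, length = unname(lens[1]), pop = p),
            class = "dloop_alignment")
}

#' @export
print.dloop_alignment <- function(x, ...) {
  cat("alignment:", length(x$seqs), "sequences x", x$length, "bp;",
      length(unique(x$pop)), "population(s)\n")
  invisible(x)
}

#' Read an aligned FASTA file
#'
#' Reads a FASTA file (via ape) and checks that all records have equal
#' length, attaching population labels from `pop_map`.
#'
#' @param path Path to a FASTA file of aligned sequences.
#' @param pop_map Optional named character vector `id -> population`.
#' @return A [alignment()] object.
#' @export
read_fasta_alignment <- function(path, pop_map = NULL) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  dna <- ape::read.FASTA(path)
  if (length(dna) == 0) stop("FASTA file contains no sequences")
  chars <- lapply(as.character(dna), function(x) paste(x, collapse = ""))
  seqs <- toupper(unlist(chars))
  lens <- nchar(seqs)
  if (length(unique(lens)) != 1)
    stop("unaligned FASTA: sequences of deviant length: ",
         paste(names(seqs)[lens != as.integer(names(sort(-table(lens)))[1])],
               collapse = ", "))
  alignment(seqs, pop_map)
}

#' Write an alignment to FASTA
#'
#' @param a A [alignment()] object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_fasta_alignment <- function(a, path) {
  x <- strsplit(tolower(a$seqs), "")
  names(x) <- names(a$seqs)
  ape::write.FASTA(ape::as.DNAbin(x), path)
  invisible(path)
}
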