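#' Collapse an alignment into haplotypes
#'
#' Identical sequences merge into haplotypes; counts are tabulated per
#' population; segregating sites (SNPs) are alignment columns with at
#' least two distinct observed bases among A, C, G, T. Under the default
#' `"mask"` policy, columns containing any N or gap are excluded from
#' haplotype identity (and from distances downstream); `"strict"` treats
#' every character literally.
#'
#' Haplotypes are ordered by decreasing total count, ties broken
#' lexicographically, so the table is invariant to input order.
#'
#' @param a A [alignment()] object.
#' @param policy `"mask"` (N/gap treated as missing) or `"strict"`.
#' @return An object of class `haplotype_table`: list with `haplotypes`
#'   (representative full-length sequences), `counts` (haplotype x
#'   population integer matrix), `snp_positions` (1-based columns),
#'   `policy` and `n_seq`.
#' @export
collapse_haplotypes <- function(a, policy = c("mask", "strict")) {
  policy <- match.arg(policy)
  if (!inherits(a, "dloop_alignment")) stop("need a dloop_alignment")
  mat <- do.call(rbind, strsplit(a$seqs, ""))
  rownames(mat) <- names(a$seqs)

  base_ok <- matrix(mat %in% c("A", "C", "G", "T"), nrow(mat))
  snp_positions <- which(vapply(seq_len(ncol(mat)), function(j) {
    length(unique(mat[base_ok[, j], j])) >= 2
  }, logical(1)))

  keep_cols <- if (policy == "mask") {
    which(apply(base_ok, 2, all))
  } else {
    seq_len(ncol(mat))
  }
  if (length(keep_cols) == 0)
    stop("no usable columns under the mask policy")
  key <- apply(mat[, keep_cols, drop = FALSE], 1, paste, collapse = "")

  groups <- split(seq_along(key), key)
  reps <- vapply(groups, function(idx) a$seqs[idx[1]], character(1))
  totals <- vapply(groups, length, integer(1))
  ord <- order(-totals, reps)
  groups <- groups[ord]; reps <- reps[ord]

  pops <- unique(a$pop)
  counts <- matrix(0L, length(groups), length(pops),
                   dimnames = list(NULL, pops))
  for (h in seq_along(groups))
    counts[h, ] <- as.integer(table(factor(a$pop[groups[[h]]], levels = pops)))

  structure(list(haplotypes = unname(reps), counts = counts,
                 snp_positions = as.integer(snp_positions),
                 policy = policy, n_seq = length(a$seqs)),
            class = "haplotype_table")
}

#' @export
print.haplotype_table <- function(x, ...) {
  cat("haplotype_table:", length(x$haplotypes), "haplotypes from",
      x$n_seq, "sequences;", length(x$snp_positions),
      "segregating site(s) at",
      paste(x$snp_positions, collapse = ", "), "\n")
  invisible(x)
}

#' Hamming distance between two aligned sequences
#'
#' Number of differing columns; positions where either sequence carries
#' a non-ACGT character (N or gap) are excluded under the `"mask"`
#' policy.
#'
#' @param h1,h2 Equal-length sequence strings.
#' @param policy `"mask"` or `"strict"`.
#' @return Non-negative integer distance.
#' @export
hamming <- function(h1, h2, policy = c("mask", "strict")) {
  policy <- match.arg(policy)
  if (nchar(h1) != nchar(h2)) stop("sequences differ in length")
  x <- strsplit(toupper(h1), "")[[1]]
  y <- strsplit(toupper(h2), "")[[1]]
  if (policy == "mask") {
    ok <- x %in% c("A", "C", "G", "T") & y %in% c("A", "C", "G", "T")
    x <- x[ok]; y <- y[ok]
  }
  sum(x != y)
}

#' Minimum-spanning haplotype network
#'
#' Kruskal minimum-spanning tree over pairwise Hamming distances between
#' haplotypes — the distance-based stand-in for a likelihood genealogy,
#' adequate and exactly testable for a handful of segregating sites.
#' Ties between equal-weight edges are broken deterministically by
#' lexicographic order of the haplotype sequences.
#'
#' @param tab A [collapse_haplotypes()] result.
#' @return An object of class `haplo_network`: `nodes` (data frame with
#'   haplotype sequence and total count) and `edges` (data frame
#'   `from`, `to` — 1-based node indices — and `distance`). A single
#'   haplotype yields zero edges.
#' @export
mst_network <- function(tab) {
  if (!inherits(tab, "haplotype_table")) stop("need a haplotype_table")
  n <- length(tab$haplotypes)
  nodes <- data.frame(haplotype = tab$haplotypes,
                      count = as.integer(rowSums(tab$counts)),
                      stringsAsFactors = FALSE)
  if (n == 1) {
    return(structure(list(nodes = nodes,
                          edges = data.frame(from = integer(0),
                                             to = integer(0),
                                             distance = integer(0))),
                     class = "haplo_network"))
  }
  pairs <- utils::combn(n, 2)
  w <- apply(pairs, 2, function(ij)
    hamming(tab$haplotypes[ij[1]], tab$haplotypes[ij[2]],
            policy = tab$policy))
  seq_lo <- pmin(tab$haplotypes[pairs[1, ]], tab$haplotypes[pairs[2, ]])
  seq_hi <- pmax(tab$haplotypes[pairs[1, ]], tab$haplotypes[pairs[2, ]])
  ord <- order(w, seq_lo, seq_hi)

  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) i <- parent[i]
    i
  }
  from <- integer(0); to <- integer(0); dist <- integer(0)
  for (e in ord) {
    i <- pairs[1, e]; j <- pairs[2, e]
    ri <- find(i); rj <- find(j)
    if (ri != rj) {
      parent[ri] <- rj
      from <- c(from, i); to <- c(to, j); dist <- c(dist, w[e])
      if (length(from) == n - 1) break
    }
  }
  structure(list(nodes = nodes,
                 edges = data.frame(from = from, to = to,
                                    distance = as.integer(dist))),
            class = "haplo_network")
}

#' @export
print.haplo_network <- function(x, ...) {
  cat("haplo_network:", nrow(x$nodes), "haplotypes,", nrow(x$edges),
      "edges, total weight", sum(x$edges$distance), "\n")
  invisible(x)
}

#' Write haplotype counts and network edges as TSVs
#'
#' @param tab A [collapse_haplotypes()] result.
#' @param net A [mst_network()] result.
#' @param counts_path,edges_path Output file paths.
#' @return Invisibly, the two paths.
#' @export
write_haplotype_tables <- function(tab, net, counts_path, edges_path) {
  cnt <- data.frame(haplotype = tab$haplotypes, tab$counts,
                    total = rowSums(tab$counts), check.names = FALSE)
  utils::write.table(cnt, counts_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  ed <- data.frame(hap_i = net$edges$from, hap_j = net$edges$to,
                   distance = net$edges$distance)
  utils::write.table(ed, edges_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(counts_path, edges_path))
}
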