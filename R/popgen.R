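#' Per-population allele frequencies at a locus
#'
#' Inputs to the Weir-Cockerham estimator: allele frequencies, the number
#' of typed individuals, and the observed heterozygote proportion carrying
#' each allele.
#'
#' @param g A [genotype_matrix()].
#' @param pop Population label.
#' @param locus Locus name.
#' @return List with `freq` (named allele frequencies summing to 1),
#'   `n` (typed individuals) and `het` (per-allele observed heterozygote
#'   proportion), or `NULL` when no individual is typed.
#' @export
allele_frequencies <- function(g, pop, locus) {
  j <- match(locus, g$loci)
  if (is.na(j)) stop("unknown locus: ", locus)
  if (!pop %in% g$pop) stop("unknown population: ", pop)
  rows <- g$pop == pop & !is.na(g$a1[, j])
  n <- sum(rows)
  if (n == 0) return(NULL)
  x1 <- g$a1[rows, j]; x2 <- g$a2[rows, j]
  alleles <- sort(unique(c(x1, x2)))
  k <- length(alleles)
  cnt <- tabulate(match(x1, alleles), k) + tabulate(match(x2, alleles), k)
  het <- x1 != x2
  hcnt <- tabulate(match(x1[het], alleles), k) +
    tabulate(match(x2[het], alleles), k)
  list(freq = stats::setNames(cnt / (2 * n), alleles), n = n,
       het = stats::setNames(hcnt / n, alleles))
}

## Weir & Cockerham (1984) variance components for two populations at one
## locus, vectorised over alleles. Inputs are per-population sample sizes
## (typed individuals), allele frequencies and per-allele observed
## heterozygote proportions. Returns the per-allele a, b, c components.
wc_components_pair <- function(nA, fA, hA, nB, fB, hB) {
  r <- 2
  n_bar <- (nA + nB) / r
  n_c <- (r * n_bar - (nA^2 + nB^2) / (r * n_bar)) / (r - 1)
  p_bar <- (nA * fA + nB * fB) / (r * n_bar)
  s2 <- (nA * (fA - p_bar)^2 + nB * (fB - p_bar)^2) / ((r - 1) * n_bar)
  h_bar <- (nA * hA + nB * hB) / (r * n_bar)
  a <- (n_bar / n_c) *
    (s2 - (p_bar * (1 - p_bar) - (r - 1) / r * s2 - h_bar / 4) / (n_bar - 1))
  b <- (n_bar / (n_bar - 1)) *
    (p_bar * (1 - p_bar) - (r - 1) / r * s2 -
       (2 * n_bar - 1) / (4 * n_bar) * h_bar)
  cc <- h_bar / 2
  list(a = a, b = b, c = cc)
}

## Core pairwise theta on raw allele arrays; popvec selects/partitions the
## rows. Used directly by the permutation loop to avoid rebuilding
## genotype_matrix objects. Returns numerator/denominator sums and
## per-locus components.
theta_from_arrays <- function(a1, a2, popvec, popA, popB,
                              keep_components = FALSE) {
  num <- 0; den <- 0
  comps <- if (keep_components) list() else NULL
  for (j in seq_len(ncol(a1))) {
    x1 <- a1[, j]; x2 <- a2[, j]
    typed <- !is.na(x1)
    iA <- typed & popvec == popA
    iB <- typed & popvec == popB
    nA <- sum(iA); nB <- sum(iB)
    if (nA == 0 || nB == 0) next          # locus unscored in one population
    n_bar <- (nA + nB) / 2
    if (n_bar <= 1) next                   # no within-population df
    alleles <- sort(unique(c(x1[iA | iB], x2[iA | iB])))
    k <- length(alleles)
    if (k < 2) next                        # monomorphic across both: skip
    fA <- (tabulate(match(x1[iA], alleles), k) +
             tabulate(match(x2[iA], alleles), k)) / (2 * nA)
    fB <- (tabulate(match(x1[iB], alleles), k) +
             tabulate(match(x2[iB], alleles), k)) / (2 * nB)
    hetA <- iA & x1 != x2
    hetB <- iB & x1 != x2
    hA <- (tabulate(match(x1[hetA], alleles), k) +
             tabulate(match(x2[hetA], alleles), k)) / nA
    hB <- (tabulate(match(x1[hetB], alleles), k) +
             tabulate(match(x2[hetB], alleles), k)) / nB
    w <- wc_components_pair(nA, fA, hA, nB, fB, hB)
    num <- num + sum(w$a)
    den <- den + sum(w$a + w$b + w$c)
    if (keep_components)
      comps[[length(comps) + 1L]] <-
        data.frame(locus = colnames(a1)[j], allele = alleles,
                   a = w$a, b = w$b, c = w$c, row.names = NULL)
  }
  theta <- if (den > 0) num / den else NA_real_
  list(theta = theta, num = num, den = den,
       components = if (keep_components) do.call(rbind, comps) else NULL)
}

#' Pairwise Weir-Cockerham theta (F_ST) between two populations
#'
#' Multi-allelic Weir & Cockerham (1984) estimator for two populations:
#' per locus and allele the variance components a (among populations),
#' b (among individuals within populations) and c (within individuals)
#' are computed from the per-population sample sizes, allele frequencies
#' and observed heterozygote proportions; theta is the ratio of sums
#' `sum(a) / sum(a + b + c)` across all loci and alleles. Loci
#' monomorphic across both populations contribute nothing; per-locus
#' sample sizes adjust to missing calls. Small negative estimates are
#' reported as computed (unbiased-estimator behaviour), never truncated.
#'
#' @param g A [genotype_matrix()].
#' @param popA,popB Population labels.
#' @param keep_components Keep the per-locus, per-allele a/b/c table.
#' @return An object of class `fst_result`: list with `pop_pair`,
#'   `theta`, `num`, `den` and optionally `components`. `theta` is `NA`
#'   (with a message) when all loci are monomorphic.
#' @export
wc_theta_pair <- function(g, popA, popB, keep_components = FALSE) {
  for (p in c(popA, popB))
    if (!p %in% g$pop) stop("unknown population: ", p)
  if (popA == popB) stop("popA and popB must differ")
  rows <- g$pop %in% c(popA, popB)
  r <- theta_from_arrays(g$a1[rows, , drop = FALSE],
                         g$a2[rows, , drop = FALSE],
                         g$pop[rows], popA, popB,
                         keep_components = keep_components)
  if (is.na(r$theta))
    message("theta undefined for (", popA, ", ", popB,
            "): all loci monomorphic")
  structure(list(pop_pair = c(popA, popB), theta = r$theta, num = r$num,
                 den = r$den, components = r$components,
                 theta_max = NULL, theta_std = NULL, p_value = NULL,
                 B = NULL),
            class = "fst_result")
}

#' @export
print.fst_result <- function(x, ...) {
  cat(sprintf("F_ST (%s vs %s): theta = %s\n", x$pop_pair[1], x$pop_pair[2],
              format(x$theta, digits = 4)))
  if (!is.null(x$theta_std))
    cat(sprintf("  theta_max = %s, standardized F'_ST = %s\n",
                format(x$theta_max, digits = 4),
                format(x$theta_std, digits = 4)))
  if (!is.null(x$p_value))
    cat(sprintf("  P = %s (%d permutations)\n",
                format(x$p_value, digits = 4), x$B))
  invisible(x)
}

#' Permutation P-value for pairwise theta
#'
#' Whole multilocus individuals are re-assigned between the two
#' populations uniformly at random, preserving sample sizes (linkage
#' within individuals is kept intact). One-sided on theta:
#' `p = (1 + #\{theta* >= theta\}) / (B + 1)`, floor `1/(B+1)` (0.001 at
#' the default B = 999).
#'
#' @param g A [genotype_matrix()].
#' @param popA,popB Population labels.
#' @param B Number of permutations (default 999).
#' @param seed Integer seed for reproducibility.
#' @return The permutation P-value (`NA` if theta is undefined).
#' @export
fst_perm_p <- function(g, popA, popB, B = 999, seed = NULL) {
  if (B < 1) stop("B must be >= 1")
  rows <- which(g$pop %in% c(popA, popB))
  if (length(rows) == 0) stop("populations not found")
  a1 <- g$a1[rows, , drop = FALSE]
  a2 <- g$a2[rows, , drop = FALSE]
  popvec <- g$pop[rows]
  obs <- theta_from_arrays(a1, a2, popvec, popA, popB)$theta
  if (is.na(obs)) return(NA_real_)
  if (!is.null(seed)) set.seed(seed)
  tol <- 1e-12 * max(1, abs(obs))
  n_extreme <- 0L
  for (b in seq_len(B)) {
    t_star <- theta_from_arrays(a1, a2, sample(popvec), popA, popB)$theta
    if (!is.na(t_star) && t_star >= obs - tol) n_extreme <- n_extreme + 1L
  }
  (n_extreme + 1) / (B + 1)
}

#' Maximum-differentiation allele recoding
#'
#' Recoding underlying Hedrick's standardized F'_ST: within each
#' population every allele label is mapped (consistently within the
#' population, disjointly across populations) to a population-private
#' label. Each population's allele-frequency spectrum and heterozygosity
#' are untouched, but the two populations share no alleles afterwards —
#' the maximum differentiation compatible with the observed
#' within-population variability. Missing calls stay missing.
#'
#' @param g A [genotype_matrix()].
#' @param popA,popB Population labels.
#' @return A [genotype_matrix()] restricted to the two populations with
#'   recoded alleles.
#' @export
recode_max <- function(g, popA, popB) {
  for (p in c(popA, popB))
    if (!p %in% g$pop) stop("unknown population: ", p)
  rows <- which(g$pop %in% c(popA, popB))
  a1 <- g$a1[rows, , drop = FALSE]
  a2 <- g$a2[rows, , drop = FALSE]
  popvec <- g$pop[rows]
  for (j in seq_len(ncol(a1))) {
    inA <- popvec == popA
    allelesA <- sort(unique(c(a1[inA, j], a2[inA, j])))
    allelesA <- allelesA[!is.na(allelesA)]
    allelesB <- sort(unique(c(a1[!inA, j], a2[!inA, j])))
    allelesB <- allelesB[!is.na(allelesB)]
    mapA <- stats::setNames(seq_along(allelesA), allelesA)
    mapB <- stats::setNames(length(allelesA) + seq_along(allelesB), allelesB)
    recode <- function(x, in_pop, map) {
      idx <- in_pop & !is.na(x)
      x[idx] <- map[as.character(x[idx])]
      x
    }
    a1[, j] <- recode(recode(a1[, j], inA, mapA), !inA, mapB)
    a2[, j] <- recode(recode(a2[, j], inA, mapA), !inA, mapB)
  }
  genotype_matrix(g$ids[rows], popvec, g$loci, a1, a2)
}

#' Hedrick-standardized F'_ST for a population pair
#'
#' `theta_max` is Weir-Cockerham theta recomputed after
#' maximum-differentiation recoding ([recode_max()]); the standardized
#' value is `theta / theta_max`, i.e. the observed differentiation as a
#' fraction of the maximum achievable given within-population
#' heterozygosity.
#'
#' @param g A [genotype_matrix()].
#' @param popA,popB Population labels.
#' @param B Optional permutation count for a P-value on raw theta.
#' @param seed Seed for the permutation P-value.
#' @return An `fst_result` with `theta`, `theta_max`, `theta_std` and
#'   (if requested) `p_value`. `theta_std` is `NA` with a warning when
#'   `theta_max <= 0`.
#' @export
standardized_fst <- function(g, popA, popB, B = NULL, seed = NULL) {
  res <- wc_theta_pair(g, popA, popB)
  gmax <- recode_max(g, popA, popB)
  res$theta_max <- wc_theta_pair(gmax, popA, popB)$theta
  if (is.na(res$theta) || is.na(res$theta_max) || res$theta_max <= 0) {
    warning("standardization undefined: theta_max <= 0 or theta undefined")
    res$theta_std <- NA_real_
  } else {
    res$theta_std <- res$theta / res$theta_max
  }
  if (!is.null(B)) {
    res$p_value <- fst_perm_p(g, popA, popB, B = B, seed = seed)
    res$B <- as.integer(B)
  }
  res
}

#' All pairwise theta (and optionally P-values and F'_ST)
#'
#' Every population pair is computed independently on the two populations
#' only (pairwise estimates, not slices of a global estimate).
#'
#' @param g A [genotype_matrix()].
#' @param B Permutation count for P-values; `NULL` skips them.
#' @param seed Base seed; each pair derives its own sub-seed.
#' @param standardized Also compute maximum-differentiation standardized
#'   F'_ST per pair.
#' @return An object of class `fst_matrix`: list of symmetric matrices
#'   `theta`, `p` and `theta_std` (entries `NA` where undefined or not
#'   requested; diagonal empty) plus the population order.
#' @export
fst_matrix <- function(g, B = NULL, seed = NULL, standardized = FALSE) {
  pops <- populations(g)
  k <- length(pops)
  if (k < 2) stop("need >= 2 populations")
  th <- matrix(NA_real_, k, k, dimnames = list(pops, pops))
  pv <- th; std <- th
  for (i in seq_len(k - 1)) {
    for (j in seq(i + 1, k)) {
      res <- suppressWarnings(suppressMessages(
        if (standardized) standardized_fst(g, pops[i], pops[j])
        else wc_theta_pair(g, pops[i], pops[j])
      ))
      th[i, j] <- th[j, i] <- res$theta
      if (standardized && !is.null(res$theta_std))
        std[i, j] <- std[j, i] <- res$theta_std
      if (!is.null(B)) {
        s <- if (is.null(seed)) NULL else derive_seed(seed, "fst", pops[i], pops[j])
        pv[i, j] <- pv[j, i] <- fst_perm_p(g, pops[i], pops[j], B = B, seed = s)
      }
    }
  }
  structure(list(pops = pops, theta = th, p = pv,
                 theta_std = if (standardized) std else NULL,
                 B = if (is.null(B)) NA_integer_ else as.integer(B)),
            class = "fst_matrix")
}

#' Format an F_ST matrix in the two-semimatrix report style
#'
#' Upper semimatrix: raw theta to 2 decimals with the permutation P-value
#' in parentheses; lower semimatrix: standardized F'_ST to 2 decimals.
#' Full precision lives in the `fst_matrix` object itself.
#'
#' @param fm An [fst_matrix()] result.
#' @return A character matrix suitable for writing as CSV/TSV.
#' @export
format_fst_table <- function(fm) {
  k <- length(fm$pops)
  out <- matrix("", k, k, dimnames = list(fm$pops, fm$pops))
  for (i in seq_len(k - 1)) {
    for (j in seq(i + 1, k)) {
      cell <- sprintf("%.2f", fm$theta[i, j])
      if (!is.na(fm$p[i, j]))
        cell <- sprintf("%s (%.3f)", cell, fm$p[i, j])
      out[i, j] <- cell
      if (!is.null(fm$theta_std) && !is.na(fm$theta_std[i, j]))
        out[j, i] <- sprintf("%.2f", fm$theta_std[i, j])
    }
  }
  out
}
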