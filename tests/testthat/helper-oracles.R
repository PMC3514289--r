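# Independent oracles, deliberately written as direct scalar
# transcriptions of the defining formulas, separate from the package's
# vectorised implementations.

# Weir & Cockerham (1984) theta for one locus and r = 2 populations.
# genoA/genoB: two-column matrices of allele labels (rows = individuals,
# NA rows = missing calls). Loops over alleles with scalar arithmetic.
oracle_wc_theta_1locus <- function(genoA, genoB) {
  genoA <- genoA[!is.na(genoA[, 1]), , drop = FALSE]
  genoB <- genoB[!is.na(genoB[, 1]), , drop = FALSE]
  nA <- nrow(genoA); nB <- nrow(genoB)
  alleles <- sort(unique(c(genoA, genoB)))
  if (length(alleles) < 2) return(NA_real_)
  r <- 2
  n_bar <- (nA + nB) / r
  n_c <- (r * n_bar - (nA^2 / (r * n_bar) + nB^2 / (r * n_bar))) / (r - 1)
  num <- 0; den <- 0
  for (A in alleles) {
    pA <- sum(genoA == A) / (2 * nA)
    pB <- sum(genoB == A) / (2 * nB)
    hA <- sum(genoA[, 1] != genoA[, 2] &
                (genoA[, 1] == A | genoA[, 2] == A)) / nA
    hB <- sum(genoB[, 1] != genoB[, 2] &
                (genoB[, 1] == A | genoB[, 2] == A)) / nB
    p_bar <- (nA * pA + nB * pB) / (r * n_bar)
    s2 <- (nA * (pA - p_bar)^2 + nB * (pB - p_bar)^2) / ((r - 1) * n_bar)
    h_bar <- (nA * hA + nB * hB) / (r * n_bar)
    a <- (n_bar / n_c) *
      (s2 - (1 / (n_bar - 1)) *
         (p_bar * (1 - p_bar) - ((r - 1) / r) * s2 - h_bar / 4))
    b <- (n_bar / (n_bar - 1)) *
      (p_bar * (1 - p_bar) - ((r - 1) / r) * s2 -
         ((2 * n_bar - 1) / (4 * n_bar)) * h_bar)
    cc <- h_bar / 2
    num <- num + a
    den <- den + a + b + cc
  }
  num / den
}

# Exact permutation P-value by full enumeration over all two-group label
# assignments (identity included), two-sided on |T| or one-sided.
oracle_exhaustive_perm_p <- function(values, labels, statistic,
                                     two_sided = TRUE) {
  labels <- as.character(labels)
  lev <- unique(labels)
  stopifnot(length(lev) == 2)
  n <- length(labels)
  nA <- sum(labels == lev[1])
  obs <- statistic(values, labels)
  combos <- combn(n, nA)
  extreme <- 0L
  for (k in seq_len(ncol(combos))) {
    lab <- rep(lev[2], n)
    lab[combos[, k]] <- lev[1]
    t <- statistic(values, lab)
    hit <- if (two_sided) abs(t) >= abs(obs) - 1e-12 else t >= obs - 1e-12
    if (hit) extreme <- extreme + 1L
  }
  extreme / ncol(combos)
}

# Minimum total weight over ALL spanning trees of a complete graph given
# its distance matrix, by brute-force enumeration of edge subsets.
# Feasible for n <= 6.
oracle_min_spanning_weight <- function(d) {
  n <- nrow(d)
  if (n == 1) return(0)
  pairs <- combn(n, 2)
  m <- ncol(pairs)
  subsets <- combn(m, n - 1)
  best <- Inf
  for (k in seq_len(ncol(subsets))) {
    es <- subsets[, k]
    # connectivity check by union-find
    parent <- seq_len(n)
    find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
    acyclic <- TRUE
    for (e in es) {
      ri <- find(pairs[1, e]); rj <- find(pairs[2, e])
      if (ri == rj) { acyclic <- FALSE; break }
      parent[ri] <- rj
    }
    if (!acyclic) next
    w <- sum(d[cbind(pairs[1, es], pairs[2, es])])
    if (w < best) best <- w
  }
  best
}

# Small fixture helpers ------------------------------------------------

rand_genotype_pair <- function(n_per_pop = 20, n_loci = 4, k_alleles = 6,
                               fst = 0.1, seed = 1) {
  cfg <- sim_config(microsats = list(n_pops = 2L,
                                     n_ind = as.integer(n_per_pop),
                                     n_loci = as.integer(n_loci),
                                     alleles_per_locus = as.integer(k_alleles),
                                     fst = fst))
  gen_microsats(cfg, seed = seed)
}
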