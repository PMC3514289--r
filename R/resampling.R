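#' Derive a reproducible sub-seed from a pipeline seed and a key
#'
#' Each test in the pipeline draws its permutations from an independent
#' stream keyed by (test name, system, ...), so adding or reordering
#' tests never perturbs the others. A small multiplicative string hash
#' folds the key into the base seed; the result always fits a 32-bit
#' integer.
#'
#' @param seed Base integer seed.
#' @param ... Character/numeric key components.
#' @return An integer seed in `[1, 2^31 - 1]`.
#' @export
derive_seed <- function(seed, ...) {
  key <- paste(c(...), collapse = "/")
  h <- as.double(seed) %% 2147483647
  for (b in utf8ToInt(key)) h <- (h * 31 + b) %% 2147483647
  as.integer(h) + 1L
}

group_order <- function(labels, ref = NULL) {
  lev <- unique(as.character(labels))
  if (!is.null(ref)) {
    if (!ref %in% lev) stop("reference group '", ref, "' not present")
    lev <- c(ref, setdiff(lev, ref))
  } else if ("lake" %in% lev) {
    ## study convention: lake first, so positive differences mean
    ## lake > stream
    lev <- c("lake", setdiff(lev, "lake"))
  }
  lev
}

#' Difference in group means
#'
#' Test statistic for two-group permutation tests of average age, body
#' size, fecundity and egg size: `mean(group A) - mean(group B)`. When
#' the labels contain `"lake"` it is taken as group A, so positive values
#' mean lake > stream.
#'
#' @param values Numeric response vector; `NA`s are dropped pairwise.
#' @param labels Two-level grouping vector of the same length.
#' @param ref Optional label to force as group A.
#' @return The signed difference in means.
#' @export
stat_mean_diff <- function(values, labels, ref = NULL) {
  labels <- as.character(labels)
  lev <- group_order(labels, ref)
  if (length(lev) != 2) stop("stat_mean_diff needs exactly two groups, got ",
                             length(lev))
  keep <- !is.na(values)
  values <- values[keep]; labels <- labels[keep]
  nA <- sum(labels == lev[1]); nB <- sum(labels == lev[2])
  if (nA == 0 || nB == 0)
    stop("insufficient data: a group is empty after missing-value removal")
  mean(values[labels == lev[1]]) - mean(values[labels == lev[2]])
}

#' Difference in the variance of population means between habitats
#'
#' Test statistic for the among-population body-size variability
#' contrast: sample variance (n-1 denominator) of the population means
#' in habitat A minus that in habitat B.
#'
#' @param pop_means Numeric vector of population mean values.
#' @param habitat_of_pop Two-level habitat label per population.
#' @param ref Optional label to force as habitat A.
#' @return Signed difference of the two variances.
#' @export
stat_var_of_group_means <- function(pop_means, habitat_of_pop, ref = NULL) {
  keep <- !is.na(pop_means)
  pop_means <- pop_means[keep]
  habitat_of_pop <- as.character(habitat_of_pop)[keep]
  lev <- group_order(habitat_of_pop, ref)
  if (length(lev) != 2)
    stop("stat_var_of_group_means needs exactly two habitat levels")
  nA <- sum(habitat_of_pop == lev[1]); nB <- sum(habitat_of_pop == lev[2])
  if (nA < 2 || nB < 2)
    stop("insufficient data: need >= 2 populations per habitat level")
  stats::var(pop_means[habitat_of_pop == lev[1]]) -
    stats::var(pop_means[habitat_of_pop == lev[2]])
}

#' Pearson chi-square statistic
#'
#' Computed over cells with positive expected count after pruning empty
#' rows/columns. Degenerate tables (a single non-empty row or column)
#' return 0 with a warning rather than failing, so permutation nulls on
#' sparse data stay defined.
#'
#' @param x Either a contingency table (matrix of counts) or a vector of
#'   categories; in the latter case `labels` supplies the row grouping.
#' @param labels Optional grouping vector when `x` is a category vector.
#' @return The chi-square statistic (>= 0).
#' @export
stat_chi_square <- function(x, labels = NULL) {
  if (!is.null(labels)) {
    keep <- !is.na(x) & !is.na(labels)
    x <- table(as.character(labels)[keep], as.character(x)[keep])
  }
  x <- as.matrix(x)
  if (any(x < 0) || any(x != round(x))) stop("counts must be non-negative integers")
  x <- x[rowSums(x) > 0, , drop = FALSE]
  x <- x[, colSums(x) > 0, drop = FALSE]
  n <- sum(x)
  if (n == 0) stop("contingency table has zero grand total")
  if (nrow(x) < 2 || ncol(x) < 2) {
    warning("degenerate contingency table: chi-square statistic set to 0")
    return(0)
  }
  expected <- outer(rowSums(x), colSums(x)) / n
  ok <- expected > 0
  sum((x[ok] - expected[ok])^2 / expected[ok])
}

#' One-way ANOVA F ratio
#'
#' `F = MS_between / MS_within` for a k-level grouping; used as the
#' permutation statistic for the plate-morph x body-size association.
#' A fully constant response returns 0 with a warning.
#'
#' @param values Numeric response vector; `NA`s dropped pairwise.
#' @param groups Grouping vector with >= 2 levels.
#' @return The F ratio (>= 0).
#' @export
stat_anova_F <- function(values, groups) {
  keep <- !is.na(values) & !is.na(groups)
  values <- values[keep]; groups <- as.character(groups)[keep]
  lev <- unique(groups)
  k <- length(lev)
  n <- length(values)
  if (k < 2) stop("stat_anova_F needs >= 2 groups")
  if (n - k < 1) stop("insufficient data: no within-group degrees of freedom")
  gm <- mean(values)
  means <- vapply(lev, function(g) mean(values[groups == g]), numeric(1))
  sizes <- vapply(lev, function(g) sum(groups == g), numeric(1))
  ssb <- sum(sizes * (means - gm)^2)
  ssw <- sum((values - means[match(groups, lev)])^2)
  if (ssw == 0) {
    if (ssb == 0) {
      warning("zero variance everywhere: F statistic set to 0")
      return(0)
    }
    return(Inf)
  }
  (ssb / (k - 1)) / (ssw / (n - k))
}

#' Permutation test with a bespoke statistic
#'
#' The inferential engine of the pipeline. The grouping labels are
#' re-shuffled uniformly without replacement `B` times (equivalently the
#' response is randomized over the predictor) and the statistic is
#' recomputed each time. The P-value uses the add-one convention
#' `p = (n_extreme + 1) / (B + 1)`, whose attainable floor `1/(B+1)`
#' matches the conventional floors 0.0001 at B = 9999 and 0.001 at
#' B = 999. Ties count as extreme.
#'
#' Sidedness: `"two_sided_abs"` counts replicates with `|T*| >= |T_obs|`
#' (used for signed difference statistics); `"one_sided_ge"` counts
#' `T* >= T_obs` (used for inherently non-negative statistics such as
#' chi-square and F).
#'
#' With `exact = TRUE` and a two-level grouping, all distinct label
#' assignments are enumerated instead (feasible for small samples) and
#' `p = n_extreme / n_assignments`, the exact permutation P-value.
#'
#' @param values Numeric (or categorical, for chi-square) response.
#' @param labels Grouping labels, same length as `values`.
#' @param statistic Function `(values, labels) -> numeric` — one of
#'   [stat_mean_diff()], [stat_var_of_group_means()], [stat_chi_square()],
#'   [stat_anova_F()] or any user statistic.
#' @param B Number of random permutations (default 9999).
#' @param seed Integer seed; the test is reproducible given it.
#' @param sidedness `"two_sided_abs"` or `"one_sided_ge"`.
#' @param statistic_name Label stored in the result.
#' @param exact Enumerate all assignments instead of sampling.
#' @return An object of class `perm_result`: list with `statistic_name`,
#'   `observed`, `B`, `n_extreme`, `p_value`, `seed`, `sidedness`,
#'   `exact`.
#' @export
perm_test <- function(values, labels, statistic, B = 9999, seed = NULL,
                      sidedness = c("two_sided_abs", "one_sided_ge"),
                      statistic_name = deparse(substitute(statistic)),
                      exact = FALSE) {
  sidedness <- match.arg(sidedness)
  if (length(values) != length(labels))
    stop("values and labels must have equal length")
  keep <- !is.na(values) & !is.na(labels)
  values <- values[keep]
  labels <- as.character(labels)[keep]
  if (length(values) == 0) stop("no complete observations")

  res <- structure(list(statistic_name = statistic_name, observed = NA_real_,
                        B = NA_integer_, n_extreme = NA_integer_,
                        p_value = NA_real_, seed = seed,
                        sidedness = sidedness, exact = exact),
                   class = "perm_result")

  if (length(unique(values)) == 1) {
    warning("constant response vector: p-value set to 1")
    res$observed <- statistic(values, labels)
    res$B <- if (exact) NA_integer_ else as.integer(B)
    res$p_value <- 1
    return(res)
  }

  obs <- statistic(values, labels)
  tol <- 1e-12 * max(1, abs(obs))
  is_extreme <- if (sidedness == "two_sided_abs") {
    function(t) abs(t) >= abs(obs) - tol
  } else {
    function(t) t >= obs - tol
  }

  if (exact) {
    lev <- unique(labels)
    if (length(lev) != 2)
      stop("exact enumeration implemented for two-level labels only")
    n <- length(labels)
    nA <- sum(labels == lev[1])
    n_assign <- choose(n, nA)
    if (n_assign > 2e5)
      stop("exact enumeration infeasible: ", n_assign, " assignments")
    combos <- utils::combn(n, nA)
    reps <- apply(combos, 2, function(idx) {
      lab <- rep(lev[2], n)
      lab[idx] <- lev[1]
      statistic(values, lab)
    })
    n_extreme <- sum(vapply(reps, is_extreme, logical(1)))
    res$observed <- obs
    res$B <- as.integer(n_assign)
    res$n_extreme <- as.integer(n_extreme)
    res$p_value <- n_extreme / n_assign
    return(res)
  }

  if (B < 1) stop("B must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  reps <- vapply(seq_len(B), function(i) statistic(values, sample(labels)),
                 numeric(1))
  n_extreme <- sum(is_extreme(reps))
  res$observed <- obs
  res$B <- as.integer(B)
  res$n_extreme <- as.integer(n_extreme)
  res$p_value <- (n_extreme + 1) / (B + 1)
  res
}

#' @export
print.perm_result <- function(x, ...) {
  cat("Permutation test:", x$statistic_name, "\n")
  cat(sprintf("  observed = %.6g\n", x$observed))
  if (isTRUE(x$exact)) {
    cat(sprintf("  exact enumeration over %d assignments\n", x$B))
  } else {
    cat(sprintf("  B = %d random permutations (%s)\n", x$B, x$sidedness))
  }
  cat(sprintf("  P = %.6g\n", x$p_value))
  invisible(x)
}
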