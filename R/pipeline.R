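#' Per-site summary of stomach-content composition
#'
#' Proportions are computed per individual first (each stomach weighted
#' equally, not pooled counts), then averaged within site; the SD is the
#' sample SD of the per-individual proportions. Individuals with a zero
#' total prey count are excluded with a warning. A site with a single
#' usable individual has no defined SD; it is reported as 0 with
#' `sd_undefined = TRUE`.
#'
#' @param counts Data frame or matrix of per-individual prey-class
#'   counts (one column per class); non-count columns `individual_id`
#'   and `site` are ignored if present.
#' @param site_of Site label per individual.
#' @return Long data frame: `site`, `prey_class`, `mean_prop`,
#'   `sd_prop`, `n`, `sd_undefined`.
#' @export
diet_summary <- function(counts, site_of) {
  if (is.data.frame(counts))
    counts <- counts[, setdiff(names(counts), c("individual_id", "site")),
                     drop = FALSE]
  counts <- as.matrix(counts)
  if (is.null(colnames(counts)))
    colnames(counts) <- paste0("class_", seq_len(ncol(counts)))
  if (nrow(counts) != length(site_of))
    stop("site_of must have one label per individual")
  totals <- rowSums(counts)
  if (any(totals == 0)) {
    warning("excluding ", sum(totals == 0),
            " individual(s) with zero total prey count")
    keep <- totals > 0
    counts <- counts[keep, , drop = FALSE]
    site_of <- site_of[keep]
    totals <- totals[keep]
  }
  if (nrow(counts) == 0) stop("no individuals with prey counts")
  props <- counts / totals
  out <- list()
  for (s in unique(site_of)) {
    p <- props[site_of == s, , drop = FALSE]
    n <- nrow(p)
    sds <- if (n > 1) apply(p, 2, stats::sd) else rep(0, ncol(p))
    out[[s]] <- data.frame(
      site = s, prey_class = colnames(counts),
      mean_prop = colMeans(p), sd_prop = sds, n = n,
      sd_undefined = n <= 1, stringsAsFactors = FALSE
    )
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Age-class composition per system and habitat
#'
#' Proportions of each calendar-year age class within every
#' (system, habitat) cell, among aged individuals; unaged individuals
#' are counted separately, never silently dropped into an age class.
#'
#' @param records Phenotype data frame ([read_phenotypes()] /
#'   [gen_phenotypes()]).
#' @return Data frame: `system`, `habitat`, one `age_<k>` proportion
#'   column per observed age class, `n_aged`, `n_unaged`.
#' @export
age_composition_table <- function(records) {
  ages <- sort(unique(records$age_calendar_year))
  cells <- unique(records[, c("system", "habitat")])
  out <- list()
  for (i in seq_len(nrow(cells))) {
    sel <- records$system == cells$system[i] &
      records$habitat == cells$habitat[i]
    a <- records$age_calendar_year[sel]
    aged <- a[!is.na(a)]
    props <- if (length(aged) > 0) {
      as.numeric(table(factor(aged, levels = ages))) / length(aged)
    } else rep(NA_real_, length(ages))
    row <- data.frame(system = cells$system[i], habitat = cells$habitat[i],
                      stringsAsFactors = FALSE)
    for (k in seq_along(ages)) row[[paste0("age_", ages[k])]] <- props[k]
    row$n_aged <- length(aged)
    row$n_unaged <- sum(is.na(a))
    out[[i]] <- row
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

perm_row <- function(test, system, pr) {
  data.frame(test = test, system = system,
             statistic_name = pr$statistic_name, observed = pr$observed,
             B = pr$B, n_extreme = pr$n_extreme, p_value = pr$p_value,
             seed = if (is.null(pr$seed)) NA_integer_ else pr$seed,
             stringsAsFactors = FALSE)
}

#' Lake-stream life-history permutation test battery
#'
#' Runs, per lake-stream system: the age and body-size mean-difference
#' tests; pooled across sites within habitat: the fecundity and egg-size
#' tests; per system: the plate-morph chi-square test; and, for
#' sufficiently polymorphic stream samples, the plate-morph x body-size
#' ANOVA-F test. Each test draws its permutations from an independent
#' stream derived from the base seed and the test's identity.
#'
#' @param records Phenotype data frame.
#' @param B Permutations per test (default 9999, floor 0.0001).
#' @param seed Base seed.
#' @param shared_lake Named character vector mapping a system without its
#'   own lake sample to the system whose lake sample it shares (the two
#'   southern stream systems drain into the lake at almost the same
#'   location and share one lake sample). Default `c(COS1 = "COS",
#'   COS2 = "COS")`.
#' @return Long data frame of permutation results (one row per test).
#' @export
life_history_tests <- function(records, B = 9999, seed = 1,
                               shared_lake = c(COS1 = "COS", COS2 = "COS")) {
  out <- list()
  systems <- unique(records$system[records$habitat %in% c("lake", "stream")])
  has_hab <- function(sy, hab)
    any(records$system == sy & records$habitat == hab)
  paired <- systems[vapply(systems, function(sy) {
    has_hab(sy, "lake") && has_hab(sy, "stream")
  }, logical(1))]
  borrowed <- systems[vapply(systems, function(sy) {
    !has_hab(sy, "lake") && has_hab(sy, "stream") &&
      sy %in% names(shared_lake) && has_hab(shared_lake[[sy]], "lake")
  }, logical(1))]

  for (sy in c(paired, borrowed)) {
    lake_sy <- if (sy %in% borrowed) shared_lake[[sy]] else sy
    sel <- (records$system == sy & records$habitat == "stream") |
      (records$system == lake_sy & records$habitat == "lake")
    d <- records[sel, ]
    pr <- perm_test(d$age_calendar_year, d$habitat, stat_mean_diff, B = B,
                    seed = derive_seed(seed, "age", sy),
                    sidedness = "two_sided_abs",
                    statistic_name = "mean age difference (lake - stream)")
    out[[length(out) + 1L]] <- perm_row("age", sy, pr)
    pr <- perm_test(d$centroid_size, d$habitat, stat_mean_diff, B = B,
                    seed = derive_seed(seed, "size", sy),
                    sidedness = "two_sided_abs",
                    statistic_name = "mean centroid size difference (lake - stream)")
    out[[length(out) + 1L]] <- perm_row("body_size", sy, pr)

    morphs <- d$plate_morph[!is.na(d$plate_morph)]
    if (length(unique(morphs)) >= 2) {
      pr <- perm_test(d$plate_morph, d$habitat, stat_chi_square, B = B,
                      seed = derive_seed(seed, "plate_chisq", sy),
                      sidedness = "one_sided_ge",
                      statistic_name = "plate morph chi-square")
      out[[length(out) + 1L]] <- perm_row("plate_morph", sy, pr)
    }
  }

  ## fecundity and egg size: pooled across sites within habitat
  fem <- records[!is.na(records$fecundity) &
                   records$habitat %in% c("lake", "stream"), ]
  if (nrow(fem) > 0 && length(unique(fem$habitat)) == 2) {
    pr <- perm_test(fem$fecundity, fem$habitat, stat_mean_diff, B = B,
                    seed = derive_seed(seed, "fecundity", "pooled"),
                    sidedness = "two_sided_abs",
                    statistic_name = "mean fecundity difference (lake - stream)")
    out[[length(out) + 1L]] <- perm_row("fecundity", "pooled", pr)

    ok <- fem$fecundity > 0 & !is.na(fem$clutch_dry_mass)
    eg <- fem[ok, ]
    if (nrow(eg) > 0 && length(unique(eg$habitat)) == 2) {
      es <- egg_size(eg$fecundity, eg$clutch_dry_mass)
      pr <- perm_test(es, eg$habitat, stat_mean_diff, B = B,
                      seed = derive_seed(seed, "egg_size", "pooled"),
                      sidedness = "two_sided_abs",
                      statistic_name = "mean egg size difference (lake - stream)")
      out[[length(out) + 1L]] <- perm_row("egg_size", "pooled", pr)
    }
  }

  ## plate morph x body size: stream samples with >= 2 morphs, each
  ## represented by >= 2 individuals
  for (sy in unique(records$system)) {
    d <- records[records$system == sy & records$habitat == "stream" &
                   !is.na(records$plate_morph) &
                   !is.na(records$centroid_size), ]
    tab <- table(d$plate_morph)
    if (length(tab) >= 2 && all(tab >= 2)) {
      pr <- perm_test(d$centroid_size, d$plate_morph, stat_anova_F, B = B,
                      seed = derive_seed(seed, "plate_size_F", sy),
                      sidedness = "one_sided_ge",
                      statistic_name = "ANOVA F: centroid size ~ plate morph")
      out[[length(out) + 1L]] <- perm_row("plate_size_anova", sy, pr)
    }
  }
  do.call(rbind, out)
}

#' Variance-of-population-means habitat contrasts
#'
#' The global body-size comparison: separate lake-stream and
#' marine-stream permutation tests using the difference in the variance
#' of population mean sizes as test statistic, permuting habitat labels
#' over populations (the permutation unit is the population).
#'
#' @param pop_sizes Data frame with `population`, `habitat`,
#'   `mean_size` (as from [gen_global_sizes()]).
#' @param B Permutations per test.
#' @param seed Base seed.
#' @return Long data frame of permutation results.
#' @export
global_size_variance_tests <- function(pop_sizes, B = 9999, seed = 1) {
  out <- list()
  contrasts <- list(c("lake", "stream"), c("marine", "stream"))
  for (ct in contrasts) {
    d <- pop_sizes[pop_sizes$habitat %in% ct, ]
    if (length(unique(d$habitat)) < 2) next
    if (min(table(d$habitat)) < 2) next
    pr <- perm_test(d$mean_size, d$habitat,
                    function(v, l) stat_var_of_group_means(v, l, ref = ct[1]),
                    B = B, seed = derive_seed(seed, "size_variance", ct[1]),
                    sidedness = "two_sided_abs",
                    statistic_name = sprintf(
                      "variance of population means (%s - stream)", ct[1]))
    out[[length(out) + 1L]] <- perm_row("size_variance",
                                        paste(ct, collapse = "_vs_"), pr)
  }
  do.call(rbind, out)
}

#' Run the full synthetic analysis pipeline
#'
#' Generates every input with the synthetic-data module (or consumes the
#' data frames supplied in `data`), then executes the enabled stages in a
#' fixed order with seeds derived per stage: life-history permutation
#' tests, global size-variance tests, the pairwise F_ST table (raw theta,
#' permutation P-values, standardized F'_ST), haplotype collapsing and
#' the minimum-spanning network, the diet summary, and the age
#' composition table. Identical (config, seed) gives identical output.
#'
#' @param config A [sim_config()], or the path to a YAML file whose
#'   top-level keys override the defaults.
#' @param seed Base integer seed for the whole run.
#' @param B Permutations for phenotype tests (default 9999).
#' @param B_fst Permutations for F_ST P-values (default 999).
#' @param stages Character vector of stages to run, a subset of
#'   `c("phenotypes", "global", "fst", "haplotypes", "diet")`.
#' @param out_dir Optional directory; when given, report tables are
#'   written there as TSVs.
#' @param data Optional named list of pre-loaded inputs (`phenotypes`,
#'   `genotypes`, `alignment`, `diet`, `global_sizes`) that replace
#'   synthetic generation for the corresponding stage.
#' @return An object of class `analysis_report`.
#' @export
run_all <- function(config = sim_config(), seed = 1, B = 9999, B_fst = 999,
                    stages = c("phenotypes", "global", "fst", "haplotypes",
                               "diet"),
                    out_dir = NULL, data = list()) {
  if (is.character(config)) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- do.call(sim_config, yaml::read_yaml(config))
  }
  known <- c("phenotypes", "global", "fst", "haplotypes", "diet")
  bad <- setdiff(stages, known)
  if (length(bad)) stop("unknown stage(s): ", paste(bad, collapse = ", "))

  report <- structure(list(seed = seed, stages = stages, config = config,
                           perm_results = NULL, fst = NULL,
                           haplotypes = NULL, network = NULL,
                           diet = NULL, age_composition = NULL),
                      class = "analysis_report")

  if ("phenotypes" %in% stages) {
    ph <- data$phenotypes
    if (is.null(ph))
      ph <- gen_phenotypes(config, seed = derive_seed(seed, "gen", "phenotypes"))
    report$phenotypes <- ph
    report$perm_results <- life_history_tests(ph, B = B, seed = seed)
    report$age_composition <- age_composition_table(ph)
  }
  if ("global" %in% stages) {
    gs <- data$global_sizes
    if (is.null(gs))
      gs <- gen_global_sizes(config, seed = derive_seed(seed, "gen", "global"))
    report$global_sizes <- gs
    gv <- global_size_variance_tests(gs, B = B, seed = seed)
    report$perm_results <- rbind(report$perm_results, gv)
  }
  if ("fst" %in% stages) {
    g <- data$genotypes
    if (is.null(g)) {
      cfg_ms <- config
      cfg_ms$microsats$pop_names <- config$phenotypes$sites$site
      cfg_ms$microsats$n_pops <- length(cfg_ms$microsats$pop_names)
      g <- gen_microsats(cfg_ms, seed = derive_seed(seed, "gen", "microsats"))
    }
    report$genotypes <- g
    report$fst <- fst_matrix(g, B = B_fst, seed = seed, standardized = TRUE)
  }
  if ("haplotypes" %in% stages) {
    aln <- data$alignment
    if (is.null(aln))
      aln <- gen_dloop(config, seed = derive_seed(seed, "gen", "dloop"))
    report$alignment <- aln
    report$haplotypes <- collapse_haplotypes(aln)
    report$network <- mst_network(report$haplotypes)
  }
  if ("diet" %in% stages) {
    diet <- data$diet
    if (is.null(diet))
      diet <- gen_diet(config, seed = derive_seed(seed, "gen", "diet"))
    report$diet_counts <- diet
    report$diet <- diet_summary(diet, diet$site)
  }

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    wt <- function(x, f) utils::write.table(
      x, file.path(out_dir, f), sep = "\t", quote = FALSE, row.names = FALSE)
    if (!is.null(report$perm_results))
      wt(report$perm_results, "permutation_tests.tsv")
    if (!is.null(report$age_composition))
      wt(report$age_composition, "age_composition.tsv")
    if (!is.null(report$fst)) {
      utils::write.table(format_fst_table(report$fst),
                         file.path(out_dir, "fst_table.tsv"),
                         sep = "\t", quote = FALSE, col.names = NA)
      utils::write.table(report$fst$theta,
                         file.path(out_dir, "fst_theta_full_precision.tsv"),
                         sep = "\t", quote = FALSE, col.names = NA)
    }
    if (!is.null(report$haplotypes))
      write_haplotype_tables(report$haplotypes, report$network,
                             file.path(out_dir, "haplotype_counts.tsv"),
                             file.path(out_dir, "haplotype_network_edges.tsv"))
    if (!is.null(report$diet)) wt(report$diet, "diet_summary.tsv")
  }
  report
}

#' @export
print.analysis_report <- function(x, ...) {
  cat("analysis_report (seed", x$seed, ")\n")
  if (!is.null(x$perm_results)) {
    cat("\nPermutation tests:\n")
    print(x$perm_results[, c("test", "system", "observed", "p_value")],
          row.names = FALSE)
  }
  if (!is.null(x$fst))
    cat("\nF_ST: ", length(x$fst$pops), " populations, pairwise theta in [",
        sprintf("%.3f", min(x$fst$theta, na.rm = TRUE)), ", ",
        sprintf("%.3f", max(x$fst$theta, na.rm = TRUE)), "]\n", sep = "")
  if (!is.null(x$haplotypes)) print(x$haplotypes)
  invisible(x)
}
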