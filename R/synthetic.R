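## Dirichlet sampler (gamma construction); zero-weight components stay
## exactly zero.
rdirichlet1 <- function(alpha) {
  x <- vapply(alpha, function(a) if (a > 0) stats::rgamma(1, a) else 0,
              numeric(1))
  s <- sum(x)
  if (s == 0) stop("all Dirichlet weights zero")
  x / s
}

default_sites <- function() {
  data.frame(
    site = c("CON_lake", "CON_stream", "COE_lake", "COE_stream",
             "COS_lake", "COS1_stream", "COS2_stream", "COW_lake",
             "COW_stream", "RHI", "DAN"),
    system = c("CON", "CON", "COE", "COE", "COS", "COS1", "COS2",
               "COW", "COW", "RHI", "DAN"),
    habitat = c("lake", "stream", "lake", "stream", "lake", "stream",
                "stream", "lake", "stream", "stream", "stream"),
    n = c(22L, 23L, 33L, 25L, 24L, 25L, 24L, 24L, 25L, 24L, 34L),
    stringsAsFactors = FALSE
  )
}

default_hap_freqs <- function() {
  ## one predominant haplotype basin-wide; a second fixed in the Rhine
  ## sample and shared with some streams; rare haplotypes mainly in
  ## streams
  m <- rbind(
    CON_lake    = c(1.00, 0.00, 0.00, 0.00, 0.00),
    CON_stream  = c(0.70, 0.10, 0.20, 0.00, 0.00),
    COE_lake    = c(1.00, 0.00, 0.00, 0.00, 0.00),
    COE_stream  = c(0.70, 0.30, 0.00, 0.00, 0.00),
    COS_lake    = c(1.00, 0.00, 0.00, 0.00, 0.00),
    COS1_stream = c(0.80, 0.00, 0.00, 0.20, 0.00),
    COS2_stream = c(0.80, 0.00, 0.00, 0.00, 0.20),
    COW_lake    = c(1.00, 0.00, 0.00, 0.00, 0.00),
    COW_stream  = c(0.85, 0.15, 0.00, 0.00, 0.00),
    RHI         = c(0.00, 1.00, 0.00, 0.00, 0.00),
    DAN         = c(1.00, 0.00, 0.00, 0.00, 0.00)
  )
  colnames(m) <- paste0("H", 1:5)
  m
}

#' Simulation configuration for the synthetic-data generators
#'
#' Bundles every tunable of the generators with defaults representing the
#' study conditions the pipeline is built around: habitat-structured age
#' distributions (streams mostly annual, lake fish mostly in their third
#' calendar year), per-age centroid-size means chosen so the overall
#' habitat means are 80.4 mm (lake) and 63.2 mm (stream), a
#' fecundity-on-size regression hitting 284 (lake) vs 94 (stream) eggs at
#' those sizes, equal per-egg dry mass in both habitats, 8 microsatellite
#' loci under a Balding-Nichols island model, and a 305-bp mitochondrial
#' alignment with 6 segregating sites defining 5 haplotypes.
#'
#' @param ... Named overrides merged into the defaults (nested lists are
#'   merged with [utils::modifyList()]).
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(...) {
  cfg <- list(
    phenotypes = list(
      sites = default_sites(),
      age_classes = c(2L, 3L, 4L),
      age_probs = list(lake = c(0.10, 0.85, 0.05),
                      stream = c(0.95, 0.05, 0.00)),
      size_mean = list(lake = c(68, 81.5, 86.6),
                       stream = c(62.5, 76.5, 80)),
      size_sd = 5,
      mass_coef = 4.9e-6, mass_exp = 3, mass_sdlog = 0.10,
      fecundity_intercept = -604.2, fecundity_slope = 11.05,
      fecundity_sd = 30,
      egg_mass_mean = 0.4, egg_mass_sdlog = 0.10,
      plate_probs = list(lake = c(full = 0.92, partial = 0.06, low = 0.02),
                         stream = c(full = 0.55, partial = 0.25, low = 0.20)),
      prop_female = 0.5,
      missing_age_rate = 0
    ),
    landmarks = list(n_landmarks = 16L, noise_sd = 0),
    microsats = list(
      n_pops = 11L, n_ind = 25L, n_loci = 8L, alleles_per_locus = 10L,
      fst = 0.10, missing_rate = 0,
      loci = c("Stn28", "Stn67", "Stn99", "Stn119", "Stn159", "Stn171",
               "Stn195", "Stn200"),
      pop_names = NULL
    ),
    dloop = list(
      length = 305L, n_snp = 6L, n_hap = 5L, topology = "star",
      pops = default_sites()$site,
      n_seq = c(24L, 20L, 30L, 24L, 24L, 24L, 22L, 24L, 24L, 18L, 22L),
      hap_freqs = default_hap_freqs()
    ),
    diet = list(
      classes = c("pelagic_cladocera", "copepods", "benthic_cladocera",
                  "other_crustacea", "vermiform_larvae",
                  "other_insect_larvae", "stickleback_eggs"),
      site_means = rbind(
        lake_offshore = c(0.34, 0.66, 0, 0, 0, 0, 0),
        lake_littoral = c(0.01, 0.07, 0.33, 0.03, 0.42, 0.15, 0.03),
        stream        = c(0.00, 0.17, 0.20, 0.00, 0.57, 0.06, 0.09)
      ),
      concentration = 4,
      n_ind = c(lake_offshore = 5L, lake_littoral = 20L, stream = 7L),
      mean_total = 20
    ),
    global_sizes = list(
      lake = list(n_pops = 9L, mean = 75, sd = 12),
      stream = list(n_pops = 8L, mean = 63, sd = 3),
      marine = list(n_pops = 5L, mean = 70, sd = 8)
    ),
    seed = 1L
  )
  utils::modifyList(cfg, list(...))
}

validate_probs <- function(p, what) {
  if (any(p < 0) || abs(sum(p) - 1) > 1e-9)
    stop("invalid configuration: ", what,
         " must be a probability vector summing to 1")
}

#' Generate a synthetic per-individual phenotype table
#'
#' Per site: ages drawn from the habitat age-class distribution; centroid
#' size Normal around the habitat-and-age mean; mass allometric in size
#' with lognormal noise; for females, fecundity is a linear function of
#' size with Gaussian noise, floored at 0 and rounded, and clutch dry
#' mass is fecundity times a lognormally perturbed per-egg mass; plate
#' morph is categorical per habitat.
#'
#' @param cfg A [sim_config()].
#' @param seed Integer seed (default `cfg$seed`).
#' @return Data frame of phenotype records (the canonical columns of
#'   [read_phenotypes()]).
#' @export
gen_phenotypes <- function(cfg = sim_config(), seed = cfg$seed) {
  p <- cfg$phenotypes
  for (h in names(p$age_probs)) validate_probs(p$age_probs[[h]],
                                               paste0("age_probs$", h))
  for (h in names(p$plate_probs)) validate_probs(p$plate_probs[[h]],
                                                 paste0("plate_probs$", h))
  if (p$size_sd <= 0) stop("invalid configuration: size_sd must be > 0")
  set.seed(seed)
  out <- list()
  for (s in seq_len(nrow(p$sites))) {
    site <- p$sites$site[s]; habitat <- p$sites$habitat[s]
    n <- p$sites$n[s]
    ages <- sample(p$age_classes, n, replace = TRUE,
                   prob = p$age_probs[[habitat]])
    mu <- p$size_mean[[habitat]][match(ages, p$age_classes)]
    cs <- stats::rnorm(n, mu, p$size_sd)
    cs <- pmax(cs, 1)                       # sizes are strictly positive
    mass <- p$mass_coef * cs^p$mass_exp * stats::rlnorm(n, 0, p$mass_sdlog)
    sex <- sample(c("F", "M"), n, replace = TRUE,
                  prob = c(p$prop_female, 1 - p$prop_female))
    fec <- rep(NA_real_, n)
    clutch <- rep(NA_real_, n)
    fem <- sex == "F"
    if (any(fem)) {
      lin <- p$fecundity_intercept + p$fecundity_slope * cs[fem] +
        stats::rnorm(sum(fem), 0, p$fecundity_sd)
      fec[fem] <- pmax(0, round(lin))
      clutch[fem] <- fec[fem] * p$egg_mass_mean *
        stats::rlnorm(sum(fem), 0, p$egg_mass_sdlog)
    }
    plate <- sample(names(p$plate_probs[[habitat]]), n, replace = TRUE,
                    prob = p$plate_probs[[habitat]])
    if (p$missing_age_rate > 0) {
      drop <- stats::runif(n) < p$missing_age_rate
      ages[drop] <- NA_integer_
    }
    out[[s]] <- data.frame(
      individual_id = sprintf("%s_%03d", site, seq_len(n)),
      site = site, system = p$sites$system[s], habitat = habitat,
      sex = sex, sampling_year = 2011L,
      age_calendar_year = as.integer(ages),
      centroid_size = cs, mass = mass, fecundity = fec,
      clutch_dry_mass = clutch, plate_morph = plate,
      stringsAsFactors = FALSE
    )
  }
  do.call(rbind, out)
}

## 16-landmark template (a stylised fish outline), centred and scaled to
## unit centroid size.
landmark_template <- function(n_landmarks = 16L) {
  t <- seq(0, 2 * pi, length.out = n_landmarks + 1)[seq_len(n_landmarks)]
  lm <- cbind(cos(t) * (1 + 0.4 * cos(t)), 0.45 * sin(t))
  lm <- sweep(lm, 2, colMeans(lm))
  lm / sqrt(sum(lm^2))
}

#' Generate landmark configurations of given centroid size
#'
#' A fixed 16-landmark template is rescaled so its centroid size equals
#' `target_cs` exactly; optional isotropic Gaussian landmark noise is
#' added afterwards (so the expected centroid size stays near the
#' target).
#'
#' @param cfg A [sim_config()] (supplies `n_landmarks` and `noise_sd`).
#' @param target_cs Target centroid size(s) in mm, one per specimen.
#' @param specimen_ids Optional ids (default `spec_1..n`).
#' @param seed Integer seed.
#' @return List of landmark sets (`specimen_id`, `landmarks`, `scale`),
#'   compatible with [centroid_size()] and [write_tps()].
#' @export
gen_landmarks <- function(cfg = sim_config(), target_cs,
                          specimen_ids = NULL, seed = cfg$seed) {
  if (any(target_cs <= 0)) stop("target_cs must be > 0")
  set.seed(seed)
  tmpl <- landmark_template(cfg$landmarks$n_landmarks)
  if (is.null(specimen_ids))
    specimen_ids <- sprintf("spec_%d", seq_along(target_cs))
  lapply(seq_along(target_cs), function(i) {
    lm <- tmpl * target_cs[i]
    if (cfg$landmarks$noise_sd > 0)
      lm <- lm + matrix(stats::rnorm(length(lm), 0, cfg$landmarks$noise_sd),
                        nrow(lm))
    list(specimen_id = specimen_ids[i], landmarks = lm, scale = 1)
  })
}

#' Simulate island-model microsatellite genotypes
#'
#' Balding-Nichols model: per locus an ancestral allele-frequency vector
#' is drawn from a symmetric Dirichlet; each population's frequencies are
#' drawn from `Dirichlet(p * (1 - F) / F)` around the ancestral vector,
#' so `F` is exactly the differentiation parameter the Weir-Cockerham
#' estimator targets; diploid genotypes are drawn under Hardy-Weinberg
#' within populations. Optionally a fraction of calls is set missing.
#'
#' @param cfg A [sim_config()] (block `microsats`).
#' @param seed Integer seed.
#' @return A [genotype_matrix()].
#' @export
gen_microsats <- function(cfg = sim_config(), seed = cfg$seed) {
  m <- cfg$microsats
  if (m$fst <= 0 || m$fst >= 1) stop("F must be in (0, 1)")
  set.seed(seed)
  pops <- m$pop_names
  if (is.null(pops)) pops <- sprintf("POP_%d", seq_len(m$n_pops))
  if (length(pops) != m$n_pops) stop("pop_names length must equal n_pops")
  loci <- m$loci
  if (length(loci) != m$n_loci)
    loci <- sprintf("locus_%d", seq_len(m$n_loci))
  n_total <- m$n_pops * m$n_ind
  a1 <- matrix(NA_integer_, n_total, m$n_loci)
  a2 <- matrix(NA_integer_, n_total, m$n_loci)
  popvec <- rep(pops, each = m$n_ind)
  scale <- (1 - m$fst) / m$fst
  for (j in seq_len(m$n_loci)) {
    anc <- rdirichlet1(rep(1, m$alleles_per_locus))
    for (pi in seq_len(m$n_pops)) {
      pf <- rdirichlet1(anc * scale)
      rows <- which(popvec == pops[pi])
      a1[rows, j] <- sample.int(m$alleles_per_locus, length(rows),
                                replace = TRUE, prob = pf)
      a2[rows, j] <- sample.int(m$alleles_per_locus, length(rows),
                                replace = TRUE, prob = pf)
    }
  }
  if (m$missing_rate > 0) {
    miss <- matrix(stats::runif(n_total * m$n_loci) < m$missing_rate,
                   n_total)
    a1[miss] <- NA_integer_; a2[miss] <- NA_integer_
  }
  ids <- sprintf("%s_%03d", popvec, sequence(rep(m$n_ind, m$n_pops)))
  genotype_matrix(ids, popvec, loci, a1, a2)
}

#' Simulate an aligned set of mitochondrial haplotype sequences
#'
#' Builds `n_hap` haplotypes on a random backbone of the configured
#' length by placing `n_snp` substitutions at distinct columns. Under the
#' `"star"` topology the mutant columns are distributed over the
#' `n_hap - 1` branches radiating from the backbone haplotype (branch
#' lengths as even as possible — with `n_hap = n_snp + 1` every branch
#' carries exactly one substitution); under `"chain"` haplotype i adds
#' its substitutions on top of haplotype i-1. Sequences are then sampled
#' per population according to the configured haplotype frequencies.
#'
#' @param cfg A [sim_config()] (block `dloop`).
#' @param seed Integer seed.
#' @return A [alignment()] object with population labels.
#' @export
gen_dloop <- function(cfg = sim_config(), seed = cfg$seed) {
  d <- cfg$dloop
  if (d$n_snp >= d$length) stop("n_snp must be < alignment length")
  if (d$n_hap < 1 || d$n_hap > d$n_snp + 1)
    stop("n_hap must be in [1, n_snp + 1]")
  hf <- as.matrix(d$hap_freqs)
  if (nrow(hf) != length(d$pops) || ncol(hf) != d$n_hap)
    stop("hap_freqs must be pops x n_hap")
  for (i in seq_len(nrow(hf))) validate_probs(hf[i, ], "hap_freqs row")
  if (length(d$n_seq) != length(d$pops))
    stop("n_seq must have one entry per population")
  set.seed(seed)

  bases <- c("A", "C", "G", "T")
  backbone <- sample(bases, d$length, replace = TRUE)
  snp_cols <- sort(sample.int(d$length, d$n_snp))
  ## assign mutant columns to branches (haplotypes 2..n_hap)
  n_branch <- max(d$n_hap - 1, 1)
  branch_of <- if (d$n_hap > 1) {
    sort(rep_len(seq_len(n_branch), d$n_snp))
  } else integer(0)

  haps <- matrix(rep(backbone, d$n_hap), nrow = d$n_hap, byrow = TRUE)
  if (d$n_hap > 1) {
    for (b in seq_len(n_branch)) {
      cols <- snp_cols[branch_of == b]
      for (col in cols) {
        alt <- sample(setdiff(bases, backbone[col]), 1)
        if (d$topology == "star") {
          haps[b + 1, col] <- alt
        } else if (d$topology == "chain") {
          rows <- seq(b + 1, d$n_hap)
          haps[rows, col] <- alt
        } else stop("unknown topology: ", d$topology)
      }
    }
  }
  hap_seqs <- apply(haps, 1, paste, collapse = "")

  seqs <- character(0); popv <- character(0)
  for (pi in seq_along(d$pops)) {
    n <- d$n_seq[pi]
    draws <- sample.int(d$n_hap, n, replace = TRUE, prob = hf[pi, ])
    ids <- sprintf("%s_seq%03d", d$pops[pi], seq_len(n))
    s <- hap_seqs[draws]
    names(s) <- ids
    seqs <- c(seqs, s)
    popv <- c(popv, stats::setNames(rep(d$pops[pi], n), ids))
  }
  alignment(seqs, popv)
}

#' Simulate per-individual stomach-content counts
#'
#' Per individual, the total prey count is Poisson and the composition is
#' Dirichlet-multinomial around the site's mean proportions with a
#' common concentration; prey classes with zero mean weight are never
#' sampled.
#'
#' @param cfg A [sim_config()] (block `diet`).
#' @param seed Integer seed.
#' @return Data frame with `individual_id`, `site` and one count column
#'   per prey class.
#' @export
gen_diet <- function(cfg = sim_config(), seed = cfg$seed) {
  d <- cfg$diet
  sm <- as.matrix(d$site_means)
  if (any(sm < 0)) stop("invalid site_means")
  sm <- sm / rowSums(sm)                      # tolerate rounded inputs
  if (d$concentration <= 0) stop("concentration must be > 0")
  set.seed(seed)
  out <- list()
  for (s in rownames(sm)) {
    n <- d$n_ind[[s]]
    counts <- matrix(0L, n, ncol(sm), dimnames = list(NULL, d$classes))
    for (i in seq_len(n)) {
      total <- stats::rpois(1, d$mean_total)
      if (total > 0) {
        pr <- rdirichlet1(sm[s, ] * d$concentration)
        counts[i, ] <- as.integer(stats::rmultinom(1, total, pr))
      }
    }
    out[[s]] <- data.frame(
      individual_id = sprintf("%s_%02d", s, seq_len(n)),
      site = s, counts, stringsAsFactors = FALSE, check.names = FALSE
    )
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Simulate population mean body sizes for the global habitat comparison
#'
#' Draws per-habitat vectors of population mean sizes (lake means much
#' more variable than stream means, marine intermediate), the input to
#' the variance-of-population-means permutation test.
#'
#' @param cfg A [sim_config()] (block `global_sizes`).
#' @param seed Integer seed.
#' @return Data frame with `population`, `habitat`, `mean_size`.
#' @export
gen_global_sizes <- function(cfg = sim_config(), seed = cfg$seed) {
  set.seed(seed)
  out <- list()
  for (h in names(cfg$global_sizes)) {
    gs <- cfg$global_sizes[[h]]
    out[[h]] <- data.frame(
      population = sprintf("%s_pop%d", h, seq_len(gs$n_pops)),
      habitat = h,
      mean_size = stats::rnorm(gs$n_pops, gs$mean, gs$sd),
      stringsAsFactors = FALSE
    )
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
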