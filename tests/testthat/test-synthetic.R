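test_that("generators are byte-reproducible given (seed, config)", {
  cfg <- sim_config()
  expect_identical(gen_phenotypes(cfg, seed = 5), gen_phenotypes(cfg, seed = 5))
  expect_identical(gen_microsats(cfg, seed = 5)$a1,
                   gen_microsats(cfg, seed = 5)$a1)
  expect_identical(gen_dloop(cfg, seed = 5)$seqs, gen_dloop(cfg, seed = 5)$seqs)
  expect_identical(gen_diet(cfg, seed = 5), gen_diet(cfg, seed = 5))
  expect_false(identical(gen_phenotypes(cfg, seed = 5),
                         gen_phenotypes(cfg, seed = 6)))
})

test_that("phenotype generator reproduces the configured habitat structure", {
  ph <- gen_phenotypes(sim_config(), seed = 11)
  # habitat means sit near the configured 80.4 / 63.2 mm anchors
  expect_equal(mean(ph$centroid_size[ph$habitat == "lake"]), 80.4,
               tolerance = 0.03)
  expect_equal(mean(ph$centroid_size[ph$habitat == "stream"]), 63.2,
               tolerance = 0.03)
  # streams are essentially annual; lake fish mostly age 3
  expect_gt(mean(ph$age_calendar_year[ph$habitat == "stream"] == 2), 0.85)
  expect_gt(mean(ph$age_calendar_year[ph$habitat == "lake"] == 3), 0.7)
  expect_true(all(ph$age_calendar_year[ph$habitat == "stream"] < 4))
  # fecundity only for females, non-negative integers
  expect_true(all(is.na(ph$fecundity[ph$sex == "M"])))
  fec <- ph$fecundity[!is.na(ph$fecundity)]
  expect_true(all(fec >= 0 & fec == round(fec)))
})

test_that("generated fecundity regresses back to the configured slope", {
  cfg <- sim_config()
  cfg$phenotypes$sites$n <- rep(300L, nrow(cfg$phenotypes$sites))
  ph <- gen_phenotypes(cfg, seed = 13)
  fem <- ph[!is.na(ph$fecundity) & ph$fecundity > 0, ]
  fit <- lm(fecundity ~ centroid_size, data = fem)
  beta <- coef(summary(fit))["centroid_size", ]
  expect_lt(abs(beta["Estimate"] - cfg$phenotypes$fecundity_slope),
            2 * beta["Std. Error"] + 0.35)
})

test_that("degenerate phenotype configs behave as configured", {
  cfg <- sim_config()
  cfg$phenotypes$size_sd <- 1e-12
  cfg$phenotypes$size_mean <- list(lake = c(70, 70, 70),
                                   stream = c(70, 70, 70))
  ph <- gen_phenotypes(cfg, seed = 17)
  expect_equal(stat_mean_diff(ph$centroid_size, ph$habitat), 0,
               tolerance = 1e-6)
  cfg2 <- sim_config()
  cfg2$phenotypes$age_probs$lake <- c(0.5, 0.4, 0.2)  # sums to 1.1
  expect_error(gen_phenotypes(cfg2, seed = 1), "probability vector")
})

test_that("landmark generator hits the target centroid size exactly and scales", {
  cfg <- sim_config()
  sets <- gen_landmarks(cfg, target_cs = c(10, 20), seed = 3)
  expect_equal(centroid_size(sets[[1]]), 10, tolerance = 1e-9)
  expect_equal(centroid_size(sets[[2]]), 20, tolerance = 1e-9)
  expect_error(gen_landmarks(cfg, target_cs = -1), "target_cs")
  # with noise, CS is close to target on average
  cfg$landmarks$noise_sd <- 0.5
  noisy <- gen_landmarks(cfg, target_cs = rep(50, 200), seed = 7)
  cs <- vapply(noisy, centroid_size, numeric(1))
  expect_equal(mean(cs), 50, tolerance = 0.5)
})

test_that("island-model genotypes recover their F parameter and limits", {
  # panmixia limit
  set.seed(19)
  th0 <- replicate(20, {
    g <- rand_genotype_pair(n_per_pop = 25, n_loci = 8, k_alleles = 10,
                            fst = 1e-6, seed = sample.int(1e6, 1))
    wc_theta_pair(g, "POP_1", "POP_2")$theta
  })
  expect_lt(abs(mean(th0)), 0.01)
  # missing-call rate lands in its binomial band
  cfg <- sim_config(microsats = list(n_pops = 2L, n_ind = 100L,
                                     missing_rate = 0.05))
  g <- gen_microsats(cfg, seed = 23)
  rate <- mean(is.na(g$a1))
  expect_lt(abs(rate - 0.05), 3 * sqrt(0.05 * 0.95 / length(g$a1)))
  expect_error(gen_microsats(sim_config(microsats = list(fst = 1.2))),
               "F must be")
})

test_that("dloop generator constructs the configured haplotype/SNP structure", {
  # star with n_hap = n_snp + 1: every branch one substitution, all MST
  # edges weight 1
  cfg <- sim_config(dloop = list(n_hap = 7L, n_snp = 6L, pops = "P1",
                                 n_seq = 300L,
                                 hap_freqs = matrix(rep(1 / 7, 7), 1)))
  a <- gen_dloop(cfg, seed = 29)
  tab <- collapse_haplotypes(a)
  expect_lte(length(tab$haplotypes), 7)
  expect_equal(length(tab$snp_positions), 6)
  net <- mst_network(tab)
  expect_true(all(net$edges$distance == 1))

  # single haplotype at frequency 1
  cfg1 <- sim_config(dloop = list(n_hap = 1L, n_snp = 6L, pops = "P1",
                                  n_seq = 10L,
                                  hap_freqs = matrix(1, 1, 1)))
  a1 <- gen_dloop(cfg1, seed = 31)
  t1 <- collapse_haplotypes(a1)
  expect_length(t1$haplotypes, 1)
  expect_length(t1$snp_positions, 0)

  # study defaults: 5 haplotypes spanning 6 segregating sites, one
  # haplotype predominant basin-wide
  a5 <- gen_dloop(sim_config(), seed = 37)
  t5 <- collapse_haplotypes(a5)
  expect_length(t5$haplotypes, 5)
  expect_length(t5$snp_positions, 6)
  expect_gt(max(rowSums(t5$counts)) / sum(t5$counts), 0.5)
  expect_equal(sum(t5$counts), 256)
})

test_that("haplotype sampling frequencies land in multinomial bands", {
  cfg <- sim_config(dloop = list(n_hap = 3L, n_snp = 2L, pops = "P1",
                                 n_seq = 256L,
                                 hap_freqs = matrix(c(0.5, 0.3, 0.2), 1)))
  a <- gen_dloop(cfg, seed = 41)
  tab <- collapse_haplotypes(a)
  props <- sort(rowSums(tab$counts) / 256, decreasing = TRUE)
  targets <- c(0.5, 0.3, 0.2)
  for (i in seq_along(props))
    expect_lt(abs(props[i] - targets[i]),
              2.576 * sqrt(targets[i] * (1 - targets[i]) / 256))
})

test_that("diet generator respects zero classes and recovers site means", {
  cfg <- sim_config()
  cfg$diet$n_ind <- c(lake_offshore = 400L, lake_littoral = 5L, stream = 5L)
  d <- gen_diet(cfg, seed = 43)
  off <- d[d$site == "lake_offshore", cfg$diet$classes]
  # zero-weight classes never sampled
  expect_true(all(off$benthic_cladocera == 0))
  expect_true(all(off$stickleback_eggs == 0))
  # mean proportions recover the configured means
  props <- as.matrix(off) / rowSums(off)
  props <- props[is.finite(rowSums(props)), ]
  expect_equal(unname(colMeans(props)[1:2]), c(0.34, 0.66),
               tolerance = 0.05)
})

test_that("generator output passes the matching reader round trip", {
  # the io round trips are covered in the io tests; here only the
  # config-validation failure modes
  expect_error(gen_dloop(sim_config(dloop = list(n_snp = 400L))), "n_snp")
  cfg <- sim_config()
  cfg$dloop$hap_freqs <- matrix(1, 2, 5)
  expect_error(gen_dloop(cfg), "pops x n_hap|probability")
})
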