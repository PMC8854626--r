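test_that("generated architectures have the requested geometry, reproducibly", {
  arch <- gen_architecture(n_regions = 23, seed = 1)
  expect_equal(sum(arch$segments$kind == "collagenous"), 23)
  expect_equal(sum(arch$segments$kind == "interruption"), 22)
  expect_equal(arch$segments$kind[1], "amino_terminus")
  expect_equal(arch$segments$kind[nrow(arch$segments)], "carboxyl_terminus")
  expect_identical(gen_architecture(n_regions = 23, seed = 1)$segments,
                   arch$segments)
  expect_error(gen_architecture(triplet_range = c(0, 0)), class = "config_error")
})

test_that("generated CDS translates Gly exactly at the Gly slots with no stops", {
  arch <- gen_architecture(n_regions = 5, seed = 3)
  cds <- gen_cds(arch, seed = 4)
  expect_equal(nchar(cds), 3 * arch$length)
  expect_identical(gen_cds(arch, seed = 4), cds)
  code <- col4gly:::GENETIC_CODE_TABLE
  codons <- substring(cds, seq(1, nchar(cds), 3), seq(3, nchar(cds), 3))
  aa <- unname(code[codons])
  expect_false(any(aa == "*"))
  gly <- gly_positions(arch)$residue
  expect_true(all(aa[gly] == "G"))
  expect_false(any(aa[-gly] == "G"))
})

test_that("registry generation embeds the proportional-hazards ground truth", {
  arch <- gen_architecture(seed = 2)
  reg <- gen_registry(arch, n_families = 100, seed = 5)
  expect_identical(gen_registry(arch, n_families = 100, seed = 5), reg)
  # one variant/feature vector per family; 1-3 males each
  per_fam <- table(reg$family_id)
  expect_true(all(per_fam >= 1 & per_fam <= 3))
  expect_true(all(tapply(reg$protein_hgvs, reg$family_id,
                         function(x) length(unique(x))) == 1))
  # null model: log-rank rejects at about the nominal level
  null_reg <- gen_registry(arch, n_families = 120,
                           log_hr = c(is_carboxyl_block = 0, is_nc_boundary = 0,
                                      is_high_destab = 0), seed = 6)
  obs <- build_family_observations(null_reg, "kidney",
                                   covariates = "is_high_destab")
  p <- logrank_test(obs$is_high_destab, obs)$p
  expect_gt(p, 0.001)  # a null draw should rarely be extreme
  # boundary log-HR recovered in sign and rough magnitude
  reg2 <- gen_registry(arch, n_families = 300,
                       log_hr = c(is_carboxyl_block = 0, is_nc_boundary = -0.8,
                                  is_high_destab = 0), seed = 7)
  obs2 <- build_family_observations(reg2, "kidney", covariates = "is_nc_boundary")
  fit <- cox_fit(obs2, "is_nc_boundary")
  expect_lt(abs(fit$terms$coef[1] + 0.8), 0.3)
})

test_that("cohort generation matches its logistic model prevalence", {
  arch <- gen_architecture(seed = 2)
  coh <- gen_cohort(arch, n = 3000, seed = 8)
  expect_identical(gen_cohort(arch, n = 3000, seed = 8), coh)
  # model-implied mean prevalence vs observed
  eta <- -2.41 + coh$is_carboxyl_block * 0.24 + coh$is_nc_boundary * (-1.25) +
    coh$is_high_destab * 0.94
  expect_lt(abs(mean(coh$outcome) - mean(plogis(eta))), 0.03)
  # flat model anchored at the observed marginal prevalence
  coh0 <- gen_cohort(arch, n = 3000, intercept = qlogis(0.158),
                     coef = c(is_carboxyl_block = 0, is_nc_boundary = 0,
                              is_high_destab = 0), seed = 9)
  expect_lt(abs(mean(coh0$outcome) - 0.158), 0.03)
})

test_that("allele tables sample variants at the rate-implied boundary fraction", {
  arch <- col4a5_like_arch()
  cds <- gen_cds(arch, seed = 11)
  uni <- make_rate_table(1, 1)
  snvs <- enumerate_gly_missense(arch, cds, uni)
  frac <- mean(snvs$position_class == "nc_boundary")
  # large sample of sites converges to the SNV boundary fraction
  tab <- gen_allele_table(arch, cds, uni, n_variants = 2000, seed = 12)
  expect_identical(gen_allele_table(arch, cds, uni, n_variants = 2000, seed = 12),
                   tab)
  obs_frac <- mean(tab$position_class == "nc_boundary")
  expect_lt(abs(obs_frac - frac), 0.02)
  expect_true(all(tab$hem >= 0 & tab$het >= 0 & tab$hom >= 0))
  expect_error(gen_allele_table(arch, cds, uni, n_variants = 1e6),
               class = "config_error")
})

test_that("binomial p-values are roughly uniform under the null sampling model", {
  arch <- col4a5_like_arch()
  cds <- gen_cds(arch, seed = 11)
  uni <- make_rate_table(1, 1)
  snvs <- enumerate_gly_missense(arch, cds, uni)
  p_true <- mean(snvs$position_class == "nc_boundary")
  ks_draws <- vapply(1:200, function(r) {
    tab <- gen_allele_table(arch, cds, uni, n_variants = 45, seed = 3000 + r)
    k <- sum(tab$position_class == "nc_boundary")
    p <- exact_binomial(k, 45, p_true, "greater")
    # randomized PIT: exact one-sided p-values of a discrete test are
    # uniform only after subtracting a uniform share of the atom at k
    set.seed(7000 + r)
    p - runif(1) * dbinom(k, 45, p_true)
  }, numeric(1))
  ks <- ks.test(ks_draws, "punif")
  expect_gt(ks$p.value, 0.01)
})

test_that("splice training windows follow the declared weight matrix", {
  tr <- gen_splice_training(n = 5000, seed = 13)
  expect_identical(gen_splice_training(n = 5000, seed = 13)$windows, tr$windows)
  m <- train_maxent("donor_5prime", tr$windows)
  marg <- col4gly:::chain_pair_marginals(m$factors)
  pos1 <- rowSums(marg[[1]])
  expect_lt(max(abs(pos1 - tr$pwm[, 1])), 0.02)
  posL <- colSums(marg[[length(marg)]])
  expect_lt(max(abs(posL - tr$pwm[, 9])), 0.02)
  # uniform matrix: scores hover near zero
  upwm <- matrix(0.25, 4, 9)
  tru <- gen_splice_training(n = 4000, pwm = upwm, seed = 14)
  mu <- train_maxent("donor_5prime", tru$windows)
  set.seed(15)
  w <- replicate(50, paste(sample(c("A", "C", "G", "T"), 9, TRUE), collapse = ""))
  s <- vapply(w, function(x) score_site(mu, x), numeric(1))
  expect_lt(max(abs(s)), 0.5)
})
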