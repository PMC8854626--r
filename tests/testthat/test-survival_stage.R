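test_that("endpoint keyword filters keep matching records only", {
  rec <- data.frame(
    family_id = c("A", "B", "C", "D"),
    phenotype_text = c("ESRD at 25", "Sensorineural deafness",
                       "isolated haematuria", "renal transplant age 31"),
    stringsAsFactors = FALSE)
  expect_equal(phenotype_keyword_filter(rec, "kidney")$family_id, c("A", "D"))
  expect_equal(phenotype_keyword_filter(rec, "hearing")$family_id, "B")
  expect_error(phenotype_keyword_filter(rec, "ocular"), class = "domain_error")
})

test_that("family aggregation follows mean / midpoint / censoring rules", {
  two_events <- data.frame(family_id = "F1", sex = "M",
                           event_age = c(20, 30), event_age_low = NA,
                           event_age_high = NA, last_seen_age = NA)
  o <- aggregate_family(two_events)
  expect_equal(o$time, 25); expect_true(o$event)

  range_only <- data.frame(family_id = "F2", sex = "M", event_age = NA,
                           event_age_low = 20, event_age_high = 30,
                           last_seen_age = NA)
  o <- aggregate_family(range_only)
  expect_equal(o$time, 25); expect_true(o$event)

  censored <- data.frame(family_id = "F3", sex = "M", event_age = NA,
                         event_age_low = NA, event_age_high = NA,
                         last_seen_age = 40)
  o <- aggregate_family(censored)
  expect_equal(o$time, 40); expect_false(o$event)

  # censored at the MAX last-seen age across males
  two_cens <- data.frame(family_id = "F4", sex = "M", event_age = NA,
                         event_age_low = NA, event_age_high = NA,
                         last_seen_age = c(35, 48))
  expect_equal(aggregate_family(two_cens)$time, 48)

  females <- data.frame(family_id = "F5", sex = "F", event_age = 30,
                        event_age_low = NA, event_age_high = NA,
                        last_seen_age = NA)
  expect_error(aggregate_family(females), class = "extraction_error")
  no_age <- data.frame(family_id = "F6", sex = "M", event_age = NA,
                       event_age_low = NA, event_age_high = NA,
                       last_seen_age = NA)
  expect_error(aggregate_family(no_age), class = "extraction_error")
})

test_that("KM estimates match the hand product-limit oracle", {
  # single event
  one <- data.frame(time = 26, event = TRUE)
  expect_equal(km_fit(one)$median, 26)

  # hand-computed three-point curve
  three <- data.frame(time = c(10, 20, 30), event = c(TRUE, FALSE, TRUE))
  km <- km_fit(three)
  expect_equal(km$survival[km$times == 10], 2 / 3)
  expect_equal(km$survival[km$times == 30], 0)
  expect_equal(km$median, 30)

  # random small sets against the oracle
  set.seed(13)
  for (i in 1:20) {
    n <- sample(3:10, 1)
    t <- sample(1:50, n)
    e <- runif(n) < 0.7
    if (!any(e)) e[1] <- TRUE
    km <- km_fit(data.frame(time = t, event = e))
    orc <- oracle_km(t, e)
    expect_equal(km$survival[match(orc$times, km$times)], orc$surv,
                 tolerance = 1e-12)
  }

  expect_error(km_fit(data.frame(time = c(-1, 3), event = c(TRUE, TRUE))),
               class = "input_error")
})

test_that("KM curves are monotone in [0,1] and recover an exponential median", {
  set.seed(19)
  t <- rexp(500, log(2) / 26)
  km <- km_fit(data.frame(time = t, event = TRUE))
  expect_true(all(diff(km$survival) <= 1e-12))
  expect_true(all(km$survival >= 0 & km$survival <= 1))
  expect_gte(km$median, 24); expect_lte(km$median, 28)

  # no censoring: KM median equals the sample median (odd n)
  for (i in 1:10) {
    n <- sample(c(5, 7, 9, 11), 1)
    t <- sample(1:100, n)
    km <- km_fit(data.frame(time = t, event = TRUE))
    expect_equal(km$median, median(t))
  }
})

test_that("log-rank statistic behaves under identity and matches Cox score test", {
  set.seed(23)
  obs <- data.frame(time = rexp(40, 0.05), event = rep(TRUE, 40))
  both <- rbind(obs, obs)
  g <- rep(c("a", "b"), each = 40)
  # identical groups: statistic 0 (identical sets tie at every event time;
  # observed equals expected by symmetry)
  lr <- logrank_test(g, both)
  expect_equal(lr$chisq, 0, tolerance = 1e-10)
  expect_equal(lr$p, 1, tolerance = 1e-10)

  # equality with the Cox score test in the absence of ties
  obs2 <- data.frame(time = c(rexp(30, 0.04), rexp(30, 0.08)),
                     event = TRUE, x = rep(0:1, each = 30))
  lr2 <- logrank_test(obs2$x, obs2)
  sc <- summary(survival::coxph(survival::Surv(time, event) ~ x,
                                data = obs2))$sctest
  expect_equal(lr2$chisq, unname(sc["test"]), tolerance = 1e-6)

  expect_error(logrank_test(rep("a", 40), obs), class = "input_error")
})

test_that("Cox fit recovers a known log hazard ratio and flags degenerate input", {
  arch <- gen_architecture(seed = 2)
  # single-draw estimates at n=150 carry ~0.2 sampling error, so recovery
  # is asserted on the mean over five replicate registries
  fits <- lapply(31:35, function(s) {
    reg <- gen_registry(arch, n_families = 150,
                        log_hr = c(is_carboxyl_block = 0, is_nc_boundary = 0,
                                   is_high_destab = 0.7), seed = s)
    obs <- build_family_observations(reg, "kidney",
                                     covariates = c("is_high_destab"))
    cox_fit(obs, "is_high_destab")
  })
  coefs <- vapply(fits, function(f) f$terms$coef[1], numeric(1))
  expect_lt(abs(mean(coefs) - 0.7), 0.3)
  fit <- fits[[1]]
  expect_lt(fit$terms$ci_low[1], fit$terms$hr[1])
  expect_lt(fit$terms$hr[1], fit$terms$ci_high[1])
  expect_gt(fit$terms$hr[1], 0)

  reg <- gen_registry(arch, n_families = 60, seed = 31)
  obs <- build_family_observations(reg, "kidney",
                                   covariates = "is_high_destab")

  obs$flat <- 1
  expect_error(cox_fit(obs, "flat"), class = "degenerate_covariate_error")
  few <- data.frame(time = c(5, 10), event = c(TRUE, FALSE), x = c(0, 1))
  expect_error(cox_fit(few, "x"), class = "input_error")
})

test_that("local-region subgroup drops boundary families and swaps covariates", {
  arch <- gen_architecture(seed = 2)
  reg <- gen_registry(arch, n_families = 120, seed = 43)
  obs <- build_family_observations(reg, "kidney",
                                   covariates = c("is_carboxyl_block", "is_nc_boundary",
                                                  "is_high_destab", "position_class"))
  sub <- survival_subgroup_local_region(obs)
  expect_false(any(sub$observations$position_class == "nc_boundary"))
  expect_equal(sub$covariates, c("amino_end", "carboxyl_end"))
  # aggregation untouched: times/events of retained families identical
  keep <- obs$position_class != "nc_boundary"
  expect_equal(sub$observations$time, obs$time[keep])
  expect_equal(sub$observations$event, obs$event[keep])
})

test_that("registry extraction reconciles counts and respects exclusions", {
  arch <- gen_architecture(seed = 2)
  reg <- gen_registry(arch, n_families = 80, seed = 53)
  # plant a multi-variant carrier family and a female-only family
  reg$n_variants[reg$family_id == reg$family_id[1]] <- 2L
  fem <- reg[reg$family_id == "FAM0002", ]
  fem$sex <- "F"
  reg <- rbind(reg[reg$family_id != "FAM0002", ], fem)
  obs <- build_family_observations(reg, "kidney")
  exc <- attr(obs, "exclusions")
  expect_equal(unname(exc["analyzed_families"]), nrow(obs))
  expect_gte(unname(exc["multi_variant"]), 1)
  expect_equal(unname(exc["female_only"]), 1)
  expect_false("FAM0001" %in% obs$family_id)
  expect_false("FAM0002" %in% obs$family_id)
})
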