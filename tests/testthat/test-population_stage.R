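test_that("context rates look up correctly and respect the transition ratio", {
  uni <- make_rate_table(titv = 1, cpg_multiplier = 1)
  expect_equal(context_rate(uni, "A", "G", "A", "T"), 1)
  k4 <- make_rate_table(titv = 4, cpg_multiplier = 1)
  expect_equal(context_rate(k4, "A", "G", "A", "T"),
               4 * context_rate(k4, "A", "G", "T", "T"))
  # CpG transition boost on both strand representations
  cpg <- make_rate_table(titv = 4, cpg_multiplier = 10)
  expect_equal(context_rate(cpg, "C", "G", "A", "T"), 40)
  expect_equal(context_rate(cpg, "A", "C", "T", "G"), 40)
  expect_error(context_rate(uni, "A", "G", "G", "T"), class = "input_error")
  expect_equal(nrow(uni), 12 * 16)
  expect_true(all(uni$rate > 0))
})

test_that("rate tables round-trip and strand-symmetrize on load", {
  path <- tempfile(fileext = ".tsv")
  rt <- make_rate_table(titv = 3, cpg_multiplier = 8)
  write_rate_table(rt, path, stranded = TRUE)
  rt2 <- read_rate_table(path)
  expect_equal(context_rate(rt2, "C", "G", "A", "A"),
               context_rate(rt, "C", "G", "A", "A"))
  # asymmetric stranded table symmetrizes when the directive is absent
  asym <- rt
  i <- with(asym, left == "A" & ref == "G" & alt == "A" & right == "T")
  j <- with(asym, left == "A" & ref == "C" & alt == "T" & right == "T")  # revcomp
  asym$rate[i] <- 10; asym$rate[j] <- 2
  write_rate_table(asym, path, stranded = FALSE)
  sym <- read_rate_table(path)
  expect_equal(context_rate(sym, "A", "G", "A", "T"), 6)
  expect_equal(context_rate(sym, "A", "C", "T", "T"), 6)
})

test_that("expected boundary fraction: toy value, scale invariance, uniform count fraction", {
  # 10-Gly single region, 2 boundary, all codons GGT, uniform rates -> 0.2
  arch <- toy_arch()
  seqv <- rep("GAT", 50)                      # Asp filler
  seqv[1] <- "ATG"
  gly <- gly_positions(arch)$residue
  seqv[gly] <- "GGT"
  xaa_yaa <- setdiff(11:40, gly)
  seqv[xaa_yaa] <- "CCT"                      # Pro at Xaa/Yaa
  cds <- paste(seqv, collapse = "")
  uni <- make_rate_table(1, 1)
  expect_equal(expected_boundary_fraction(arch, cds, uni), 0.2)

  # global rescale leaves the ratio unchanged
  x7 <- uni; x7$rate <- x7$rate * 7
  expect_equal(expected_boundary_fraction(arch, cds, x7), 0.2)

  # CDS/architecture mismatch
  expect_error(expected_boundary_fraction(arch, substr(cds, 1, 30), uni),
               class = "consistency_error")
})

test_that("expected fraction matches the exhaustive enumeration oracle on toys", {
  set.seed(103)
  rt <- make_rate_table(titv = 4, cpg_multiplier = 10)
  uni <- make_rate_table(1, 1)
  for (i in 1:6) {
    arch <- random_arch(n_regions = sample(2:4, 1))
    if (3 * arch$length > 300) next
    cds <- gen_cds(arch, seed = i)
    for (tab in list(uni, rt)) {
      expect_equal(expected_boundary_fraction(arch, cds, tab),
                   oracle_expected_fraction(arch, cds, tab),
                   tolerance = 1e-12)
    }
    f <- expected_boundary_fraction(arch, cds, rt)
    expect_gte(f, 0); expect_lte(f, 1)
  }
})

test_that("exact binomial matches direct pmf summation and tail identities", {
  # reference points
  expect_lt(exact_binomial(15, 45, 0.101, "greater"), 0.001)
  expect_equal(exact_binomial(1, 1, 0.5, "greater"), 0.5)
  expect_equal(exact_binomial(0, 20, 0.3, "greater"), 1.0)
  expect_error(exact_binomial(3, 5, 1.2), class = "domain_error")
  expect_error(exact_binomial(6, 5, 0.5), class = "domain_error")

  set.seed(107)
  for (i in 1:30) {
    n <- sample(1:1000, 1)
    k <- sample(0:n, 1)
    p0 <- runif(1, 0.01, 0.99)
    expect_equal(exact_binomial(k, n, p0, "greater"),
                 min(1, oracle_binom_tail(k, n, p0, upper = TRUE)),
                 tolerance = 1e-12)
    expect_equal(exact_binomial(k, n, p0, "less"),
                 min(1, oracle_binom_tail(k, n, p0, upper = FALSE)),
                 tolerance = 1e-12)
    # tail-complement identity: P(X>=k) + P(X<=k) = 1 + P(X=k)
    expect_equal(exact_binomial(k, n, p0, "greater") +
                   exact_binomial(k, n, p0, "less"),
                 1 + dbinom(k, n, p0), tolerance = 1e-12)
  }

  # two-sided agrees with stats::binom.test
  for (i in 1:10) {
    n <- sample(5:200, 1); k <- sample(0:n, 1); p0 <- runif(1, 0.05, 0.95)
    expect_equal(exact_binomial(k, n, p0, "two_sided"),
                 binom.test(k, n, p0)$p.value, tolerance = 1e-9)
  }
})

test_that("allele totals use X-linked counting and are additive", {
  expect_equal(allele_total(249, 442, 7), 705L)
  expect_equal(allele_total(4, 3, 0), 7L)
  expect_equal(allele_total(0, 0, 0), 0L)
  expect_error(allele_total(-1, 0, 0), class = "domain_error")
  set.seed(109)
  for (i in 1:20) {
    a <- sample(0:500, 3)
    expect_equal(allele_total(a[1], a[2], a[3]),
                 allele_total(a[1], 0, 0) + allele_total(0, a[2], 0) +
                   allele_total(0, 0, a[3]))
  }
})

test_that("carrier prevalence counts individuals once and validates totals", {
  r <- data.frame(hem = 2, het = 3, hom = 1)
  pv <- carrier_prevalence(r, 1000, 1000)
  expect_equal(pv$prevalence, 6 / 2000)
  expect_equal(pv$one_in, 333)
  expect_equal(carrier_prevalence(data.frame(hem = integer(0), het = integer(0),
                                             hom = integer(0)), 10, 10)$prevalence, 0)
  big <- data.frame(hem = 30, het = 0, hom = 0)
  expect_error(carrier_prevalence(big, 10, 10), class = "consistency_error")
  expect_error(carrier_prevalence(r, 0, 10), class = "domain_error")
})
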