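test_that("observed heterozygosity counts differing allele pairs", {
  # all homozygous -> 0; half the loci heterozygous -> 0.5
  gt0 <- make_toy_genotypes(c("0/0 1/1 0/0 1/1", "1/1 0/0 1/1 0/0"))
  expect_equal(observed_heterozygosity(gt0), 0)
  gt1 <- make_toy_genotypes("0/1 1/1 0/1 0/0")
  expect_equal(observed_heterozygosity(gt1), 0.5)
  # founding population at p = 0.1 sits near 2p(1-p)
  spec <- genome_spec(n_neutral = 500, n_migrant = 5, n_conserved = 5,
                      maf_recipient = c(0.1, 0.1), maf_source = c(0.1, 0.1))
  f <- draw_founding_frequencies(spec, seed = 60)
  pop <- initialize_population(spec, "recipient", 400, f, seed = 61)
  expect_lt(abs(observed_heterozygosity(pop) - 0.18),
            4 * sqrt(0.18 * 0.82 / (400 * 500)))
  # population and genotype_table code paths agree exactly
  expect_equal(observed_heterozygosity(pop),
               observed_heterozygosity(genotypes(pop)))
})

test_that("expected heterozygosity is multi-state gene diversity", {
  gt <- make_toy_genotypes(c("0/0 0/0", "0/0 0/0"))
  expect_equal(expected_heterozygosity(gt), 0)
  # one locus at p = 0.5 among 2 loci: mean(0.5, 0) = 0.25
  gt2 <- make_toy_genotypes(c("0/1 0/0", "1/0 0/0"))
  expect_equal(expected_heterozygosity(gt2), 0.25)
  # He ~ Ho at HWE founding
  spec <- genome_spec(n_neutral = 400, n_migrant = 5, n_conserved = 5)
  f <- draw_founding_frequencies(spec, seed = 62)
  pop <- initialize_population(spec, "recipient", 500, f, seed = 63)
  expect_lt(abs(expected_heterozygosity(pop) - observed_heterozygosity(pop)),
            0.01)
})

test_that("migrant ancestry is the source-diagnostic allele fraction", {
  cls <- c("neutral", "migrant", "migrant")
  none <- make_toy_genotypes(c("0/1 0/0 0/0", "1/1 0/0 0/0"), cls)
  expect_equal(migrant_ancestry(none), 0)
  full <- make_toy_genotypes(c("0/1 1/1 1/1", "1/1 1/1 1/1"), cls)
  expect_equal(migrant_ancestry(full), 1)
  f1 <- make_toy_genotypes("0/0 0/1 1/0", cls)  # F1 migrant x resident
  expect_equal(migrant_ancestry(f1), 0.5)
  # invariant under permuting individuals and loci
  set.seed(64)
  tab <- random_toy_table(12, 8, seed = 65, states = 0:1)
  base <- migrant_ancestry(
    make_toy_genotypes(list(A1 = tab$A1, A2 = tab$A2),
                       rep(c("neutral", "migrant"), each = 4)))
  for (i in 1:5) {
    ind <- sample(12)
    loc <- c(sample(4), 4 + sample(4))
    perm <- make_toy_genotypes(list(A1 = tab$A1[ind, loc],
                                    A2 = tab$A2[ind, loc]),
                               rep(c("neutral", "migrant"), each = 4))
    expect_equal(migrant_ancestry(perm), base)
  }
})

test_that("F_IS matches the brute-force Nei oracle to 10 significant figures", {
  # hand-built 4-individual, 2-locus table
  toy <- make_toy_genotypes(c("0/1 0/0", "0/0 0/1", "1/1 0/0", "0/1 0/0"))
  expect_equal(f_is(toy), nei_fis_oracle(toy$A1, toy$A2), tolerance = 1e-12)
  # random tables, including three-state loci
  for (s in 1:8) {
    tab <- random_toy_table(10, 5, seed = 100 + s)
    got <- f_is(tab, loci = "all")
    want <- nei_fis_oracle(tab$A1, tab$A2)
    expect_equal(got, want, tolerance = 1e-10)
  }
  # fully homozygous polymorphic table -> 1; all-heterozygote table -> < 0
  hom <- make_toy_genotypes(c("0/0", "1/1"))
  expect_equal(f_is(hom), 1)
  het <- make_toy_genotypes(c("0/1", "0/1", "1/0"))
  expect_lt(f_is(het), 0)
  # a large random-mating population sits near zero
  spec <- genome_spec(n_neutral = 300, n_migrant = 5, n_conserved = 5)
  f <- draw_founding_frequencies(spec, seed = 66)
  pop <- initialize_population(spec, "recipient", 800, f, seed = 67)
  expect_lt(abs(f_is(pop)), 0.02)
  # monomorphic-only input is undefined
  expect_true(is.na(f_is(make_toy_genotypes(c("0/0", "0/0")))))
})

test_that("F_ST matches the brute-force Weir-Cockerham oracle", {
  for (s in 1:8) {
    x <- random_toy_table(8, 5, seed = 200 + s)
    y <- random_toy_table(10, 5, seed = 300 + s,
                          prob = c(0.3, 0.5, 0.2))
    got <- f_st(x, y, loci = "all")
    want <- wc_theta_oracle(x$A1, x$A2, y$A1, y$A2)
    expect_equal(got, want, tolerance = 1e-10)
  }
})

test_that("F_ST is symmetric, null at identity, one at fixed differences", {
  x <- random_toy_table(12, 6, seed = 70)
  y <- random_toy_table(12, 6, seed = 71)
  expect_equal(f_st(x, y, loci = "all"), f_st(y, x, loci = "all"),
               tolerance = 1e-12)
  # theta of a sample against itself carries only the O(1/n) finite-sample
  # correction (identical samples look "too similar"); it vanishes at the
  # sample sizes the simulator monitors
  big <- random_toy_table(400, 6, seed = 70)
  expect_lt(abs(f_st(big, big, loci = "all")), 2 / 400)
  spec <- genome_spec(n_neutral = 2, n_migrant = 2, n_conserved = 2)
  a <- genotype_table(matrix(0L, 6, 6), matrix(0L, 6, 6), spec)
  b <- genotype_table(matrix(1L, 6, 6), matrix(1L, 6, 6), spec)
  expect_equal(f_st(a, b, loci = "all"), 1)
  expect_true(is.na(f_st(a, a, loci = "all")))  # nothing polymorphic
  expect_error(f_st(make_toy_genotypes("0/1"), make_toy_genotypes("0/1")),
               "at least 2")
})

test_that("founding source-recipient divergence sits at the analytic value", {
  # 100 fixed-difference diagnostic loci against ~1000 shared-frequency
  # neutral loci give theta ~ 0.357 by the ratio of sums
  spec <- genome_spec()
  f <- draw_founding_frequencies(spec, seed = 72)
  rec <- initialize_population(spec, "recipient", 1000, f, seed = 73,
                               track_lrs = FALSE)
  src <- initialize_population(spec, "source", 1000, f, seed = 74,
                               track_lrs = FALSE)
  theta <- f_st(rec, src)
  expect_lt(abs(theta - 0.357), 0.015)
})

test_that("yearly metrics assemble and flag degenerate populations", {
  pop <- small_population(n = 30, seed = 75)
  m <- yearly_metrics(pop, year = 3)
  expect_equal(m$census, 30L)
  expect_true(m$ho_neutral >= 0 && m$ho_neutral <= 1)
  expect_false(m$extirpated)
  expect_equal(m$births, 0L)
  # all-male remnant: sex ratio undefined
  rows <- alive_rows(pop)
  pop$sex[rows] <- 2L
  expect_true(is.na(yearly_metrics(pop, year = 4)$sex_ratio))
  # extirpated population reports missing metrics
  pop$extirpated <- TRUE
  m2 <- yearly_metrics(pop, year = 5)
  expect_true(m2$extirpated)
  expect_true(is.na(m2$ho_neutral))
})

test_that("replicate summaries give central 84% bands over extant runs", {
  # identical replicates: zero-width band equal to the mean
  base <- data.frame(year = 1:5, value = c(1, 2, 3, 4, 5),
                     extirpated = FALSE)
  s <- summarize_replicates(list(base, base, base))
  v <- s$summary[s$summary$metric == "value", ]
  expect_equal(v$mean, base$value)
  expect_equal(v$lower, v$mean)
  expect_equal(v$upper, v$mean)
  expect_true(all(is.na(s$extirpation_years)))
  # band always contains the mean; quantiles of normal draws ~ +/- 1.4
  set.seed(76)
  reps <- lapply(1:100, function(i)
    data.frame(year = 1:20, value = rnorm(20), extirpated = FALSE))
  s2 <- summarize_replicates(reps)
  v2 <- s2$summary[s2$summary$metric == "value", ]
  expect_true(all(v2$lower <= v2$mean & v2$mean <= v2$upper))
  expect_lt(abs(mean(v2$lower) + 1.405), 0.12)
  expect_lt(abs(mean(v2$upper) - 1.405), 0.12)
  # extirpated replicates drop out from their extirpation year onward
  cut <- base
  cut$extirpated <- c(FALSE, FALSE, TRUE, TRUE, TRUE)
  cut$value <- 100
  s3 <- summarize_replicates(list(base, base, cut))
  v3 <- s3$summary[s3$summary$metric == "value", ]
  expect_equal(v3$n_replicates, c(3L, 3L, 2L, 2L, 2L))
  expect_equal(v3$mean[3:5], base$value[3:5])
  expect_equal(unname(s3$extirpation_years), c(NA, NA, 3))
})

test_that("drift accumulates: divergence from the year-0 snapshot grows", {
  cfg <- make_mini_scenario("smoke")
  set.seed(77)
  fst_by_year <- sapply(1:6, function(i) {
    tab <- run_replicate(cfg, i)
    tab$fst_vs_recipient0[match(c(10, 35, 60), tab$year)]
  })
  means <- rowMeans(fst_by_year)
  expect_true(all(diff(means) > 0))
})
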