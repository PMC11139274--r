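test_that("genome spec enforces its invariants", {
  spec <- genome_spec()
  expect_equal(spec$n_loci, 1200L)
  expect_equal(spec$mu_conserved, spec$mu_neutral * spec$constraint_u)
  expect_equal(spec$mu_conserved, 4.84e-9)
  expect_length(spec$idx_neutral, 1000L)
  expect_error(genome_spec(n_neutral = 0), "positive")
  expect_error(genome_spec(maf_recipient = c(0.2, 0.1)), "lower bound")
  expect_error(genome_spec(maf_recipient = c(0, 0.1)), "bounds")
  expect_error(genome_spec(maf_recipient = c(0.3, 0.6)), "bounds")
})

test_that("founding frequencies respect the configured ranges", {
  spec <- genome_spec()
  f <- draw_founding_frequencies(spec, seed = 1)
  p <- f$p_alt[spec$idx_neutral, "recipient"]
  expect_true(all(p >= 0.05 & p <= 0.15))
  expect_true(f$shared)
  expect_identical(p, f$p_alt[spec$idx_neutral, "source"])
  # migrant-diagnostic loci fixed for alternate alleles, conserved invariant
  expect_true(all(f$p_alt[spec$idx_migrant, "recipient"] == 0))
  expect_true(all(f$p_alt[spec$idx_migrant, "source"] == 1))
  expect_true(all(f$p_alt[spec$idx_conserved, ] == 0))

  # degenerate point interval
  spec2 <- genome_spec(maf_recipient = c(0.1, 0.1), maf_source = c(0.1, 0.1))
  f2 <- draw_founding_frequencies(spec2, seed = 2)
  expect_true(all(f2$p_alt[spec2$idx_neutral, ] == 0.1))

  # mean of uniform draws on [0.40, 0.50] is ~0.45
  spec3 <- genome_spec(maf_recipient = c(0.40, 0.50),
                       maf_source = c(0.40, 0.50))
  f3 <- draw_founding_frequencies(spec3, seed = 3)
  se <- sqrt(0.1^2 / 12 / 1000)
  expect_lt(abs(mean(f3$p_alt[spec3$idx_neutral, "recipient"]) - 0.45), 4 * se)

  # differing ranges draw independently
  spec4 <- genome_spec(maf_source = c(0.40, 0.50))
  f4 <- draw_founding_frequencies(spec4, seed = 4)
  expect_false(f4$shared)
  expect_true(all(f4$p_alt[spec4$idx_neutral, "source"] >= 0.40))
  expect_true(all(f4$p_alt[spec4$idx_neutral, "recipient"] <= 0.15))
})

test_that("founder genotypes follow Hardy-Weinberg founding", {
  spec <- genome_spec(n_neutral = 200, n_migrant = 20, n_conserved = 20,
                      maf_recipient = c(0.1, 0.1), maf_source = c(0.1, 0.1))
  f <- draw_founding_frequencies(spec, seed = 5)
  gt <- init_genotypes(spec, 1000, "recipient", f, seed = 6)
  # p = 0.1 everywhere: per-individual neutral heterozygosity ~ 2p(1-p)
  ho <- observed_heterozygosity(gt)
  se <- sqrt(0.18 * 0.82 / (1000 * 200))
  expect_lt(abs(ho - 2 * 0.1 * 0.9), 4 * se)
  # diagnostic and conserved founding states
  expect_true(all(gt$A1[, spec$idx_migrant] == 0L))
  gt_src <- init_genotypes(spec, 50, "source", f, seed = 7)
  expect_true(all(gt_src$A1[, spec$idx_migrant] == 1L))
  expect_true(all(gt_src$A2[, spec$idx_migrant] == 1L))
  expect_true(all(gt$A1[, spec$idx_conserved] == 0L))
  # p = 0 at conserved loci: all founders homozygous reference
  expect_true(all(gt$A2[, spec$idx_conserved] == 0L))
})

test_that("mutation is Bernoulli per allele copy with class rates", {
  spec <- genome_spec(n_neutral = 50, n_migrant = 10, n_conserved = 10)
  f <- draw_founding_frequencies(spec, seed = 8)
  gt <- init_genotypes(spec, 20, "recipient", f, seed = 9)

  # mu = 0: unchanged
  spec0 <- genome_spec(n_neutral = 50, n_migrant = 10, n_conserved = 10,
                       mu_neutral = 0, constraint_u = 0)
  expect_identical(mutate_genotypes(gt, spec0, seed = 1)$A1, gt$A1)

  # mu = 1: every allele copy in every class becomes mutant
  spec1 <- genome_spec(n_neutral = 50, n_migrant = 10, n_conserved = 10,
                       mu_neutral = 1, constraint_u = 1)
  mut <- mutate_genotypes(gt, spec1, seed = 2)
  expect_true(all(mut$A1 == 2L) && all(mut$A2 == 2L))
  # and the input table was not modified (value semantics)
  expect_true(all(gt$A1[, spec$idx_conserved] == 0L))

  # realized counts match the Bernoulli expectation within 3 SE
  mu <- 5e-4
  specm <- genome_spec(n_neutral = 50, n_migrant = 10, n_conserved = 10,
                       mu_neutral = mu, constraint_u = 2.2)
  set.seed(10)
  n_slots_neutral <- 2 * 20 * 60   # neutral + migrant loci
  n_slots_cons <- 2 * 20 * 10
  reps <- 200
  counts <- replicate(reps, {
    m <- mutate_genotypes(gt, specm)
    c(neu = sum(m$A1[, 1:60] == 2L) + sum(m$A2[, 1:60] == 2L),
      con = sum(m$A1[, 61:70] == 2L) + sum(m$A2[, 61:70] == 2L))
  })
  exp_neu <- n_slots_neutral * mu
  se_neu <- sqrt(n_slots_neutral * mu * (1 - mu) / reps)
  expect_lt(abs(mean(counts["neu", ]) - exp_neu), 3 * se_neu)
  exp_con <- n_slots_cons * mu * 2.2
  se_con <- sqrt(n_slots_cons * mu * 2.2 / reps)
  expect_lt(abs(mean(counts["con", ]) - exp_con), 3 * se_con)
})

test_that("mutation is monotone: the mutant state is absorbing", {
  spec <- genome_spec(n_neutral = 30, n_migrant = 5, n_conserved = 5,
                      mu_neutral = 0.05, constraint_u = 2)
  f <- draw_founding_frequencies(spec, seed = 11)
  gt <- init_genotypes(spec, 15, "recipient", f, seed = 12)
  set.seed(13)
  total <- sum(gt$A1 == 2L) + sum(gt$A2 == 2L)
  for (i in 1:20) {
    gt <- mutate_genotypes(gt)
    new_total <- sum(gt$A1 == 2L) + sum(gt$A2 == 2L)
    expect_gte(new_total, total)
    total <- new_total
  }
})

test_that("deleterious counting requires homozygous-mutant conserved loci", {
  spec <- genome_spec(n_neutral = 2, n_migrant = 2, n_conserved = 3)
  base <- matrix(0L, 2, 7)
  gt <- genotype_table(base, base, spec)
  counts <- count_deleterious(gt)
  expect_equal(counts$mutations, c(0L, 0L))     # founders carry none
  expect_equal(counts$deleterious, c(0L, 0L))
  # one mutant copy at one conserved locus: 1 mutation, 0 deleterious
  a1 <- base; a1[1, 5] <- 2L
  gt1 <- genotype_table(a1, base, spec)
  expect_equal(count_deleterious(gt1)$mutations[1], 1L)
  expect_equal(count_deleterious(gt1)$deleterious[1], 0L)
  # two conserved loci homozygous mutant: 4 mutations, 2 deleterious
  a1 <- base; a1[1, c(5, 7)] <- 2L
  a2 <- base; a2[1, c(5, 7)] <- 2L
  gt2 <- genotype_table(a1, a2, spec)
  expect_equal(count_deleterious(gt2)$mutations[1], 4L)
  expect_equal(count_deleterious(gt2)$deleterious[1], 2L)
})

test_that("Mendelian transmission is fair and conserves fixed genotypes", {
  spec <- genome_spec(n_neutral = 1, n_migrant = 1, n_conserved = 1)
  aa <- matrix(c(0L, 0L, 0L), 1, 3)
  AA <- matrix(c(1L, 0L, 0L), 1, 3)
  # AA x AA -> AA; AA x aa -> Aa always
  gt_fix <- genotype_table(rbind(AA, AA), rbind(AA, AA), spec)
  off <- mendelian_offspring(gt_fix, 1, 2, mutate = FALSE, seed = 1)
  expect_equal(off$A1[1, 1], 1L)
  expect_equal(off$A2[1, 1], 1L)
  gt_cross <- genotype_table(rbind(AA, aa), rbind(AA, aa), spec)
  for (i in 1:10) {
    off <- mendelian_offspring(gt_cross, 1, 2, mutate = FALSE)
    expect_equal(sort(c(off$A1[1, 1], off$A2[1, 1])), c(0L, 1L))
  }
  # Aa x Aa segregates 1:2:1 (chi-square at n = 10^4)
  het <- genotype_table(rbind(c(1L, 0L, 0L), c(1L, 0L, 0L)),
                        rbind(c(0L, 0L, 0L), c(0L, 0L, 0L)), spec)
  set.seed(14)
  geno <- replicate(10000, {
    o <- mendelian_offspring(het, 1, 2, mutate = FALSE)
    o$A1[1, 1] + o$A2[1, 1]
  })
  obs <- tabulate(geno + 1L, nbins = 3)
  p <- suppressWarnings(chisq.test(obs, p = c(0.25, 0.5, 0.25)))$p.value
  expect_gt(p, 0.001)
})

test_that("diagnostic alleles are conserved under transmission", {
  # offspring's count of source-diagnostic alleles equals what it inherited
  spec <- genome_spec(n_neutral = 5, n_migrant = 10, n_conserved = 5,
                      mu_neutral = 0, constraint_u = 0)
  set.seed(15)
  for (case in 1:10) {
    A1 <- matrix(sample(0:1, 2 * 20, TRUE), 2, 20)
    A2 <- matrix(sample(0:1, 2 * 20, TRUE), 2, 20)
    gt <- genotype_table(A1, A2, spec)
    off <- mendelian_offspring(gt, 1, 2, mutate = FALSE)
    mig <- spec$idx_migrant
    for (l in mig) {
      inherited <- off$A1[1, l] + off$A2[1, l]
      from_a <- c(A1[1, l], A2[1, l])
      from_b <- c(A1[2, l], A2[2, l])
      expect_true(off$A1[1, l] %in% from_a)
      expect_true(off$A2[1, l] %in% from_b)
      expect_lte(inherited, any(from_a == 1) + any(from_b == 1))
      expect_gte(inherited, all(from_a == 1) + all(from_b == 1))
    }
  }
})
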