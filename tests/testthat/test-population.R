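test_that("founder populations start with the configured structure", {
  pop <- small_population(n = 300, seed = 20)
  expect_equal(population_size(pop), 300L)
  snap <- population_snapshot(pop)
  expect_true(all(snap$age >= 0 & snap$age <= 9))
  expect_true(all(snap$origin == "resident"))
  expect_error(initialize_population(genome_spec(), "recipient", 0,
                                     draw_founding_frequencies(genome_spec())),
               "positive")
})

test_that("founder sex assignment is a fair coin", {
  spec <- genome_spec(n_neutral = 5, n_migrant = 2, n_conserved = 2)
  f <- draw_founding_frequencies(spec, seed = 21)
  set.seed(22)
  fem <- replicate(60, {
    pop <- initialize_population(spec, "recipient", 200, f)
    sum(population_snapshot(pop)$sex == "female")
  })
  se <- sqrt(0.25 * 200 * 60) / 60
  expect_lt(abs(mean(fem) - 100), 4 * se)
})

test_that("aging advances live individuals and spares newborns", {
  pop <- small_population(n = 30, seed = 23)
  ages0 <- pop$age[alive_rows(pop)]
  age_population(pop)
  expect_equal(pop$age[alive_rows(pop)], ages0 + 1L)
  expect_equal(mean(pop$age[alive_rows(pop)]), mean(ages0) + 1)
})

test_that("age hazard is the age/lifespan quotient with a hard ceiling", {
  spec <- genome_spec(n_neutral = 4, n_migrant = 2, n_conserved = 2)
  f <- draw_founding_frequencies(spec, seed = 24)
  # deterministic removal at the lifespan
  pop <- initialize_population(spec, "recipient", 50, f, seed = 25)
  pop$age[alive_rows(pop)] <- 10L
  apply_age_mortality(pop)
  expect_equal(population_size(pop), 0L)
  # age 0 never dies of age
  pop0 <- initialize_population(spec, "recipient", 50, f, seed = 26)
  pop0$age[alive_rows(pop0)] <- 0L
  apply_age_mortality(pop0)
  expect_equal(population_size(pop0), 50L)
  # age 5 dies with probability ~0.5
  set.seed(27)
  surv <- replicate(100, {
    p <- initialize_population(spec, "recipient", 50, f)
    p$age[alive_rows(p)] <- 5L
    apply_age_mortality(p)
    population_size(p)
  })
  se <- sqrt(0.25 * 50 * 100) / 100
  expect_lt(abs(mean(surv) - 25), 4 * se)
})

test_that("mutation-load hazards are zero-cost at zero and increasing", {
  haz <- rescuesim:::.load_hazard
  expect_equal(haz(0), 0)
  expect_equal(haz(1), 0.5)
  expect_gt(haz(3), haz(1))
  # individuals without conserved mutations are never touched
  pop <- small_population(n = 50, seed = 28)
  apply_mutation_mortality(pop)
  expect_equal(population_size(pop), 50L)
})

test_that("mutation-cost mortality kills carriers at rate 1 - 1/(m+1)", {
  spec <- genome_spec(n_neutral = 4, n_migrant = 2, n_conserved = 4)
  f <- draw_founding_frequencies(spec, seed = 29)
  set.seed(30)
  alive_counts <- replicate(200, {
    pop <- initialize_population(spec, "recipient", 20, f)
    # plant exactly one mutant conserved copy in everyone (m = 1)
    rescuesim:::.set_cells(pop$G1, rep(spec$idx_conserved[1], 20),
                           alive_rows(pop), 2L)
    pop$has_mutants <- TRUE
    apply_mutation_mortality(pop)
    population_size(pop)
  })
  se <- sqrt(0.25 * 20 * 200) / 200
  expect_lt(abs(mean(alive_counts) - 10), 4 * se)
})

test_that("maturity viability fires once and credits matured offspring", {
  pop <- small_population(n = 40, seed = 31)
  idx <- alive_rows(pop)
  pop$age[idx] <- 1L
  pop$checked[idx] <- FALSE
  apply_maturity_viability(pop)
  expect_true(all(pop$checked[alive_rows(pop)]))
  expect_equal(population_size(pop), 40L)  # d = 0 for all founders
  # a deleterious (homozygous-mutant) carrier dies with probability 0.5
  spec <- pop$spec
  f <- draw_founding_frequencies(spec, seed = 32)
  set.seed(33)
  survived <- replicate(200, {
    p <- initialize_population(spec, "recipient", 10, f)
    rows <- alive_rows(p)
    p$age[rows] <- 1L
    p$checked[rows] <- FALSE
    rescuesim:::.set_cells(p$G1, rep(spec$idx_conserved[1], 10), rows, 2L)
    rescuesim:::.set_cells(p$G2, rep(spec$idx_conserved[1], 10), rows, 2L)
    p$has_mutants <- TRUE
    apply_maturity_viability(p)
    population_size(p)
  })
  se <- sqrt(0.25 * 10 * 200) / 200
  expect_lt(abs(mean(survived) - 5), 4 * se)
})

test_that("no individual older than the lifespan appears in any census", {
  cfg <- make_mini_scenario("smoke")
  set.seed(34)
  freqs <- draw_founding_frequencies(cfg$genome)
  rec <- initialize_population(cfg$genome, "recipient", 60, freqs)
  src <- initialize_population(cfg$genome, "source", 100, freqs,
                               track_lrs = FALSE)
  for (y in 1:25) {
    run_year(rec, src, cfg, y)
    expect_true(all(pop_ages <- rec$age[alive_rows(rec)] <= 10))
    expect_true(all(src$age[alive_rows(src)] <= 10))
  }
})

test_that("yearly census conservation: N(end) = N(start) + births - deaths", {
  cfg <- make_mini_scenario("smoke")
  set.seed(35)
  freqs <- draw_founding_frequencies(cfg$genome)
  rec <- initialize_population(cfg$genome, "recipient", 60, freqs)
  src <- initialize_population(cfg$genome, "source", 100, freqs,
                               track_lrs = FALSE)
  for (y in 1:30) {
    n_start <- population_size(rec)
    row <- run_year(rec, src, cfg, y)
    expect_equal(row$census, n_start + row$births - row$deaths)
  }
})

test_that("population snapshots and LRS records stay consistent", {
  cfg <- make_mini_scenario("smoke")
  tab <- run_replicate(cfg, 1)
  lrs <- attr(tab, "lrs")
  expect_true(all(lrs$offspring >= lrs$offspring_matured))
  expect_true(all(lrs$mates[lrs$offspring > 0] >= 1))
  # everyone with offspring was recorded as born before or at their death
  dead <- lrs[!is.na(lrs$death), ]
  expect_true(all(dead$death >= dead$born))
})
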