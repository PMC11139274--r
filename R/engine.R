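#' Scenario configuration
#'
#' Assembles the full parameter set of one simulation cell: genome layout and
#' founding minor-allele-frequency regime, crash schedule, migration regime
#' and timing, run length, replicate count and seeding, demographic rates,
#' and monitoring options.
#'
#' The founding MAF regimes are `"low/low"` (both populations 0.05-0.15),
#' `"high/high"` (both 0.40-0.50), `"high_source/low_recipient"` and
#' `"low_source/high_recipient"`.  When both populations share a range, the
#' per-locus founding frequencies are shared between them; when ranges
#' differ, draws are independent.
#'
#' @param crash A crash category name or a [crash_schedule()] (default
#'   `"none"`).
#' @param migration A regime name or a [build_schedule()] result (default
#'   `"none"`).
#' @param timing Burst/pulse timing, passed to [build_schedule()].
#' @param maf_regime Founding MAF regime (default `"low/low"`).
#' @param years Run length in years (default 350).
#' @param replicates Replicate count (default 100).
#' @param base_seed Base seed; each replicate derives its own deterministic
#'   seed from `(base_seed, replicate index)`.
#' @param r Per-capita logistic growth rate (default 1).
#' @param noise_sd Density-independent noise sd on the logistic target
#'   (default 1).
#' @param k_source Source-population carrying capacity (default 5000).
#' @param extirpation_threshold Census at or below which the recipient is
#'   functionally extirpated and the replicate halts (default 10).
#' @param migrant_bias Preferentially select migrant-containing pairs for
#'   breeding (default TRUE).
#' @param max_lifespan Maximum lifespan in years (default 10).
#' @param genome Optional [genome_spec()] overriding the default 1200-SNP
#'   layout (its MAF ranges are set from `maf_regime`).
#' @param track_lrs Track recipient lifetime reproductive success (default
#'   TRUE).
#' @param fst_years,fis_years,het_years Years at which F_ST / F_IS /
#'   heterozygosity are evaluated (NULL = every year).  These statistics
#'   are per-year independent measurements, so thinning them changes
#'   nothing at the years retained; census, migrant ancestry and the
#'   demographic counters are always recorded yearly.
#' @param name Scenario label used in outputs.
#' @return A `scenario_config` object.
#' @examples
#' cfg <- scenario_config(crash = "endangered",
#'                        migration = "one_per_generation",
#'                        replicates = 3, years = 60)
#' cfg$crash$k_crash  # 300
#' @export
scenario_config <- function(crash = "none", migration = "none", timing = NULL,
                            maf_regime = "low/low", years = 350,
                            replicates = 100, base_seed = 42, r = 1,
                            noise_sd = 1, k_source = 5000,
                            extirpation_threshold = 10, migrant_bias = TRUE,
                            max_lifespan = 10, genome = NULL,
                            track_lrs = TRUE, fst_years = NULL,
                            fis_years = NULL, het_years = NULL,
                            name = NULL) {
  if (!inherits(crash, "crash_schedule")) crash <- crash_schedule(crash)
  if (!inherits(migration, "migration_schedule"))
    migration <- build_schedule(migration, timing = timing, years = years)
  ranges <- .maf_ranges(maf_regime)
  if (is.null(genome)) {
    genome <- genome_spec(maf_recipient = ranges$recipient,
                          maf_source = ranges$source)
  } else {
    genome$maf_recipient <- ranges$recipient
    genome$maf_source <- ranges$source
  }
  replicates <- as.integer(replicates)
  if (replicates < 1L) stop("replicates must be >= 1")
  if (crash$category != "none" && years < crash$minima_end)
    stop("run must extend at least to the end of the crash minima")
  if (is.null(name))
    name <- paste0(crash$category, ".", migration$regime,
                   if (!is.null(migration$timing))
                     paste0(".", migration$timing),
                   ".", gsub("/", "-", maf_regime))
  structure(list(
    crash = crash, migration = migration, maf_regime = maf_regime,
    years = as.integer(years), replicates = replicates,
    base_seed = base_seed, r = r, noise_sd = noise_sd,
    k_source = k_source, extirpation_threshold = extirpation_threshold,
    migrant_bias = migrant_bias, max_lifespan = max_lifespan,
    genome = genome, track_lrs = track_lrs,
    fst_years = fst_years, fis_years = fis_years, het_years = het_years,
    name = name
  ), class = "scenario_config")
}

.maf_ranges <- function(regime) {
  lo <- c(0.05, 0.15)
  hi <- c(0.40, 0.50)
  switch(regime,
         "low/low" = list(recipient = lo, source = lo),
         "high/high" = list(recipient = hi, source = hi),
         "high_source/low_recipient" = list(recipient = lo, source = hi),
         "low_source/high_recipient" = list(recipient = hi, source = lo),
         stop("unknown maf_regime: ", regime))
}

#' @export
print.scenario_config <- function(x, ...) {
  cat("Scenario:", x$name, "\n")
  cat(sprintf("  %d years, %d replicates, base seed %s\n", x$years,
              x$replicates, format(x$base_seed)))
  print(x$crash)
  print(x$migration)
  cat(sprintf("  founding MAF regime %s; K_source %g; r = %g; noise sd %g\n",
              x$maf_regime, x$k_source, x$r, x$noise_sd))
  invisible(x)
}

# One population's breeding sub-cycle: pairing, logistic quota, breeder
# selection, offspring creation.
.step_breeding <- function(pop, k, config) {
  pairs <- form_pairs(pop)
  quota <- offspring_quota(population_size(pop), k, r = config$r,
                           noise_sd = config$noise_sd)
  breeders <- select_breeders(pairs, quota,
                              migrant_bias = config$migrant_bias)
  reproduce(pop, breeders)
}

.step_mortality <- function(pop, config) {
  apply_maturity_viability(pop)
  apply_mutation_mortality(pop)
  apply_age_mortality(pop, max_lifespan = config$max_lifespan)
}

#' Advance both populations through one simulated year
#'
#' Executes the yearly cycle in order: aging; scheduled migrant transfer
#' into the recipient; pair formation with the Allee effect, logistic
#' offspring quota (census after immigration, before births) and
#' reproduction with newborn mutation, for each population; yearly mutation
#' of standing individuals; maturity-viability, mutation-cost and age
#' mortality; metric capture for the recipient; extirpation check.  The
#' source runs the identical cycle with its own carrying capacity and no
#' immigration.
#'
#' @param recipient,source [population_state] environments.
#' @param config A [scenario_config()].
#' @param year Simulation year (1-based).
#' @param snapshots Year-0 snapshot summaries (see [run_replicate()]), or
#'   NULL to skip divergence metrics.
#' @return The recipient's one-row metrics data frame for the year; the
#'   population states are updated in place.
#' @export
run_year <- function(recipient, source, config, year, snapshots = NULL) {
  recipient$year <- year
  source$year <- year
  recipient$deaths_year <- 0L
  source$deaths_year <- 0L

  age_population(recipient)
  age_population(source)

  n_mig <- migrants_at(config$migration, year)
  if (n_mig > 0L) transfer_migrants(source, recipient, n_mig, year = year)

  standing_r <- alive_rows(recipient)
  standing_s <- alive_rows(source)
  k_now <- carrying_capacity_at(year, config$crash)
  breeding <- .step_breeding(recipient, k_now, config)
  .step_breeding(source, config$k_source, config)

  mutate_population(recipient, standing_r)
  mutate_population(source, standing_s)

  .step_mortality(recipient, config)
  .step_mortality(source, config)

  want_fst <- is.null(config$fst_years) || year %in% config$fst_years
  want_fis <- is.null(config$fis_years) || year %in% config$fis_years
  want_het <- is.null(config$het_years) || year %in% config$het_years
  row <- yearly_metrics(recipient, snapshots = snapshots,
                        breeding = breeding, year = year,
                        deaths = recipient$deaths_year,
                        compute_fst = want_fst, compute_fis = want_fis,
                        compute_het = want_het)
  if (row$census <= config$extirpation_threshold) {
    recipient$extirpated <- TRUE
    row$extirpated <- TRUE
  }
  row
}

.replicate_seed <- function(base_seed, replicate) {
  s <- (abs(as.numeric(base_seed)) * 1009 + as.numeric(replicate) * 7919) %%
    2147483646
  as.integer(s) + 1L
}

#' Run one replicate of a scenario
#'
#' Initializes both populations at carrying capacity, stores year-0 genotype
#' snapshots (as per-locus summaries over the neutral + migrant-diagnostic
#' loci) for the two divergence comparisons, then iterates [run_year()]
#' through the configured horizon or until the recipient is functionally
#' extirpated.  Fully deterministic given `(base_seed, replicate)`.
#'
#' @param config A [scenario_config()].
#' @param replicate Replicate index (default 1).
#' @return A data frame of per-year metrics (one row per completed year,
#'   fewer than `config$years` only if extirpated), with attributes
#'   `extirpation_year` (NA if the recipient survived), `lrs` (the
#'   recipient's lifetime-reproductive-success records when tracked),
#'   `scenario`, `replicate` and `seed`.
#' @export
run_replicate <- function(config, replicate = 1L) {
  stopifnot(inherits(config, "scenario_config"))
  seed <- .replicate_seed(config$base_seed, replicate)
  set.seed(seed)
  freqs <- draw_founding_frequencies(config$genome)
  recipient <- initialize_population(config$genome, "recipient",
                                     config$crash$k_historic, freqs,
                                     track_lrs = config$track_lrs)
  source_pop <- initialize_population(config$genome, "source",
                                      config$k_source, freqs,
                                      track_lrs = FALSE)
  snapshots <- list(recipient = locus_summary(recipient, "neutral+migrant"),
                    source = locus_summary(source_pop, "neutral+migrant"))
  rows <- vector("list", config$years)
  for (year in seq_len(config$years)) {
    rows[[year]] <- run_year(recipient, source_pop, config, year, snapshots)
    if (recipient$extirpated) break
  }
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  attr(out, "extirpation_year") <-
    if (recipient$extirpated) max(out$year) else NA_integer_
  if (config$track_lrs) attr(out, "lrs") <- lrs_records(recipient)
  attr(out, "scenario") <- config$name
  attr(out, "replicate") <- replicate
  attr(out, "seed") <- seed
  out
}

#' Run all replicates of one scenario
#'
#' @param config A [scenario_config()].
#' @param replicates Number of replicates (default `config$replicates`).
#' @param progress Print a progress line per replicate (default FALSE).
#' @return A `scenario_result` list: `config`; `metrics`, the long
#'   per-replicate yearly table (with a `replicate` column); `summary`, the
#'   [summarize_replicates()] result; `lrs`, pooled LRS records when
#'   tracked.
#' @export
run_scenario <- function(config, replicates = config$replicates,
                         progress = FALSE) {
  tabs <- vector("list", replicates)
  lrs <- vector("list", replicates)
  for (i in seq_len(replicates)) {
    tab <- run_replicate(config, i)
    lrs[[i]] <- attr(tab, "lrs")
    if (!is.null(lrs[[i]])) lrs[[i]]$replicate <- i
    attributes(tab)[c("lrs")] <- NULL
    tab$replicate <- i
    tabs[[i]] <- tab
    if (progress)
      message(sprintf("  replicate %d/%d: %d years%s", i, replicates,
                      max(tab$year),
                      if (any(tab$extirpated)) " (extirpated)" else ""))
  }
  metrics <- do.call(rbind, tabs)
  metrics$scenario <- config$name
  summ <- if (replicates >= 2L) summarize_replicates(metrics) else NULL
  structure(list(config = config, metrics = metrics, summary = summ,
                 lrs = if (config$track_lrs) do.call(rbind, lrs) else NULL),
            class = "scenario_result")
}

#' @export
print.scenario_result <- function(x, ...) {
  cat("Scenario result:", x$config$name, "\n")
  nrep <- length(unique(x$metrics$replicate))
  next_ <- if (!is.null(x$summary))
    sum(!is.na(x$summary$extirpation_years)) else NA
  cat(sprintf("  %d replicates, %s extirpated\n", nrep, format(next_)))
  invisible(x)
}

#' Run a grid of scenarios
#'
#' Runs every configuration in turn (replicate streams are derived from
#' each scenario's own base seed, so results are independent of execution
#' order) and optionally writes tidy outputs: per-scenario yearly metrics
#' CSV, summary CSV, and a JSON configuration echo when jsonlite is
#' available.
#'
#' @param configs A list of [scenario_config()]s.
#' @param replicates Optional replicate-count override for every scenario.
#' @param out_dir Optional output directory.
#' @param progress Print progress (default TRUE).
#' @return Named list of `scenario_result`s.
#' @export
run_scenario_grid <- function(configs, replicates = NULL, out_dir = NULL,
                              progress = TRUE) {
  if (inherits(configs, "scenario_config")) configs <- list(configs)
  results <- list()
  for (cfg in configs) {
    if (progress) message("scenario: ", cfg$name)
    res <- tryCatch(
      run_scenario(cfg, replicates = if (is.null(replicates))
        cfg$replicates else replicates, progress = FALSE),
      error = function(e) {
        warning("scenario '", cfg$name, "' failed: ", conditionMessage(e))
        NULL
      })
    if (is.null(res)) next
    results[[cfg$name]] <- res
    if (!is.null(out_dir)) .write_scenario_outputs(res, out_dir)
  }
  results
}

.write_scenario_outputs <- function(res, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  base <- file.path(out_dir, res$config$name)
  write.csv(res$metrics, paste0(base, ".metrics.csv"), row.names = FALSE)
  if (!is.null(res$summary))
    write.csv(res$summary$summary, paste0(base, ".summary.csv"),
              row.names = FALSE)
  if (requireNamespace("jsonlite", quietly = TRUE)) {
    cfg <- res$config
    echo <- list(name = cfg$name, years = cfg$years,
                 replicates = cfg$replicates, base_seed = cfg$base_seed,
                 crash = unclass(cfg$crash),
                 migration = list(regime = cfg$migration$regime,
                                  timing = cfg$migration$timing,
                                  events = as.list(cfg$migration$events)),
                 maf_regime = cfg$maf_regime, r = cfg$r,
                 noise_sd = cfg$noise_sd, k_source = cfg$k_source,
                 extirpation_threshold = cfg$extirpation_threshold,
                 migrant_bias = cfg$migrant_bias)
    jsonlite::write_json(echo, paste0(base, ".config.json"),
                         auto_unbox = TRUE, pretty = TRUE)
  }
  invisible(NULL)
}

#' The headline scenario grid
#'
#' Convenience constructor for the crossed study design: each extinction-risk
#' category with and without one migrant per generation, plus burst and
#' pulse regimes at both timings for the crash categories, all at the
#' low/low founding MAF regime.
#'
#' @param replicates Replicates per scenario (default 100).
#' @param base_seed Base seed (default 42).
#' @param maf_regime Founding MAF regime (default `"low/low"`).
#' @return A list of [scenario_config()]s.
#' @export
default_scenario_grid <- function(replicates = 100, base_seed = 42,
                                  maf_regime = "low/low") {
  crashes <- c("none", "vulnerable", "endangered", "critically_endangered")
  configs <- list()
  for (cr in crashes) {
    for (mig in c("none", "one_per_generation"))
      configs[[length(configs) + 1L]] <-
        scenario_config(crash = cr, migration = mig,
                        maf_regime = maf_regime, replicates = replicates,
                        base_seed = base_seed)
    if (cr == "none") next
    for (mig in c("burst", "pulse"))
      for (tm in c("during_restoration", "after_restoration"))
        configs[[length(configs) + 1L]] <-
          scenario_config(crash = cr, migration = mig, timing = tm,
                          maf_regime = maf_regime, replicates = replicates,
                          base_seed = base_seed)
  }
  configs
}
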