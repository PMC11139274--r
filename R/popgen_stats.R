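#' Per-locus allele-state summary
#'
#' One pass over a set of individuals and loci producing, per locus: allele-
#' copy counts per state (0/1/2), counts of individuals carrying exactly one
#' copy of each state, and the number of heterozygous individuals.  All
#' monitoring statistics (heterozygosities, F_IS, Weir-Cockerham F_ST,
#' migrant ancestry) are computed from these summaries, so an expensive
#' genotype scan happens once per population per year — and year-0 snapshots
#' can be stored as summaries instead of full genotype matrices.
#'
#' @param x A [population_state] (live individuals) or [genotype_table()]
#'   (all rows).
#' @param loci Locus class subset: `"neutral"`, `"migrant"`, `"conserved"`,
#'   `"neutral+migrant"` or `"all"`.
#' @return A `locus_summary` with elements `cnt` (3 x L allele-copy counts),
#'   `het1` (3 x L single-copy carrier counts), `nhet` (heterozygous
#'   individuals per locus), `n` (sample size), `cols` (locus columns).
#' @export
locus_summary <- function(x, loci = "all") {
  UseMethod("locus_summary")
}

#' @export
locus_summary.population_state <- function(x, loci = "all") {
  cols <- .locus_cols(x$spec, loci)
  s <- .locus_state_counts(x$G1, x$G2, alive_rows(x), as.integer(cols))
  structure(list(cnt = s$cnt, het1 = s$het1, nhet = as.numeric(s$nhet),
                 n = s$n, cols = cols, loci = loci, spec = x$spec),
            class = "locus_summary")
}

#' @export
locus_summary.genotype_table <- function(x, loci = "all") {
  cols <- .locus_cols(x$spec, loci)
  A1 <- x$A1[, cols, drop = FALSE]
  A2 <- x$A2[, cols, drop = FALSE]
  cnt <- het1 <- matrix(0, 3, length(cols))
  for (s in 0:2) {
    in1 <- A1 == s
    in2 <- A2 == s
    cnt[s + 1L, ] <- colSums(in1) + colSums(in2)
    het1[s + 1L, ] <- colSums(in1 != in2)
  }
  structure(list(cnt = cnt, het1 = het1, nhet = colSums(A1 != A2),
                 n = nrow(A1), cols = cols, loci = loci, spec = x$spec),
            class = "locus_summary")
}

.as_summary <- function(x, loci) {
  if (inherits(x, "locus_summary")) {
    if (!identical(x$loci, loci))
      stop("locus_summary was built over locus set '", x$loci,
           "', not '", loci, "'")
    x
  } else locus_summary(x, loci)
}

#' Observed heterozygosity
#'
#' Mean, over live individuals, of the fraction of neutral loci at which the
#' two allele copies differ (equivalently: total heterozygous genotypes over
#' individuals x loci).
#'
#' @param x A [population_state], [genotype_table()] or neutral-loci
#'   [locus_summary()].
#' @param loci Locus set (default `"neutral"`, as monitored).
#' @return Proportion in \[0, 1\]; `NA` for an empty population.
#' @export
observed_heterozygosity <- function(x, loci = "neutral") {
  s <- .as_summary(x, loci)
  if (s$n == 0L) return(NA_real_)
  sum(s$nhet) / (s$n * length(s$cols))
}

#' Expected heterozygosity (gene diversity)
#'
#' Mean over neutral loci of `1 - sum(p_a^2)` computed from the current
#' population allele frequencies over the three possible states
#' (uncorrected; the small-sample correction enters only inside [f_is()]).
#'
#' @inheritParams observed_heterozygosity
#' @return Proportion in \[0, 1\]; `NA` for an empty population.
#' @export
expected_heterozygosity <- function(x, loci = "neutral") {
  s <- .as_summary(x, loci)
  if (s$n == 0L) return(NA_real_)
  p <- s$cnt / (2 * s$n)
  mean(1 - colSums(p^2))
}

#' Migrant ancestry proportion
#'
#' Fraction of all allele copies at the migrant-diagnostic loci, over the
#' whole population, that are the source-diagnostic allele.
#'
#' @param x A [population_state], [genotype_table()] or migrant-loci
#'   [locus_summary()].
#' @return Proportion in \[0, 1\]; `NA` for an empty population.
#' @export
migrant_ancestry <- function(x) {
  s <- .as_summary(x, "migrant")
  if (s$n == 0L) return(NA_real_)
  sum(s$cnt[2L, ]) / (2 * s$n * length(s$cols))
}

#' Inbreeding coefficient F_IS
#'
#' Nei's within-population inbreeding coefficient `1 - Ho / Hs` over
#' polymorphic neutral loci, with the per-locus gene diversity carrying the
#' small-sample correction: `Hs = n/(n-1) (1 - sum p^2 - Ho_l / (2n))`.
#' `Ho` and `Hs` are averaged across polymorphic loci before the ratio, the
#' convention of standard basic-statistics implementations.  Monomorphic
#' loci are excluded.
#'
#' @inheritParams observed_heterozygosity
#' @return F_IS in \[-1, 1\]; `NA` when no locus is polymorphic or fewer
#'   than two individuals are present.
#' @export
f_is <- function(x, loci = "neutral") {
  s <- .as_summary(x, loci)
  n <- s$n
  if (n < 2L) return(NA_real_)
  p <- s$cnt / (2 * n)
  poly <- colSums(p > 0) > 1L
  if (!any(poly)) return(NA_real_)
  ho <- s$nhet[poly] / n
  hs <- n / (n - 1) * (1 - colSums(p[, poly, drop = FALSE]^2) - ho / (2 * n))
  1 - mean(ho) / mean(hs)
}

#' Weir-Cockerham F_ST between two samples
#'
#' The Weir & Cockerham (1984) theta estimator for two populations,
#' aggregated as a ratio of sums: per locus and per allele state the
#' variance components a (among populations), b (among individuals within
#' populations) and c (within individuals) are computed, summed over states
#' and loci, and theta = sum(a) / sum(a + b + c).  Loci monomorphic in the
#' pooled sample are dropped (they contribute 0/0).  By default the
#' comparison runs over the neutral plus migrant-diagnostic loci — the locus
#' set under which two founding populations sharing neutral frequencies but
#' fixed for alternate diagnostic alleles sit at theta ~ 0.36.
#'
#' @param x,y [population_state]s, [genotype_table()]s or matching
#'   [locus_summary()]s (each with >= 2 individuals).
#' @param loci Locus set (default `"neutral+migrant"`).
#' @return Theta; `NA` when no locus is polymorphic in the pooled sample.
#' @examples
#' spec <- genome_spec(n_neutral = 2, n_migrant = 2, n_conserved = 2)
#' a <- genotype_table(matrix(0L, 4, 6), matrix(0L, 4, 6), spec)
#' b <- genotype_table(matrix(1L, 4, 6), matrix(1L, 4, 6), spec)
#' f_st(a, b, loci = "all")  # fixed differences everywhere -> 1
#' @export
f_st <- function(x, y, loci = "neutral+migrant") {
  sx <- .as_summary(x, loci)
  sy <- .as_summary(y, loci)
  if (sx$n < 2L || sy$n < 2L)
    stop("both samples must contain at least 2 individuals")
  comp <- .wc_components(sx, sy)
  denom <- sum(comp$a + comp$b + comp$c)
  if (denom == 0) return(NA_real_)
  sum(comp$a) / denom
}

# Weir & Cockerham (1984) variance components for r = 2 samples, vectorized
# over allele states (rows) and loci (columns).
.wc_components <- function(sx, sy) {
  n1 <- sx$n; n2 <- sy$n
  p1 <- sx$cnt / (2 * n1)
  p2 <- sy$cnt / (2 * n2)
  h1 <- sx$het1 / n1
  h2 <- sy$het1 / n2
  pooled_states <- (sx$cnt + sy$cnt) > 0
  keep <- colSums(pooled_states) > 1L  # polymorphic in the pooled sample
  r <- 2
  nbar <- (n1 + n2) / r
  nc <- (r * nbar - (n1^2 + n2^2) / (r * nbar)) / (r - 1)
  pbar <- (n1 * p1 + n2 * p2) / (r * nbar)
  s2 <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / ((r - 1) * nbar)
  hbar <- (n1 * h1 + n2 * h2) / (r * nbar)
  a <- nbar / nc *
    (s2 - 1 / (nbar - 1) *
       (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4))
  b <- nbar / (nbar - 1) *
    (pbar * (1 - pbar) - (r - 1) / r * s2 - (2 * nbar - 1) / (4 * nbar) * hbar)
  cc <- hbar / 2
  list(a = a[, keep, drop = FALSE], b = b[, keep, drop = FALSE],
       c = cc[, keep, drop = FALSE])
}

#' Sex ratio of the live population
#' @param pop A [population_state].
#' @return Females per male; `NA` when either sex is absent.
#' @export
sex_ratio <- function(pop) {
  rows <- alive_rows(pop)
  nf <- sum(pop$sex[rows] == SEX_FEMALE)
  nm <- sum(pop$sex[rows] == SEX_MALE)
  if (nm == 0L || nf == 0L) return(NA_real_)
  nf / nm
}

#' Assemble the yearly monitoring record for the recipient population
#'
#' Fills one row of per-year monitored quantities: census and adult counts,
#' sex ratio, observed/expected neutral heterozygosity, migrant ancestry,
#' F_IS, F_ST against the year-0 recipient and source snapshots, effective
#' migrants and parents, births and deaths.  F_IS and the two F_ST
#' comparisons are computed only when requested (they are per-year
#' independent measurements and may be thinned to a year grid).
#'
#' @param pop The recipient [population_state] after this year's mortality.
#' @param snapshots List with `recipient` and `source` year-0
#'   [locus_summary()]s over `"neutral+migrant"` loci (as produced by
#'   [run_replicate()]), or NULL to skip divergence.
#' @param breeding This year's [reproduce()] info (or NULL).
#' @param year Simulation year.
#' @param deaths Deaths recorded this year.
#' @param compute_fst,compute_fis,compute_het Whether to evaluate the
#'   divergence, inbreeding and heterozygosity statistics this year
#'   (default TRUE).  When only `compute_het` is off but F-statistics are
#'   requested, heterozygosities come for free from the same genotype scan
#'   and are still reported; when all three are off, only the cheap
#'   migrant-diagnostic scan runs and the genetic-diversity columns are NA.
#' @return A one-row data frame of metrics.
#' @export
yearly_metrics <- function(pop, snapshots = NULL, breeding = NULL,
                           year = pop$year, deaths = pop$deaths_year,
                           compute_fst = TRUE, compute_fis = TRUE,
                           compute_het = TRUE) {
  rows <- alive_rows(pop)
  n <- length(rows)
  extinct <- pop$extirpated
  if (n == 0L || extinct) {
    return(.fast_df(list(year = year, census = n, n_adults = NA_integer_,
                         sex_ratio = NA_real_, ho_neutral = NA_real_,
                         he_neutral = NA_real_, migrant_ancestry = NA_real_,
                         f_is = NA_real_, fst_vs_recipient0 = NA_real_,
                         fst_vs_source0 = NA_real_,
                         n_effective_migrants = NA_integer_,
                         n_effective_parents = NA_integer_,
                         births = if (is.null(breeding)) NA_integer_ else
                           breeding$births,
                         deaths = deaths, extirpated = TRUE)))
  }
  want_fst <- compute_fst && !is.null(snapshots)
  need_full <- compute_het || compute_fis || want_fst
  if (need_full) {
    s_nm <- locus_summary(pop, "neutral+migrant")
    s_neut <- .subset_summary(s_nm, pop$spec$idx_neutral)
    s_mig <- .subset_summary(s_nm, pop$spec$idx_migrant, loci = "migrant")
  } else {
    s_mig <- locus_summary(pop, "migrant")
  }
  fst_r <- fst_s <- NA_real_
  if (want_fst) {
    fst_r <- f_st(snapshots$recipient, s_nm)
    fst_s <- f_st(snapshots$source, s_nm)
  }
  .fast_df(list(
    year = year,
    census = n,
    n_adults = sum(pop$age[rows] >= 1L),
    sex_ratio = sex_ratio(pop),
    ho_neutral = if (need_full) observed_heterozygosity(s_neut) else NA_real_,
    he_neutral = if (need_full) expected_heterozygosity(s_neut) else NA_real_,
    migrant_ancestry = migrant_ancestry(s_mig),
    f_is = if (compute_fis && need_full) f_is(s_neut) else NA_real_,
    fst_vs_recipient0 = fst_r,
    fst_vs_source0 = fst_s,
    n_effective_migrants = if (is.null(breeding)) 0L else
      breeding$n_effective_migrants,
    n_effective_parents = if (is.null(breeding)) 0L else
      breeding$n_effective_parents,
    births = if (is.null(breeding)) 0L else breeding$births,
    deaths = deaths,
    extirpated = FALSE))
}

# Restrict a neutral+migrant summary to a column subset without rescanning.
.subset_summary <- function(s, cols, loci = "neutral") {
  sel <- match(cols, s$cols)
  structure(list(cnt = s$cnt[, sel, drop = FALSE],
                 het1 = s$het1[, sel, drop = FALSE],
                 nhet = s$nhet[sel], n = s$n, cols = cols, loci = loci,
                 spec = s$spec),
            class = "locus_summary")
}

#' Summarize replicate metric tables
#'
#' Computes, per year and metric, the across-replicate mean and a central
#' 84% quantile band (8% and 92% quantiles; non-overlap of such bands
#' approximates a test at alpha = 0.05).  Summaries at a given year cover
#' only replicates still extant then — extirpated replicates drop out from
#' their extirpation year onward rather than being zero-imputed; their
#' extirpation years are reported separately.
#'
#' @param tables A list of per-replicate metric data frames from
#'   [run_replicate()], or a single long data frame with a `replicate`
#'   column.
#' @param quantile_pair Lower/upper band quantiles (default `c(0.08, 0.92)`).
#' @return A `replicate_summary` list: `summary`, a long data frame (year,
#'   metric, mean, lower, upper, n_replicates); `extirpation_years`, one
#'   entry per replicate (NA when the replicate survived); `quantile_pair`.
#' @export
summarize_replicates <- function(tables, quantile_pair = c(0.08, 0.92)) {
  stopifnot(length(quantile_pair) == 2L, quantile_pair[1] <= quantile_pair[2])
  if (is.data.frame(tables)) {
    stopifnot("replicate" %in% names(tables))
    long <- tables
    reps <- sort(unique(long$replicate))
    ext <- vapply(split(long, long$replicate), function(d) {
      if (any(d$extirpated)) min(d$year[d$extirpated]) else NA_real_
    }, numeric(1))
  } else {
    if (length(tables) < 2L)
      stop("at least two replicate tables are required")
    ext <- vapply(tables, function(d) {
      if (any(d$extirpated)) min(d$year[d$extirpated]) else NA_real_
    }, numeric(1))
    for (i in seq_along(tables)) tables[[i]]$replicate <- i
    long <- do.call(rbind, tables)
    reps <- seq_along(tables)
  }
  long <- long[!long$extirpated, , drop = FALSE]
  metrics <- setdiff(names(long),
                     c("year", "replicate", "extirpated"))
  pieces <- lapply(metrics, function(m) {
    v <- long[[m]]
    if (!is.numeric(v)) return(NULL)
    by_year <- split(v, long$year)
    yrs <- as.integer(names(by_year))
    mean_v <- vapply(by_year, function(z) mean(z, na.rm = TRUE), numeric(1))
    lo <- vapply(by_year, function(z)
      quantile(z, quantile_pair[1], na.rm = TRUE, names = FALSE), numeric(1))
    hi <- vapply(by_year, function(z)
      quantile(z, quantile_pair[2], na.rm = TRUE, names = FALSE), numeric(1))
    nrep <- vapply(by_year, length, integer(1))
    data.frame(year = yrs, metric = m, mean = unname(mean_v),
               lower = unname(lo), upper = unname(hi),
               n_replicates = unname(nrep))
  })
  out <- do.call(rbind, pieces)
  out <- out[order(out$metric, out$year), ]
  rownames(out) <- NULL
  structure(list(summary = out,
                 extirpation_years = setNames(ext, reps),
                 quantile_pair = quantile_pair),
            class = "replicate_summary")
}

#' @export
print.replicate_summary <- function(x, ...) {
  nrep <- length(x$extirpation_years)
  next_ <- sum(!is.na(x$extirpation_years))
  cat(sprintf(
    "Replicate summary: %d replicates (%d extirpated), %d metrics, years %d-%d\n",
    nrep, next_, length(unique(x$summary$metric)),
    min(x$summary$year), max(x$summary$year)))
  cat(sprintf("  band: central %.0f%% quantiles (%.2f, %.2f)\n",
              100 * diff(x$quantile_pair), x$quantile_pair[1],
              x$quantile_pair[2]))
  invisible(x)
}
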