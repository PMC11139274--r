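#' Miniature test scenarios
#'
#' Deterministic, seconds-scale down-scalings of the full study design used
#' by the test-suite and the CLI demo: K = 60 recipients, K = 200 source
#' individuals, a 40-SNP genome (20 neutral / 10 migrant-diagnostic / 10
#' conserved), 60 years with a crash over years 20-35, and 10 replicates.
#' All module contracts hold at this scale; mini scenarios are plumbing and
#' are not calibrated to reproduce full-scale results.
#'
#' Profiles: `"smoke"` is a no-crash, no-migration control; `"crash"` is a
#' severe crash (floor tuned so that extirpations occur in some replicates)
#' without migration; `"rescue"` is an endangered-severity crash with pulse
#' translocations after restoration.
#'
#' @param profile `"smoke"`, `"crash"` or `"rescue"`.
#' @param seed Base seed stored in the configuration (default 1).
#' @return A [scenario_config()].
#' @examples
#' cfg <- make_mini_scenario("smoke")
#' tab <- run_replicate(cfg, 1)
#' tail(tab$census, 1)
#' @export
make_mini_scenario <- function(profile = c("smoke", "crash", "rescue"),
                               seed = 1) {
  profile <- match.arg(profile)
  genome <- genome_spec(n_neutral = 20L, n_migrant = 10L, n_conserved = 10L)
  k <- 60
  mk_crash <- function(k_crash)
    crash_schedule("critically_endangered", k_historic = k, k_crash = k_crash,
                   decline_start = 20, decline_years = 5, minima_end = 35)
  common <- list(maf_regime = "low/low", years = 60L, replicates = 10L,
                 base_seed = seed, k_source = 200, genome = genome,
                 track_lrs = TRUE)
  args <- switch(profile,
    smoke = list(crash = crash_schedule("none", k_historic = k),
                 migration = "none"),
    crash = list(crash = mk_crash(18), migration = "none"),
    rescue = list(crash = mk_crash(30),
                  migration = build_schedule(
                    "pulse", years = 60L,
                    event_years = c(26, 31, 36, 41),
                    event_sizes = rep(5L, 4))))
  cfg <- do.call(scenario_config, c(args, common))
  cfg$name <- paste0("mini_", profile)
  cfg
}

#' Hand-checkable toy genotype tables
#'
#' Builds a small [genotype_table()] from an explicit allele layout for
#' estimator golden tests.  The layout is either a character vector with one
#' string per individual of slash-separated genotypes (e.g. `"0/1 1/1"`), or
#' a list with integer matrices `A1` and `A2`.  Locus classes default to all
#' neutral.
#'
#' @param layout Character vector of per-individual genotype strings, or
#'   `list(A1 = , A2 = )`.
#' @param classes Character vector of per-locus classes (`"neutral"`,
#'   `"migrant"`, `"conserved"`), in that class order; default all neutral.
#' @return A [genotype_table()].
#' @examples
#' gt <- make_toy_genotypes(c("0/0 0/1", "1/1 0/0"))
#' observed_heterozygosity(gt)  # 0.25
#' @export
make_toy_genotypes <- function(layout, classes = NULL) {
  if (is.character(layout)) {
    cells <- strsplit(trimws(layout), "\\s+")
    lens <- lengths(cells)
    if (length(unique(lens)) != 1L)
      stop("ragged layout: individuals have differing locus counts")
    parse_cell <- function(s) {
      parts <- strsplit(s, "/", fixed = TRUE)[[1]]
      if (length(parts) != 2L) stop("malformed genotype '", s, "'")
      as.integer(parts)
    }
    n <- length(cells)
    L <- lens[1]
    A1 <- matrix(0L, n, L)
    A2 <- matrix(0L, n, L)
    for (i in seq_len(n)) {
      for (j in seq_len(L)) {
        g <- parse_cell(cells[[i]][j])
        A1[i, j] <- g[1]
        A2[i, j] <- g[2]
      }
    }
  } else if (is.list(layout) && all(c("A1", "A2") %in% names(layout))) {
    A1 <- as.matrix(layout$A1)
    A2 <- as.matrix(layout$A2)
    if (!identical(dim(A1), dim(A2)))
      stop("ragged layout: A1 and A2 differ in shape")
  } else {
    stop("layout must be a character vector or list(A1, A2)")
  }
  L <- ncol(A1)
  if (is.null(classes)) classes <- rep("neutral", L)
  if (length(classes) != L)
    stop("classes must name every locus")
  counts <- c(neutral = sum(classes == "neutral"),
              migrant = sum(classes == "migrant"),
              conserved = sum(classes == "conserved"))
  if (sum(counts) != L) stop("unknown locus class in 'classes'")
  if (!identical(classes,
                 rep(c("neutral", "migrant", "conserved"), times = counts)))
    stop("classes must be grouped neutral, migrant, conserved")
  spec <- .toy_genome_spec(counts[["neutral"]], counts[["migrant"]],
                           counts[["conserved"]])
  genotype_table(A1, A2, spec)
}

# A genome_spec-shaped object allowing empty locus classes, for toy tables.
.toy_genome_spec <- function(n_neutral, n_migrant, n_conserved) {
  n_loci <- n_neutral + n_migrant + n_conserved
  structure(list(
    n_neutral = n_neutral, n_migrant = n_migrant, n_conserved = n_conserved,
    n_loci = n_loci,
    idx_neutral = seq_len(n_neutral),
    idx_migrant = n_neutral + seq_len(n_migrant),
    idx_conserved = n_neutral + n_migrant + seq_len(n_conserved),
    classes = rep(c("neutral", "migrant", "conserved"),
                  times = c(n_neutral, n_migrant, n_conserved)),
    maf_recipient = c(0.05, 0.15), maf_source = c(0.05, 0.15),
    mu_neutral = 2.2e-9, constraint_u = 2.2, mu_conserved = 2.2e-9 * 2.2
  ), class = "genome_spec")
}
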