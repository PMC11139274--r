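#' Carrying-capacity crash schedule
#'
#' Describes the habitat-crash-and-restoration trajectory of the recipient
#' population's carrying capacity: a historic capacity, a linear 10-year
#' decline beginning at `decline_start` down to the crash floor `k_crash`,
#' maintenance at the floor through `minima_end`, and instantaneous
#' restoration to the historic capacity afterwards.  The three named crash
#' categories follow IUCN-style declines from K = 1000: vulnerable (30%
#' decline, floor 700), endangered (70%, floor 300) and critically
#' endangered (90%, floor 100).
#'
#' @param category `"none"`, `"vulnerable"`, `"endangered"` or
#'   `"critically_endangered"`.
#' @param k_historic Historic carrying capacity (default 1000).
#' @param k_crash Crash-floor capacity; defaults to the category's value.
#' @param decline_start Year the decline begins (default 100).
#' @param decline_years Duration of the decline ramp (default 10).
#' @param minima_end Last year at the floor (default 150); capacity returns
#'   to `k_historic` from `minima_end + 1` onward.
#' @return A `crash_schedule` object.
#' @examples
#' s <- crash_schedule("critically_endangered")
#' carrying_capacity_at(c(0, 105, 130, 200), s)  # 1000, 550, 100, 1000
#' @export
crash_schedule <- function(category = c("none", "vulnerable", "endangered",
                                        "critically_endangered"),
                           k_historic = 1000, k_crash = NULL,
                           decline_start = 100, decline_years = 10,
                           minima_end = 150) {
  category <- match.arg(category)
  if (is.null(k_crash))
    k_crash <- switch(category, none = k_historic,
                      vulnerable = 0.7 * k_historic,
                      endangered = 0.3 * k_historic,
                      critically_endangered = 0.1 * k_historic)
  if (category != "none") {
    if (k_crash >= k_historic)
      stop("k_crash must be below k_historic when a crash is configured")
    if (minima_end < decline_start + decline_years)
      stop("minima_end must lie at or after the end of the decline ramp")
  }
  structure(list(category = category, k_historic = k_historic,
                 k_crash = k_crash, decline_start = decline_start,
                 decline_years = decline_years, minima_end = minima_end),
            class = "crash_schedule")
}

#' @export
print.crash_schedule <- function(x, ...) {
  if (x$category == "none") {
    cat("Crash schedule: none (constant K =", x$k_historic, ")\n")
  } else {
    cat(sprintf(
      "Crash schedule '%s': K %g -> %g over years %d-%d, floor through year %d\n",
      x$category, x$k_historic, x$k_crash, x$decline_start,
      x$decline_start + x$decline_years, x$minima_end))
  }
  invisible(x)
}

#' Carrying capacity in a given year
#'
#' Vectorized over `year`: the historic capacity before the decline and
#' after restoration, linear interpolation across the decline ramp, and the
#' crash floor through the minima.
#'
#' @param year Simulation year(s), >= 0.
#' @param schedule A [crash_schedule()].
#' @return Numeric capacity, same length as `year`.
#' @export
carrying_capacity_at <- function(year, schedule) {
  stopifnot(inherits(schedule, "crash_schedule"))
  if (schedule$category == "none")
    return(rep(schedule$k_historic, length(year)))
  k <- rep(schedule$k_historic, length(year))
  ramp_end <- schedule$decline_start + schedule$decline_years
  on_ramp <- year > schedule$decline_start & year < ramp_end
  k[on_ramp] <- schedule$k_historic +
    (year[on_ramp] - schedule$decline_start) / schedule$decline_years *
    (schedule$k_crash - schedule$k_historic)
  at_floor <- year >= ramp_end & year <= schedule$minima_end
  k[at_floor] <- schedule$k_crash
  k
}

#' Logistic offspring quota
#'
#' The target next-year population size follows the discrete logistic map
#' `N' = (1 + r (1 - N/K)) N`, perturbed by density-independent Gaussian
#' noise (sd `noise_sd`) and rounded; the number of offspring to create is
#' `max(0, N' - N)`.  The quota is clamped at zero when the map points
#' downward — population reductions are handled by the mortality processes,
#' not by culling.
#'
#' @param n_t Census size before reproduction.
#' @param k Current carrying capacity (> 0).
#' @param r Per-capita growth rate (default 1).
#' @param noise_sd Standard deviation of the noise (default 1; 0 disables).
#' @return Integer offspring count, >= 0.
#' @examples
#' offspring_quota(500, 1000, noise_sd = 0)  # 250
#' offspring_quota(1000, 1000, noise_sd = 0) # 0 (logistic fixed point)
#' @export
offspring_quota <- function(n_t, k, r = 1, noise_sd = 1) {
  stopifnot(n_t >= 0, k > 0)
  n_next <- (1 + r * (1 - n_t / k)) * n_t
  if (noise_sd > 0) n_next <- rnorm(1, n_next, noise_sd)
  n_next <- max(0, round(n_next))
  max(0L, as.integer(n_next - n_t))
}

#' Random monogamous pairing with an Allee mate-finding effect
#'
#' Mature individuals (age >= 1) are shuffled and paired across sexes; the
#' number of candidate pairs `P` is the minority-sex count.  Each candidate
#' pair is retained independently with probability `1 - 1/P` — the
#' mate-finding probability shrinks as the adult pool shrinks, and a lone
#' pair can never breed.  Pairing is redrawn from scratch every year.
#'
#' @param pop A [population_state].
#' @return A data frame of retained pairs with columns `female`, `male`
#'   (storage row indices) and `has_migrant`; its `"n_candidates"` attribute
#'   records `P`.
#' @export
form_pairs <- function(pop) {
  rows <- which(pop$alive & pop$age >= 1L)
  females <- rows[pop$sex[rows] == SEX_FEMALE]
  males <- rows[pop$sex[rows] == SEX_MALE]
  p_cand <- min(length(females), length(males))
  if (p_cand == 0L) {
    empty <- .fast_df(list(female = integer(0), male = integer(0),
                           has_migrant = logical(0)))
    attr(empty, "n_candidates") <- p_cand
    return(empty)
  }
  females <- females[sample.int(length(females), p_cand)]
  males <- males[sample.int(length(males), p_cand)]
  keep <- runif(p_cand) < 1 - 1 / p_cand
  f <- females[keep]
  m <- males[keep]
  pairs <- .fast_df(list(
    female = f, male = m,
    has_migrant = pop$origin[f] == ORIGIN_MIGRANT |
      pop$origin[m] == ORIGIN_MIGRANT))
  attr(pairs, "n_candidates") <- p_cand
  pairs
}

#' Allocate the offspring quota across retained pairs
#'
#' Pairs are ordered migrant-containing first (random order within tiers)
#' when `migrant_bias` is on, fully at random otherwise, and assigned two
#' offspring each down the order until the quota is exhausted (the last pair
#' served may receive one).  Fecundity is capped at two offspring per pair
#' per year; quota beyond `2 * nrow(pairs)` goes unfilled.
#'
#' @param pairs Retained pairs from [form_pairs()] (already in random
#'   order).
#' @param quota Offspring quota from [offspring_quota()].
#' @param migrant_bias Preferentially choose migrant-containing pairs
#'   (default TRUE).
#' @return The pairs with an `n_offspring` column (0, 1 or 2).
#' @export
select_breeders <- function(pairs, quota, migrant_bias = TRUE) {
  stopifnot(quota >= 0)
  n <- nrow(pairs)
  if (n == 0L) {
    pairs$n_offspring <- integer(0)
    return(pairs)
  }
  if (migrant_bias && any(pairs$has_migrant)) {
    # stable reorder keeps the (already random) within-tier order
    pairs <- pairs[order(!pairs$has_migrant), , drop = FALSE]
  }
  assigned <- pmin(2L, pmax(0L, quota - 2L * (seq_len(n) - 1L)))
  pairs$n_offspring <- as.integer(assigned)
  pairs
}

#' Create the assigned offspring
#'
#' Produces each breeding pair's assigned offspring by Mendelian
#' transmission (one uniformly chosen allele copy per parent per locus),
#' assigns sex by a fair coin, applies newborn mutation, and updates the
#' parents' lifetime-reproductive-success counters (mates counted once per
#' new partner).  Newborns enter at age 0 with resident origin.
#'
#' @param pop A [population_state].
#' @param breeders Pairs with `n_offspring` from [select_breeders()].
#' @return Invisibly, a list with `births`, `n_effective_parents` (distinct
#'   individuals with at least one offspring this year),
#'   `n_effective_migrants` (migrants among them) and `newborn_rows`.
#' @export
reproduce <- function(pop, breeders) {
  sel <- which(breeders$n_offspring > 0L)
  fem <- breeders$female[sel]
  mal <- breeders$male[sel]
  noff <- breeders$n_offspring[sel]
  births <- sum(noff)
  if (births == 0L)
    return(invisible(list(births = 0L, n_effective_parents = 0L,
                          n_effective_migrants = 0L,
                          newborn_rows = integer(0))))
  mothers <- rep(fem, noff)
  fathers <- rep(mal, noff)
  if (any(pop$sex[fem] != SEX_FEMALE) || any(pop$sex[mal] != SEX_MALE) ||
      any(!pop$alive[c(fem, mal)]))
    stop("breeding pairs must be alive and of opposite sex")
  slots <- .alloc_slots(pop, births)
  .make_offspring(pop$G1, pop$G2, mothers, fathers, slots)
  sex <- c(SEX_FEMALE, SEX_MALE)[1L + (runif(births) >= 0.5)]
  .register_individuals(pop, slots, sex, 0L, ORIGIN_RESIDENT,
                        pop$id[mothers], pop$id[fathers])
  mutate_population(pop, slots)
  parents <- unique(c(fem, mal))
  if (pop$track_lrs) {
    lrs <- pop$lrs
    mid <- pop$id[fem]; fid <- pop$id[mal]
    for (i in seq_along(mid)) {
      lrs$offspring[mid[i]] <- lrs$offspring[mid[i]] + noff[i]
      lrs$offspring[fid[i]] <- lrs$offspring[fid[i]] + noff[i]
      key <- paste0(mid[i], "_", fid[i])
      if (is.null(pop$pair_seen[[key]])) {
        pop$pair_seen[[key]] <- TRUE
        lrs$mates[mid[i]] <- lrs$mates[mid[i]] + 1L
        lrs$mates[fid[i]] <- lrs$mates[fid[i]] + 1L
      }
    }
  }
  invisible(list(
    births = as.integer(births),
    n_effective_parents = length(parents),
    n_effective_migrants = sum(pop$origin[parents] == ORIGIN_MIGRANT),
    newborn_rows = slots))
}
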