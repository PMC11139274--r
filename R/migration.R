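#' Migration schedule
#'
#' Builds the year-by-year migrant counts for the four connectivity regimes:
#' `"none"` (no movement), `"one_per_generation"` (one migrant every year of
#' the run — the model's generation time is the 1-year age of maturity),
#' `"burst"` (a single translocation of 100 individuals) and `"pulse"` (four
#' translocations of 25).  Burst and pulse events are timed either during
#' habitat restoration (burst year 125; pulses 125, 140, 155, 170) or after
#' restoration completes (burst year 151; pulses 151, 165, 181, 195).
#'
#' @param regime One of `"none"`, `"one_per_generation"`, `"burst"`,
#'   `"pulse"`.
#' @param timing `"during_restoration"` or `"after_restoration"`; required
#'   for burst/pulse and disallowed otherwise.
#' @param years Total run length (default 350).
#' @param event_years,event_sizes Optional explicit event map overriding the
#'   regime defaults (used by down-scaled demo scenarios).
#' @return A `migration_schedule` with an `events` map (named integer
#'   vector, year -> migrant count).
#' @examples
#' build_schedule("pulse", "after_restoration")$events
#' # 151 165 181 195
#' #  25  25  25  25
#' @export
build_schedule <- function(regime = c("none", "one_per_generation", "burst",
                                      "pulse"),
                           timing = NULL, years = 350,
                           event_years = NULL, event_sizes = NULL) {
  regime <- match.arg(regime)
  if (regime %in% c("none", "one_per_generation")) {
    if (!is.null(timing))
      stop("timing applies only to burst and pulse regimes")
  } else if (is.null(event_years)) {
    if (is.null(timing)) stop("burst/pulse regimes require a timing")
    timing <- match.arg(timing, c("during_restoration", "after_restoration"))
  }
  if (is.null(event_years)) {
    events <- switch(regime,
      none = integer(0),
      one_per_generation = setNames(rep(1L, years), seq_len(years)),
      burst = setNames(100L,
                       if (timing == "during_restoration") 125L else 151L),
      pulse = setNames(rep(25L, 4),
                       if (timing == "during_restoration")
                         c(125L, 140L, 155L, 170L)
                       else c(151L, 165L, 181L, 195L)))
  } else {
    if (length(event_years) != length(event_sizes))
      stop("event_years and event_sizes must have equal length")
    events <- setNames(as.integer(event_sizes), as.integer(event_years))
  }
  events <- events[as.integer(names(events)) <= years]
  structure(list(regime = regime, timing = timing, years = years,
                 events = events),
            class = "migration_schedule")
}

#' @export
print.migration_schedule <- function(x, ...) {
  cat("Migration schedule:", x$regime,
      if (!is.null(x$timing)) paste0("(", x$timing, ")"), "\n")
  if (length(x$events) && x$regime != "one_per_generation") {
    cat("  events:",
        paste(sprintf("year %s: %d", names(x$events), x$events),
              collapse = ", "), "\n")
  } else if (x$regime == "one_per_generation") {
    cat("  1 migrant every year, years 1-", x$years, "\n", sep = "")
  }
  invisible(x)
}

#' Migrants scheduled for a year
#' @param schedule A [build_schedule()] result.
#' @param year Simulation year.
#' @return Integer migrant count (0 when none scheduled).
#' @export
migrants_at <- function(schedule, year) {
  stopifnot(inherits(schedule, "migration_schedule"))
  hit <- schedule$events[as.character(year)]
  if (is.na(hit)) 0L else as.integer(hit)
}

#' Transfer migrants from the source to the recipient population
#'
#' Samples `n` mature individuals uniformly without replacement from the
#' source population, removes them there, and appends them to the recipient
#' with origin `migrant` and the arrival year recorded.  Genotype rows move
#' verbatim — a translocation, not a re-draw.  If fewer than `n` mature
#' source individuals exist, all available are moved with a warning; an
#' extirpated source contributes none.
#'
#' @param source,recipient [population_state] environments sharing a genome
#'   spec.
#' @param n Number of migrants requested (>= 0).
#' @param year Arrival year recorded on the migrants.
#' @return Invisibly, the recipient-side storage rows of the migrants.
#' @export
transfer_migrants <- function(source, recipient, n, year = recipient$year) {
  stopifnot(n >= 0)
  if (n == 0L) return(invisible(integer(0)))
  if (source$extirpated || population_size(source) == 0L) {
    warning("source population unavailable; no migrants transferred")
    return(invisible(integer(0)))
  }
  mature <- which(source$alive & source$age >= 1L)
  k <- min(n, length(mature))
  if (k < n)
    warning(sprintf("only %d mature source individuals available (%d requested)",
                    k, n))
  if (k == 0L) return(invisible(integer(0)))
  take <- mature[sample.int(length(mature), k)]
  dest <- .alloc_slots(recipient, k)
  .copy_columns(source$G1, take, recipient$G1, dest)
  .copy_columns(source$G2, take, recipient$G2, dest)
  .register_individuals(recipient, dest, source$sex[take], source$age[take],
                        ORIGIN_MIGRANT, 0L, 0L,
                        arrival = as.integer(year))
  # translocation is not mortality: remove from source without a death record
  source$alive[take] <- FALSE
  if (source$has_mutants) recipient$has_mutants <- TRUE
  invisible(dest)
}
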