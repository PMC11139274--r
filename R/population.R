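#' Population state
#'
#' A population is stored as an environment (reference semantics): the
#' per-individual attribute vectors and the genotype store are preallocated
#' with spare capacity, an `alive` mask marks occupied slots, and slots of
#' removed individuals are recycled for newborns.  The genotype store keeps
#' the two allele matrices transposed (loci as rows, individuals as
#' columns) in single-byte encoding so that per-individual operations touch
#' contiguous memory; it is internal — use [genotypes()] for a value-
#' semantics [genotype_table()] view and [population_snapshot()] for the
#' individual table.  All mutating operations ([age_population()], the
#' mortality steps, [reproduce()], [transfer_migrants()]) update the state
#' in place and invisibly return it.
#'
#' Each individual has a persistent integer id (never reused within a
#' population), a sex, an age in whole years, an origin flag (resident or
#' translocated migrant; offspring of migrants are residents — ancestry is
#' tracked genetically), optional parent ids, and lifetime-reproductive-
#' success counters (number of distinct mates, offspring, and offspring
#' that survived to maturity) kept when `track_lrs` is on.
#'
#' @name population_state
NULL

.new_population_env <- function(spec, label, cap, track_lrs) {
  pop <- new.env(parent = emptyenv())
  pop$spec <- spec
  pop$label <- label
  pop$cap <- cap
  pop$alive <- logical(cap)
  pop$sex <- integer(cap)
  pop$age <- integer(cap)
  pop$origin <- integer(cap)
  pop$arrival <- rep(NA_integer_, cap)
  pop$id <- integer(cap)
  pop$pid1 <- integer(cap)
  pop$pid2 <- integer(cap)
  pop$checked <- logical(cap)
  pop$G1 <- matrix(as.raw(0), spec$n_loci, cap)
  pop$G2 <- matrix(as.raw(0), spec$n_loci, cap)
  pop$next_id <- 1L
  pop$year <- 0L
  pop$has_mutants <- FALSE
  pop$extirpated <- FALSE
  pop$deaths_year <- 0L
  pop$track_lrs <- track_lrs
  if (track_lrs) {
    pop$lrs <- new.env(parent = emptyenv())
    pop$lrs$n <- 0L
    for (f in c("born", "death", "mates", "offspring", "matured", "origin",
                "sex"))
      assign(f, integer(256L), envir = pop$lrs)
    pop$pair_seen <- new.env(parent = emptyenv(), hash = TRUE)
  }
  class(pop) <- "population_state"
  pop
}

.grow_population <- function(pop, need) {
  new_cap <- pop$cap
  while (new_cap < need) new_cap <- new_cap * 2L
  pad <- new_cap - pop$cap
  for (f in c("alive", "checked"))
    assign(f, c(get(f, envir = pop), logical(pad)), envir = pop)
  for (f in c("sex", "age", "origin", "id", "pid1", "pid2"))
    assign(f, c(get(f, envir = pop), integer(pad)), envir = pop)
  pop$arrival <- c(pop$arrival, rep(NA_integer_, pad))
  pop$G1 <- cbind(pop$G1, matrix(as.raw(0), pop$spec$n_loci, pad))
  pop$G2 <- cbind(pop$G2, matrix(as.raw(0), pop$spec$n_loci, pad))
  pop$cap <- new_cap
  invisible(pop)
}

# Storage slots (store columns) for k new individuals.
.alloc_slots <- function(pop, k) {
  free <- which(!pop$alive)
  if (length(free) < k) {
    .grow_population(pop, pop$cap + (k - length(free)))
    free <- which(!pop$alive)
  }
  free[seq_len(k)]
}

.lrs_grow <- function(lrs, need) {
  cur <- length(lrs$born)
  if (need <= cur) return(invisible(NULL))
  new_len <- cur
  while (new_len < need) new_len <- new_len * 2L
  for (f in c("born", "death", "mates", "offspring", "matured", "origin",
              "sex")) {
    v <- get(f, envir = lrs)
    length(v) <- new_len
    v[is.na(v)] <- 0L
    assign(f, v, envir = lrs)
  }
  invisible(NULL)
}

# Register k new individuals in slots; returns their persistent ids.
.register_individuals <- function(pop, slots, sex, age, origin, pid1, pid2,
                                  arrival = NA_integer_) {
  k <- length(slots)
  ids <- pop$next_id + seq_len(k) - 1L
  pop$next_id <- pop$next_id + k
  pop$alive[slots] <- TRUE
  pop$sex[slots] <- sex
  pop$age[slots] <- age
  pop$origin[slots] <- origin
  pop$arrival[slots] <- arrival
  pop$id[slots] <- ids
  pop$pid1[slots] <- pid1
  pop$pid2[slots] <- pid2
  pop$checked[slots] <- age >= 1L
  if (pop$track_lrs) {
    lrs <- pop$lrs
    .lrs_grow(lrs, max(ids))
    lrs$n <- max(lrs$n, max(ids))
    lrs$born[ids] <- pop$year
    lrs$death[ids] <- NA_integer_
    lrs$origin[ids] <- origin
    lrs$sex[ids] <- sex
  }
  ids
}

.kill_rows <- function(pop, slots) {
  if (!length(slots)) return(invisible(pop))
  pop$alive[slots] <- FALSE
  pop$deaths_year <- pop$deaths_year + length(slots)
  if (pop$track_lrs) pop$lrs$death[pop$id[slots]] <- pop$year
  invisible(pop)
}

#' Initialize a founder population
#'
#' Creates `n` founders at carrying capacity: sex assigned by a fair coin,
#' age drawn from a Poisson distribution centered on the age of maturity
#' (1 year) and truncated to \[0, 9\] so no founder is removed on the first
#' time step, and each neutral allele copy drawn Bernoulli with the locus's
#' founding frequency (Hardy-Weinberg founding, as in [init_genotypes()]);
#' migrant-diagnostic loci are fixed for the population's diagnostic allele
#' and conserved loci are homozygous reference.
#'
#' @param spec A [genome_spec()].
#' @param label `"recipient"` or `"source"`.
#' @param n Number of founders (> 0); the study-scale defaults are 1000
#'   recipients and 5000 source individuals.
#' @param freqs Founding frequencies from [draw_founding_frequencies()].
#' @param seed Optional integer seed.
#' @param track_lrs Keep per-individual lifetime-reproductive-success
#'   records (default TRUE).
#' @param cap Initial slot capacity (defaults to headroom above `n`).
#' @return A [population_state] environment.
#' @examples
#' spec <- genome_spec(n_neutral = 20, n_migrant = 5, n_conserved = 5)
#' f <- draw_founding_frequencies(spec, seed = 1)
#' pop <- initialize_population(spec, "recipient", 50, f, seed = 2)
#' population_size(pop)
#' @export
initialize_population <- function(spec, label = c("recipient", "source"), n,
                                  freqs, seed = NULL, track_lrs = TRUE,
                                  cap = NULL) {
  label <- match.arg(label)
  stopifnot(inherits(spec, "genome_spec"),
            inherits(freqs, "founding_frequencies"))
  n <- as.integer(n)
  if (n <= 0L) stop("n must be positive")
  if (!is.null(seed)) set.seed(seed)
  if (is.null(cap)) cap <- max(64L, as.integer(2^ceiling(log2(n * 1.6))))
  pop <- .new_population_env(spec, label, cap, track_lrs)
  slots <- seq_len(n)
  p <- freqs$p_alt[, label]
  .fill_founder_alleles(pop$G1, slots, p)
  .fill_founder_alleles(pop$G2, slots, p)
  sex <- ifelse(runif(n) < 0.5, SEX_FEMALE, SEX_MALE)
  age <- pmin(rpois(n, 1), 9L)
  .register_individuals(pop, slots, as.integer(sex), as.integer(age),
                        ORIGIN_RESIDENT, 0L, 0L)
  pop
}

#' @export
print.population_state <- function(x, ...) {
  cat(sprintf("<population_state '%s'> year %d: %d alive (%d slot capacity)%s\n",
              x$label, x$year, population_size(x), x$cap,
              if (x$extirpated) " [extirpated]" else ""))
  invisible(x)
}

#' Census size (number of live individuals)
#' @param pop A [population_state].
#' @return Integer census count.
#' @export
population_size <- function(pop) sum(pop$alive)

#' Storage slots of live individuals
#' @param pop A [population_state].
#' @return Integer vector of occupied storage slots.
#' @export
alive_rows <- function(pop) which(pop$alive)

#' Extract the live individuals' genotypes as a value-semantics table
#' @param pop A [population_state].
#' @return A [genotype_table()] with one row per live individual, in slot
#'   order of the internal storage.
#' @export
genotypes <- function(pop) {
  idx <- alive_rows(pop)
  L <- pop$spec$n_loci
  to_int <- function(g) {
    m <- matrix(as.integer(g[, idx, drop = FALSE]), L, length(idx))
    t(m)
  }
  genotype_table(to_int(pop$G1), to_int(pop$G2), pop$spec)
}

#' Tabular snapshot of the live individuals
#' @param pop A [population_state].
#' @return A data frame with id, sex, age, origin, parent ids, arrival year
#'   and (when tracked) LRS counters; one row per live individual.
#' @export
population_snapshot <- function(pop) {
  slots <- alive_rows(pop)
  out <- data.frame(
    id = pop$id[slots],
    sex = c("female", "male")[pop$sex[slots]],
    age = pop$age[slots],
    origin = c("resident", "migrant")[pop$origin[slots] + 1L],
    parent1 = ifelse(pop$pid1[slots] == 0L, NA_integer_, pop$pid1[slots]),
    parent2 = ifelse(pop$pid2[slots] == 0L, NA_integer_, pop$pid2[slots]),
    arrival_year = pop$arrival[slots]
  )
  if (pop$track_lrs) {
    ids <- pop$id[slots]
    out$lrs_mates <- pop$lrs$mates[ids]
    out$lrs_offspring <- pop$lrs$offspring[ids]
    out$lrs_offspring_matured <- pop$lrs$matured[ids]
  }
  out
}

#' Lifetime reproductive success records
#'
#' Returns the accumulated per-individual records (living and dead) of a
#' population with `track_lrs` enabled: birth and death year, origin, sex,
#' number of distinct mates, offspring produced, and offspring that
#' survived to maturity.
#'
#' @param pop A [population_state] with LRS tracking.
#' @return A data frame with one row per individual ever alive.
#' @export
lrs_records <- function(pop) {
  if (!pop$track_lrs) stop("population was created with track_lrs = FALSE")
  lrs <- pop$lrs
  n <- lrs$n
  idx <- seq_len(n)
  data.frame(id = idx, born = lrs$born[idx], death = lrs$death[idx],
             sex = c("female", "male")[pmax(lrs$sex[idx], 1L)],
             origin = c("resident", "migrant")[lrs$origin[idx] + 1L],
             mates = lrs$mates[idx], offspring = lrs$offspring[idx],
             offspring_matured = lrs$matured[idx])
}

#' Advance every live individual's age by one year
#'
#' Newborns enter at age 0 and are first aged at the start of the following
#' year.
#'
#' @param pop A [population_state].
#' @return The population, invisibly (modified in place).
#' @export
age_population <- function(pop) {
  slots <- alive_rows(pop)
  pop$age[slots] <- pop$age[slots] + 1L
  invisible(pop)
}

#' Age-dependent mortality
#'
#' Each live individual dies with probability `age / max_lifespan`; any
#' individual at or beyond the maximum lifespan is removed deterministically
#' (so nobody survives past age nine under the default lifespan of 10).
#'
#' @param pop A [population_state].
#' @param max_lifespan Maximum lifespan in years (default 10).
#' @return The population, invisibly (modified in place).
#' @export
apply_age_mortality <- function(pop, max_lifespan = 10) {
  slots <- alive_rows(pop)
  if (!length(slots)) return(invisible(pop))
  p <- pmin(1, pop$age[slots] / max_lifespan)
  die <- runif(length(slots)) < p
  .kill_rows(pop, slots[die])
  invisible(pop)
}

.conserved_load <- function(pop, slots) {
  .mutant_load_counts(pop$G1, pop$G2, slots, pop$spec$idx_conserved)
}

# Mutation-load hazard: zero cost at c = 0 and increasing in c.
.load_hazard <- function(count) 1 - 1 / (count + 1)

#' Yearly mutation-cost mortality
#'
#' Each live individual carrying `m >= 1` mutated allele copies at conserved
#' loci dies with probability `1 - 1/(m + 1)`; individuals with no conserved
#' mutations are unaffected.  At the default mutation rates this hazard
#' fires essentially never; it matters under elevated rates.
#'
#' @param pop A [population_state].
#' @return The population, invisibly (modified in place).
#' @export
apply_mutation_mortality <- function(pop) {
  if (!pop$has_mutants) return(invisible(pop))
  slots <- alive_rows(pop)
  if (!length(slots)) return(invisible(pop))
  m <- .conserved_load(pop, slots)[, 1]
  cand <- m >= 1L
  if (any(cand)) {
    die <- runif(sum(cand)) < .load_hazard(m[cand])
    .kill_rows(pop, slots[cand][die])
  } else {
    # no live carrier left: the mutant lineage was purged, so the load
    # scans can be skipped again until a new conserved mutation arises
    pop$has_mutants <- FALSE
  }
  invisible(pop)
}

#' One-time maturity viability check
#'
#' In the year an individual's age reaches maturity (1 year) it is checked
#' once: carrying `d >= 1` deleterious (homozygous-mutant) conserved loci
#' it dies with probability `1 - 1/(d + 1)`; with none it survives the
#' check.  Survivors are credited to their parents' matured-offspring
#' counters when LRS tracking is on.
#'
#' @param pop A [population_state].
#' @return The population, invisibly (modified in place).
#' @export
apply_maturity_viability <- function(pop) {
  slots <- which(pop$alive & !pop$checked & pop$age >= 1L)
  if (!length(slots)) return(invisible(pop))
  pop$checked[slots] <- TRUE
  survivors <- slots
  if (pop$has_mutants) {
    d <- .conserved_load(pop, slots)[, 2]
    cand <- d >= 1L
    if (any(cand)) {
      die <- runif(sum(cand)) < .load_hazard(d[cand])
      killed <- slots[cand][die]
      .kill_rows(pop, killed)
      survivors <- setdiff(slots, killed)
    }
  }
  if (pop$track_lrs && length(survivors)) {
    pids <- c(pop$pid1[survivors], pop$pid2[survivors])
    pids <- pids[pids > 0L]
    if (length(pids)) {
      tab <- tabulate(pids, nbins = pop$lrs$n)
      nz <- which(tab > 0L)
      pop$lrs$matured[nz] <- pop$lrs$matured[nz] + tab[nz]
    }
  }
  invisible(pop)
}

#' Yearly mutation of standing individuals
#'
#' Applies class-rate mutation to the listed individuals (default: all live
#' individuals) of the population's genotype store, in place: the number of
#' mutated allele slots per class is drawn from the binomial exactly
#' equivalent to independent per-copy Bernoulli trials and the slots placed
#' uniformly.
#'
#' @param pop A [population_state].
#' @param slots Storage slots to mutate (default: live individuals).
#' @return The population, invisibly.
#' @export
mutate_population <- function(pop, slots = alive_rows(pop)) {
  if (!length(slots)) return(invisible(pop))
  spec <- pop$spec
  for (cls in list(list(cols = c(spec$idx_neutral, spec$idx_migrant),
                        mu = spec$mu_neutral),
                   list(cols = spec$idx_conserved, mu = spec$mu_conserved))) {
    hits <- .draw_mutation_slots(length(slots), cls$cols, cls$mu,
                                 rows = slots)
    if (!is.null(hits)) {
      one <- hits$copy == 1L
      if (any(one))
        .set_cells(pop$G1, hits$col[one], hits$row[one], 2L)
      if (any(!one))
        .set_cells(pop$G2, hits$col[!one], hits$row[!one], 2L)
      if (any(hits$col %in% spec$idx_conserved)) pop$has_mutants <- TRUE
    }
  }
  invisible(pop)
}
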