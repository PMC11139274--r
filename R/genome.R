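#' Genome layout specification
#'
#' Defines the diploid SNP genome carried by every simulated individual.  Loci
#' fall in three classes: putatively neutral SNPs used for diversity and
#' divergence monitoring, migrant-diagnostic SNPs fixed for alternate alleles
#' in the two founding populations (used to measure migrant ancestry), and
#' selectively constrained ("conserved") SNPs at which mutations carry a
#' fitness cost.  Allele states are coded `0` (reference / recipient
#' diagnostic), `1` (alternate / source diagnostic) and `2` (mutant, an
#' absorbing third state so that constrained-site mutation counting never
#' confuses standing variation with new mutations).
#'
#' @param n_neutral,n_migrant,n_conserved Locus counts per class (defaults
#'   1000/100/100, i.e. a 1200-SNP genome).
#' @param maf_recipient,maf_source Closed intervals (length-2 numeric) from
#'   which founding minor allele frequencies of neutral loci are drawn
#'   uniformly, per population.  Bounds must lie in (0, 0.5].
#' @param mu_neutral Per-allele-copy, per-year mutation probability at neutral
#'   and migrant-diagnostic loci (default 2.2e-9, a mammalian-like rate).
#' @param constraint_u Selective constraint multiplier for conserved loci; the
#'   conserved-site rate is `mu_neutral * constraint_u` (default 2.2, giving
#'   4.84e-9).
#' @return A `genome_spec` object: locus counts, class column indices,
#'   mutation rates and founding frequency ranges.
#' @examples
#' spec <- genome_spec()
#' spec$mu_conserved  # 4.84e-9
#' @export
genome_spec <- function(n_neutral = 1000L, n_migrant = 100L,
                        n_conserved = 100L,
                        maf_recipient = c(0.05, 0.15),
                        maf_source = c(0.05, 0.15),
                        mu_neutral = 2.2e-9, constraint_u = 2.2) {
  n_neutral <- as.integer(n_neutral)
  n_migrant <- as.integer(n_migrant)
  n_conserved <- as.integer(n_conserved)
  if (any(c(n_neutral, n_migrant, n_conserved) <= 0L))
    stop("all locus counts must be positive")
  check_maf <- function(r, what) {
    if (length(r) != 2L || !is.numeric(r) || any(!is.finite(r)))
      stop(what, " must be a finite numeric interval of length 2")
    if (r[1] > r[2]) stop(what, ": lower bound exceeds upper bound")
    if (r[1] <= 0 || r[2] > 0.5)
      stop(what, " bounds must lie in (0, 0.5]")
    as.numeric(r)
  }
  maf_recipient <- check_maf(maf_recipient, "maf_recipient")
  maf_source <- check_maf(maf_source, "maf_source")
  if (!is.numeric(mu_neutral) || mu_neutral < 0 || mu_neutral > 1)
    stop("mu_neutral must be a probability")
  if (!is.numeric(constraint_u) || constraint_u < 0)
    stop("constraint_u must be non-negative")
  mu_conserved <- mu_neutral * constraint_u
  if (mu_conserved > 1) stop("mu_neutral * constraint_u exceeds 1")
  n_loci <- n_neutral + n_migrant + n_conserved
  structure(list(
    n_neutral = n_neutral, n_migrant = n_migrant, n_conserved = n_conserved,
    n_loci = n_loci,
    idx_neutral = seq_len(n_neutral),
    idx_migrant = n_neutral + seq_len(n_migrant),
    idx_conserved = n_neutral + n_migrant + seq_len(n_conserved),
    classes = rep(c("neutral", "migrant", "conserved"),
                  times = c(n_neutral, n_migrant, n_conserved)),
    maf_recipient = maf_recipient, maf_source = maf_source,
    mu_neutral = mu_neutral, constraint_u = constraint_u,
    mu_conserved = mu_conserved
  ), class = "genome_spec")
}

#' @export
print.genome_spec <- function(x, ...) {
  cat("Genome specification:", x$n_loci, "SNP loci\n")
  cat("  neutral:  ", x$n_neutral,
      sprintf("  (founding MAF recipient %.2f-%.2f, source %.2f-%.2f)\n",
              x$maf_recipient[1], x$maf_recipient[2],
              x$maf_source[1], x$maf_source[2]))
  cat("  migrant-diagnostic:", x$n_migrant, "\n")
  cat("  conserved:", x$n_conserved, "\n")
  cat(sprintf("  mutation rates: neutral %.3g, conserved %.3g per allele copy per year\n",
              x$mu_neutral, x$mu_conserved))
  invisible(x)
}

.locus_cols <- function(spec, loci) {
  loci <- match.arg(loci, c("neutral", "migrant", "conserved", "neutral+migrant",
                            "all"), several.ok = FALSE)
  switch(loci,
         neutral = spec$idx_neutral,
         migrant = spec$idx_migrant,
         conserved = spec$idx_conserved,
         `neutral+migrant` = c(spec$idx_neutral, spec$idx_migrant),
         all = seq_len(spec$n_loci))
}

#' Draw founding allele frequencies
#'
#' Draws one founding frequency per neutral locus, uniformly from each
#' population's configured minor-allele-frequency interval.  When the two
#' populations share the same interval a single draw per locus is used for
#' both (the same minor allele at the same frequency in both populations);
#' when the intervals differ the draws are independent.  Migrant-diagnostic
#' loci are fixed: frequency 0 of the source-diagnostic allele in the
#' recipient, 1 in the source.  Conserved loci carry no founding variation.
#'
#' @param spec A [genome_spec()].
#' @param seed Optional integer seed (uses the current RNG stream when NULL).
#' @return A `founding_frequencies` object with element `p_alt`, an
#'   `n_loci x 2` matrix (columns `recipient`, `source`) of founding
#'   frequencies of the state-1 allele, and `shared`, whether the neutral
#'   draws were shared between populations.
#' @examples
#' f <- draw_founding_frequencies(genome_spec(), seed = 1)
#' range(f$p_alt[1:1000, "recipient"])  # inside [0.05, 0.15]
#' @export
draw_founding_frequencies <- function(spec, seed = NULL) {
  stopifnot(inherits(spec, "genome_spec"))
  if (!is.null(seed)) set.seed(seed)
  shared <- isTRUE(all.equal(spec$maf_recipient, spec$maf_source))
  p_rec <- runif(spec$n_neutral, spec$maf_recipient[1], spec$maf_recipient[2])
  p_src <- if (shared) p_rec else
    runif(spec$n_neutral, spec$maf_source[1], spec$maf_source[2])
  p_alt <- matrix(0, spec$n_loci, 2,
                  dimnames = list(NULL, c("recipient", "source")))
  p_alt[spec$idx_neutral, "recipient"] <- p_rec
  p_alt[spec$idx_neutral, "source"] <- p_src
  p_alt[spec$idx_migrant, "source"] <- 1
  structure(list(p_alt = p_alt, shared = shared, spec = spec),
            class = "founding_frequencies")
}

#' Construct a genotype table
#'
#' A genotype table is a pair of integer allele matrices (`A1`, `A2`, one row
#' per individual, one column per locus; states 0/1/2) together with the
#' genome specification describing the locus classes.
#'
#' @param A1,A2 Integer matrices of identical dimensions with values in
#'   \{0, 1, 2\}.
#' @param spec A [genome_spec()] whose total locus count matches `ncol(A1)`.
#' @return A `genotype_table` object.
#' @export
genotype_table <- function(A1, A2, spec) {
  A1 <- as.matrix(A1); A2 <- as.matrix(A2)
  storage.mode(A1) <- "integer"; storage.mode(A2) <- "integer"
  if (!identical(dim(A1), dim(A2)))
    stop("A1 and A2 must have identical dimensions")
  if (ncol(A1) != spec$n_loci)
    stop("genotype table has ", ncol(A1), " loci but the genome spec has ",
         spec$n_loci)
  if (nrow(A1) > 0 && (min(A1, A2) < 0L || max(A1, A2) > 2L))
    stop("allele states must be coded 0, 1 or 2")
  structure(list(A1 = A1, A2 = A2, spec = spec), class = "genotype_table")
}

#' @export
print.genotype_table <- function(x, ...) {
  cat("Genotype table:", nrow(x$A1), "individuals x", ncol(x$A1), "loci\n")
  invisible(x)
}

#' Initialize founder genotypes
#'
#' Each neutral allele copy is the alternate allele independently with its
#' locus's founding frequency (Hardy-Weinberg founding, so realized founding
#' heterozygosity is approximately `2p(1-p)`).  Migrant-diagnostic loci are
#' homozygous for the population's diagnostic allele; conserved loci are
#' homozygous reference in all founders.
#'
#' @param spec A [genome_spec()].
#' @param n Number of founders (> 0).
#' @param population `"recipient"` or `"source"`.
#' @param freqs Founding frequencies from [draw_founding_frequencies()].
#' @param seed Optional integer seed.
#' @return A [genotype_table()] with `n` rows.
#' @examples
#' spec <- genome_spec(n_neutral = 10, n_migrant = 4, n_conserved = 4)
#' f <- draw_founding_frequencies(spec, seed = 1)
#' gt <- init_genotypes(spec, 5, "source", f, seed = 2)
#' all(gt$A1[, spec$idx_migrant] == 1L)  # source-diagnostic alleles
#' @export
init_genotypes <- function(spec, n, population = c("recipient", "source"),
                           freqs, seed = NULL) {
  population <- match.arg(population)
  stopifnot(inherits(spec, "genome_spec"),
            inherits(freqs, "founding_frequencies"))
  n <- as.integer(n)
  if (n <= 0L) stop("n must be positive")
  if (!is.null(seed)) set.seed(seed)
  p <- freqs$p_alt[, population]
  A1 <- .draw_allele_matrix(n, p, spec)
  A2 <- .draw_allele_matrix(n, p, spec)
  genotype_table(A1, A2, spec)
}

# One allele copy per individual per locus: Bernoulli(p_locus) of state 1.
# Only neutral loci need randomness; diagnostic/conserved loci are fixed.
.draw_allele_matrix <- function(n, p, spec) {
  a <- matrix(0L, n, spec$n_loci)
  idx <- spec$idx_neutral
  a[, idx] <- runif(n * length(idx)) < rep(p[idx], each = n)
  fixed <- which(p == 1)
  if (length(fixed)) a[, fixed] <- 1L
  storage.mode(a) <- "integer"
  a
}

#' Apply one round of mutation to a genotype table
#'
#' Every allele copy independently mutates to the absorbing mutant state
#' (coded 2) with its class rate: `mu_neutral` at neutral and
#' migrant-diagnostic loci, `mu_conserved` at conserved loci.  The number of
#' mutated allele slots per class is drawn from the exactly equivalent
#' binomial distribution and the slots placed uniformly, so the realized
#' process matches per-copy Bernoulli trials at any rate.
#'
#' @param gt A [genotype_table()].
#' @param spec Genome spec (defaults to the table's own).
#' @param seed Optional integer seed.
#' @return The mutated genotype table (value semantics: the input is not
#'   modified).
#' @export
mutate_genotypes <- function(gt, spec = gt$spec, seed = NULL) {
  stopifnot(inherits(gt, "genotype_table"))
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(gt$A1)
  if (n == 0L) return(gt)
  A1 <- gt$A1 + 0L  # force copies so the input table is untouched
  A2 <- gt$A2 + 0L
  for (cls in list(list(cols = c(spec$idx_neutral, spec$idx_migrant),
                        mu = spec$mu_neutral),
                   list(cols = spec$idx_conserved, mu = spec$mu_conserved))) {
    hits <- .draw_mutation_slots(n, cls$cols, cls$mu)
    if (!is.null(hits)) {
      one <- hits$copy == 1L
      if (any(one)) A1[cbind(hits$row[one], hits$col[one])] <- 2L
      if (any(!one)) A2[cbind(hits$row[!one], hits$col[!one])] <- 2L
    }
  }
  genotype_table(A1, A2, spec)
}

# Sample mutated allele slots among n individuals x cols x 2 copies.
# Returns NULL when no slot mutates.
.draw_mutation_slots <- function(n, cols, mu, rows = seq_len(n)) {
  n_slots <- 2 * length(rows) * length(cols)
  if (n_slots == 0 || mu <= 0) return(NULL)
  k <- rbinom(1L, n_slots, mu)
  if (k == 0L) return(NULL)
  slots <- if (k == n_slots) seq_len(n_slots) else sample.int(n_slots, k)
  slots <- slots - 1L
  copy <- slots %% 2L + 1L
  rest <- slots %/% 2L
  nr <- length(rows)
  list(copy = copy,
       row = rows[rest %% nr + 1L],
       col = cols[rest %/% nr + 1L])
}

#' Mutant load at conserved loci
#'
#' Counts, per individual, the number of mutated allele copies at conserved
#' loci and the number of conserved loci homozygous for the mutant state.
#' Homozygous-mutant conserved loci are the deleterious genotypes that feed
#' the maturity viability check; the total mutated-copy count feeds the
#' yearly mutation-cost mortality.
#'
#' @param gt A [genotype_table()].
#' @param individuals Optional row indices (default all rows).
#' @return A data frame with columns `mutations` (mutated conserved allele
#'   copies) and `deleterious` (homozygous-mutant conserved loci).
#' @export
count_deleterious <- function(gt, individuals = NULL) {
  stopifnot(inherits(gt, "genotype_table"))
  rows <- if (is.null(individuals)) seq_len(nrow(gt$A1)) else
    as.integer(individuals)
  cons <- gt$spec$idx_conserved
  m1 <- gt$A1[rows, cons, drop = FALSE] == 2L
  m2 <- gt$A2[rows, cons, drop = FALSE] == 2L
  data.frame(mutations = rowSums(m1) + rowSums(m2),
             deleterious = rowSums(m1 & m2))
}

#' Mendelian offspring genotype
#'
#' At every locus the offspring receives one uniformly chosen allele copy
#' from each parent, independently across loci; class-rate mutation is then
#' applied to the newborn genotype.
#'
#' @param gt A [genotype_table()] holding both parents.
#' @param parent_a,parent_b Row indices of the two parents.
#' @param mutate Apply newborn mutation afterwards (default TRUE).
#' @param seed Optional integer seed.
#' @return A one-row [genotype_table()].
#' @export
mendelian_offspring <- function(gt, parent_a, parent_b, mutate = TRUE,
                                seed = NULL) {
  stopifnot(inherits(gt, "genotype_table"))
  if (!is.null(seed)) set.seed(seed)
  L <- ncol(gt$A1)
  gamete <- function(p) {
    g <- gt$A1[p, ]
    take2 <- runif(L) < 0.5
    g[take2] <- gt$A2[p, take2]
    g
  }
  off <- genotype_table(matrix(gamete(parent_a), 1L),
                        matrix(gamete(parent_b), 1L), gt$spec)
  if (mutate) off <- mutate_genotypes(off)
  off
}
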