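# Independent brute-force oracles for the F-statistics, written directly
# from the published definitions as naive per-locus, per-allele loops.
# They share no code with the package's vectorized estimators.

# Weir & Cockerham (1984) theta for two samples, ratio-of-sums aggregation.
# x1a/x1b and x2a/x2b are individuals x loci allele matrices.
wc_theta_oracle <- function(x1a, x1b, x2a, x2b) {
  stopifnot(ncol(x1a) == ncol(x2a))
  num <- den <- 0
  r <- 2
  for (l in seq_len(ncol(x1a))) {
    g1 <- cbind(x1a[, l], x1b[, l])
    g2 <- cbind(x2a[, l], x2b[, l])
    alleles <- unique(c(g1, g2))
    if (length(alleles) < 2) next  # monomorphic in the pooled sample
    n1 <- nrow(g1); n2 <- nrow(g2)
    nbar <- (n1 + n2) / r
    nc <- (r * nbar - (n1^2 + n2^2) / (r * nbar)) / (r - 1)
    for (A in alleles) {
      p1 <- mean(g1 == A)
      p2 <- mean(g2 == A)
      h1 <- mean(rowSums(g1 == A) == 1)  # heterozygotes carrying one copy
      h2 <- mean(rowSums(g2 == A) == 1)
      pbar <- (n1 * p1 + n2 * p2) / (r * nbar)
      s2 <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / ((r - 1) * nbar)
      hbar <- (n1 * h1 + n2 * h2) / (r * nbar)
      a <- nbar / nc *
        (s2 - (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4) / (nbar - 1))
      b <- nbar / (nbar - 1) *
        (pbar * (1 - pbar) - (r - 1) / r * s2 -
           (2 * nbar - 1) / (4 * nbar) * hbar)
      cc <- hbar / 2
      num <- num + a
      den <- den + a + b + cc
    }
  }
  num / den
}

# Nei (1987) F_IS = 1 - mean(Ho)/mean(Hs) over polymorphic loci, with the
# small-sample corrected gene diversity Hs = n/(n-1) (1 - sum p^2 - Ho/2n).
nei_fis_oracle <- function(xa, xb) {
  n <- nrow(xa)
  hos <- hss <- numeric(0)
  for (l in seq_len(ncol(xa))) {
    g <- cbind(xa[, l], xb[, l])
    alleles <- unique(c(g))
    if (length(alleles) < 2) next
    p <- vapply(alleles, function(A) mean(g == A), numeric(1))
    ho <- mean(g[, 1] != g[, 2])
    hs <- n / (n - 1) * (1 - sum(p^2) - ho / (2 * n))
    hos <- c(hos, ho)
    hss <- c(hss, hs)
  }
  if (!length(hos)) return(NA_real_)
  1 - mean(hos) / mean(hss)
}

# Random small genotype table on the 0/1/2 state space.
random_toy_table <- function(n, L, seed, states = 0:2,
                             prob = c(0.5, 0.4, 0.1)) {
  prob <- prob[seq_along(states)]
  set.seed(seed)
  make_toy_genotypes(list(
    A1 = matrix(sample(states, n * L, TRUE, prob), n, L),
    A2 = matrix(sample(states, n * L, TRUE, prob), n, L)))
}

# Founding-frequency + population shorthand for small populations.
small_population <- function(n = 40, label = "recipient", seed = 1,
                             spec = genome_spec(n_neutral = 20,
                                                n_migrant = 10,
                                                n_conserved = 10),
                             track_lrs = TRUE) {
  f <- draw_founding_frequencies(spec, seed = seed)
  initialize_population(spec, label, n, f, seed = seed + 1,
                        track_lrs = track_lrs)
}
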