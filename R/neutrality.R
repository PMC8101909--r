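# Neutrality tests: Tajima's D and Fu's Fs, with p-values from coalescent
# simulation.
#
# p-value conventions (documented, one-tailed lower, as in common practice
# for expansion scanning): p_D = P(D_sim <= D_obs) from genealogies
# simulated conditional on the observed number of segregating sites
# (fixed-S scheme: S mutations placed multinomially on branches in
# proportion to length); p_Fs = P(Fs_sim <= Fs_obs) from genealogies
# simulated at theta equal to the observed mean pairwise differences.
# Fu's Fs is conventionally called significant at the 5% level only when
# p < 0.02.

# Tajima (1989) constants and statistic from n, S and mean pairwise
# differences.
tajima_d_stat <- function(n, S, k_hat) {
  if (S == 0 || n < 4) return(NA_real_)
  i <- seq_len(n - 1)
  a1 <- sum(1 / i); a2 <- sum(1 / i^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1
  e2 <- c2 / (a1^2 + a2)
  (k_hat - S / a1) / sqrt(e1 * S + e2 * S * (S - 1))
}

# Segregating sites and mean raw pairwise differences of an alignment
# (pairwise deletion for the differences; a site is segregating when at
# least two distinct non-missing bases occur).
align_summary_stats <- function(aln) {
  cls <- classify_sites(aln)
  d <- pairwise_distances(aln, "raw")
  n <- nrow(aln)
  k_hat <- sum(d[upper.tri(d)]) / (n * (n - 1) / 2)
  hap <- collapse_haplotypes(aln)
  list(n = n, S = cls$n_variable, k_hat = k_hat,
       k_obs = nrow(hap$haplotypes))
}

#' Tajima's D with simulation p-value
#'
#' `D = (k_hat - S/a1) / sqrt(e1*S + e2*S*(S-1))` with the Tajima (1989)
#' constants; `k_hat` is the mean raw pairwise difference count and `S` the
#' number of segregating sites. The p-value is the lower tail
#' `P(D_sim <= D_obs)` over `n_sim` constant-size coalescent genealogies
#' carrying exactly `S` mutations each (fixed-S scheme).
#'
#' @param aln a `haplo_alignment` (the population subset to test), or
#'   `NULL` if `n`, `S` and `k_hat` are given directly.
#' @param n,S,k_hat summary statistics, used when `aln` is `NULL`.
#' @param n_sim null simulations for the p-value (0 skips).
#' @param seed integer seed.
#' @return list `D`, `p` (`NA` when `S = 0`), `n`, `S`, `k_hat`.
#' @export
tajimas_d <- function(aln = NULL, n = NULL, S = NULL, k_hat = NULL,
                      n_sim = 1000, seed = NULL) {
  if (!is.null(aln)) {
    st <- align_summary_stats(aln)
    n <- st$n; S <- st$S; k_hat <- st$k_hat
  }
  if (n < 4) stop("Tajima's D requires n >= 4", call. = FALSE)
  D <- tajima_d_stat(n, S, k_hat)
  p <- NA_real_
  if (!is.na(D) && n_sim > 0) {
    if (!is.null(seed)) set.seed(seed)
    cst <- demographic_model("constant", theta = 1)
    le <- 0L
    for (b in seq_len(n_sim)) {
      gen <- sim_genealogy(n, cst)
      n_mut <- fixed_s_mutations(branch_lengths(gen), S)
      st <- genealogy_stats(gen, n_mut)
      Db <- tajima_d_stat(n, st$S, st$k_hat)
      if (!is.na(Db) && Db <= D + 1e-12) le <- le + 1L
    }
    p <- (le + 1) / (n_sim + 1)
  }
  list(D = D, p = p, n = n, S = S, k_hat = k_hat)
}

# Place exactly S mutations on branches, multinomially by branch length.
fixed_s_mutations <- function(branch_len, S) {
  if (S == 0) return(integer(length(branch_len)))
  as.integer(stats::rmultinom(1, S, prob = branch_len))
}

# log unsigned Stirling numbers of the first kind, |s(n, 1..n)|,
# by the log-safe recursion |s(n+1,k)| = |s(n,k-1)| + n*|s(n,k)|.
log_stirling_first <- local({
  cache <- new.env(parent = emptyenv())
  function(n) {
    key <- as.character(n)
    if (!is.null(cache[[key]])) return(cache[[key]])
    ls <- 0            # n = 1: |s(1,1)| = 1
    for (m in seq_len(n - 1)) {
      prev <- c(-Inf, ls)              # |s(m, k-1)| term
      stay <- c(ls, -Inf) + log(m)     # m * |s(m, k)| term
      mx <- pmax(prev, stay)
      ls <- mx + log(exp(prev - mx) + exp(stay - mx))
      ls[is.nan(ls)] <- -Inf
    }
    cache[[key]] <- ls
    ls
  }
})

# Pr(K >= k_obs) under the Ewens sampling distribution with parameter theta:
# Pr(K = k) = |s(n,k)| theta^k / (theta (theta+1) ... (theta+n-1)).
ewens_k_tail <- function(n, k_obs, theta) {
  if (k_obs <= 1) return(1)
  ls <- log_stirling_first(n)
  k <- seq_len(n)
  lognum <- ls + k * log(theta)
  logden <- sum(log(theta + 0:(n - 1)))
  logp <- lognum - logden
  sum(exp(logp[k >= k_obs]))
}

#' Fu's Fs with simulation p-value
#'
#' `Fs = log(S' / (1 - S'))` where `S' = Pr(K >= k_obs | theta = k_hat)`
#' under the Ewens sampling distribution; large negative values indicate an
#' excess of haplotypes relative to the pairwise diversity, the signature
#' of demographic expansion. The p-value is `P(Fs_sim <= Fs_obs)` over
#' constant-size coalescent simulations at `theta = k_hat`.
#'
#' @param n sample size.
#' @param k_obs observed number of distinct haplotypes.
#' @param k_hat observed mean pairwise differences (> 0).
#' @param n_sim null simulations for the p-value (0 skips).
#' @param seed integer seed.
#' @return list `Fs`, `p` (`NA` when undefined: `k_obs = 1` or
#'   `k_hat = 0`), `S_prime`.
#' @export
fu_fs <- function(n, k_obs, k_hat, n_sim = 1000, seed = NULL) {
  stopifnot(n >= 2, k_obs >= 1, k_obs <= n)
  if (k_hat <= 0 || k_obs <= 1)
    return(list(Fs = NA_real_, p = NA_real_, S_prime = 1))
  sp <- ewens_k_tail(n, k_obs, k_hat)
  if (sp >= 1 || sp <= 0)
    return(list(Fs = NA_real_, p = NA_real_, S_prime = sp))
  Fs <- log(sp / (1 - sp))
  p <- NA_real_
  if (n_sim > 0) {
    if (!is.null(seed)) set.seed(seed)
    mod <- demographic_model("constant", theta = k_hat)
    le <- 0L
    for (b in seq_len(n_sim)) {
      gen <- sim_genealogy(n, mod)
      n_mut <- drop_mutations(branch_lengths(gen))
      st <- genealogy_stats(gen, n_mut)
      if (st$k_hat <= 0 || st$k_obs <= 1) next
      spb <- ewens_k_tail(n, st$k_obs, st$k_hat)
      if (spb >= 1 || spb <= 0) next
      if (log(spb / (1 - spb)) <= Fs + 1e-12) le <- le + 1L
    }
    p <- (le + 1) / (n_sim + 1)
  }
  list(Fs = Fs, p = p, S_prime = sp)
}

#' Neutrality tests for an alignment subset
#'
#' Convenience wrapper computing the shared summary statistics once and
#' returning both Tajima's D and Fu's Fs with their simulation p-values.
#'
#' @param aln a `haplo_alignment`.
#' @param n_sim null simulations per test.
#' @param seed integer seed.
#' @return list with `n`, `S`, `k_hat`, `k_obs`, `D`, `p_D`, `Fs`, `p_Fs`.
#' @export
neutrality_tests <- function(aln, n_sim = 1000, seed = NULL) {
  st <- align_summary_stats(aln)
  td <- tajimas_d(n = st$n, S = st$S, k_hat = st$k_hat, n_sim = n_sim,
                  seed = seed)
  fs <- fu_fs(st$n, st$k_obs, st$k_hat, n_sim = n_sim,
              seed = if (is.null(seed)) NULL else seed + 1L)
  list(n = st$n, S = st$S, k_hat = st$k_hat, k_obs = st$k_obs,
       D = td$D, p_D = td$p, Fs = fs$Fs, p_Fs = fs$p)
}
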