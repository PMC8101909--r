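# Shared fixtures and independent oracles used across the suite. Every
# oracle here is written as a direct, brute-force restatement of the
# quantity's definition, independent of the package's implementation path.

# Alignment from a named character vector of sequence strings.
aln_from_strings <- function(x, marker = "test") {
  as_alignment(x, marker_name = marker)
}

# Trivial one-site popmap over the given sample ids.
popmap_single <- function(ids) {
  as_popmap(data.frame(sample_id = ids, range = "R", area = "A",
                       site_id = "S", stringsAsFactors = FALSE))
}

# Brute-force Hamming distance between two sequence strings, pairwise
# deletion of non-ACGT sites, by explicit column scan.
oracle_hamming <- function(a, b) {
  av <- strsplit(a, "")[[1]]; bv <- strsplit(b, "")[[1]]
  n <- 0L
  for (i in seq_along(av)) {
    if (av[i] %in% c("A", "C", "G", "T") && bv[i] %in% c("A", "C", "G", "T")
        && av[i] != bv[i]) n <- n + 1L
  }
  n
}

# Brute-force per-column site classification tally.
oracle_classify <- function(aln) {
  m <- unclass(aln)
  n_pi <- n_s <- 0L
  for (j in seq_len(ncol(m))) {
    col <- m[, j]
    col <- col[col %in% c("A", "C", "G", "T")]
    tab <- table(col)
    if (length(tab) >= 2) {
      if (sum(tab >= 2) >= 2) n_pi <- n_pi + 1L else n_s <- n_s + 1L
    }
  }
  list(n_variable = n_pi + n_s, n_pi = n_pi, n_singleton = n_s)
}

# Nucleotide diversity by explicit iteration over all sample pairs, with
# the K2P distances coming from ape (independent implementation):
# pi = n/(n-1) * sum_{i<j} 2 p_i p_j d_ij over haplotypes reduces to the
# plain mean pairwise distance over samples.
oracle_pi <- function(aln) {
  dna <- ape::as.DNAbin(tolower(unclass(aln)))
  d <- ape::dist.dna(dna, model = "K80", pairwise.deletion = TRUE)
  mean(as.vector(d))
}

# Mean raw pairwise differences by explicit pair loop.
oracle_mean_pairdiff <- function(aln) {
  m <- unclass(aln)
  n <- nrow(m)
  tot <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    tot <- tot + sum(m[i, ] != m[j, ] &
                       m[i, ] %in% c("A", "C", "G", "T") &
                       m[j, ] %in% c("A", "C", "G", "T"))
  }
  tot / (n * (n - 1) / 2)
}

# Mismatch histogram by explicit pair loop.
oracle_mismatch <- function(aln) {
  m <- unclass(aln)
  n <- nrow(m)
  v <- integer(0)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    v <- c(v, sum(m[i, ] != m[j, ] &
                    m[i, ] %in% c("A", "C", "G", "T") &
                    m[j, ] %in% c("A", "C", "G", "T")))
  }
  tabulate(v + 1L, nbins = max(v) + 1L) / length(v)
}

# Independent two-level AMOVA decomposition written from the definitional
# sums of squares (explicit double loops, no shared code with amova()).
oracle_amova <- function(d2, pop, grp_of_pop) {
  pops <- unique(pop)
  grp <- grp_of_pop[pop]
  N <- nrow(d2); P <- length(pops); G <- length(unique(grp))
  ss_block <- function(idx) {
    s <- 0
    for (i in idx) for (j in idx) s <- s + d2[i, j]
    s / (2 * length(idx))
  }
  ss_t <- ss_block(seq_len(N))
  ss_p <- sum(vapply(pops, function(p) ss_block(which(pop == p)), 0))
  ss_g <- sum(vapply(unique(grp), function(g) ss_block(which(grp == g)), 0))
  ssd_wp <- ss_p
  ssd_ap <- ss_g - ss_p
  ssd_ag <- ss_t - ss_g
  n_p <- vapply(pops, function(p) sum(pop == p), 0)
  names(n_p) <- pops
  n_g <- vapply(unique(grp), function(g) sum(grp == g), 0)
  names(n_g) <- unique(grp)
  sum_np2_over_g <- sum(vapply(unique(grp), function(g) {
    sum(n_p[unique(pop[grp == g])]^2) / n_g[[g]]
  }, 0))
  n1 <- (N - sum_np2_over_g) / (P - G)
  n2 <- (sum_np2_over_g - sum(n_p^2) / N) / (G - 1)
  n3 <- (N - sum(n_g^2) / N) / (G - 1)
  s2c <- ssd_wp / (N - P)
  s2b <- (ssd_ap / (P - G) - s2c) / n1
  s2a <- (ssd_ag / (G - 1) - s2c - n2 * s2b) / n3
  c(a = s2a, b = s2b, c = s2c)
}

# Full-enumeration probability-mass exact test for a 2x2 table with fixed
# margins (hypergeometric): p = sum of P(table) over tables with
# P <= P(observed).
oracle_exact_2x2 <- function(tab) {
  r1 <- sum(tab[1, ]); c1 <- sum(tab[, 1]); n <- sum(tab)
  lo <- max(0, r1 + c1 - n); hi <- min(r1, c1)
  probs <- vapply(lo:hi, function(a) stats::dhyper(a, c1, n - c1, r1), 0)
  p_obs <- stats::dhyper(tab[1, 1], c1, n - c1, r1)
  sum(probs[probs <= p_obs + 1e-12])
}
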