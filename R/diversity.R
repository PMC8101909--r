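# Within-population diversity: Nei gene (haplotype) diversity with its
# sampling variance, nucleotide diversity from K2P distances, and mean raw
# pairwise differences.

#' Nei haplotype (gene) diversity
#'
#' `H = n/(n-1) * (1 - sum p_i^2)` with `p_i` the haplotype relative
#' frequencies; the variance is Nei's (1987) formula
#' `V = 2/(n(n-1)) * (2(n-2) * (sum p^3 - (sum p^2)^2) + sum p^2 - (sum p^2)^2)`.
#'
#' @param counts positive integer haplotype counts (one entry per haplotype).
#' @return list with `H`, `V_H`, `sd_H`, `n`, `k`.
#' @export
haplotype_diversity <- function(counts) {
  counts <- counts[counts > 0]
  n <- sum(counts)
  if (n < 2) stop("need at least 2 samples", call. = FALSE)
  p <- counts / n
  s2 <- sum(p^2)
  s3 <- sum(p^3)
  H <- n / (n - 1) * (1 - s2)
  V <- 2 / (n * (n - 1)) * (2 * (n - 2) * (s3 - s2^2) + s2 - s2^2)
  list(H = H, V_H = V, sd_H = sqrt(max(V, 0)), n = n, k = length(counts))
}

#' Nucleotide diversity and mean pairwise differences
#'
#' Nucleotide diversity is the bias-corrected average pairwise distance per
#' site between two sampled sequences,
#' `pi = n/(n-1) * sum_{i<j} 2 p_i p_j d_ij`, with `d_ij` the K2P distance
#' (substitutions/site) between haplotypes. The mean number of raw pairwise
#' differences per pair (`k_hat`, the mismatch mean times its bias
#' correction) uses raw difference counts instead.
#'
#' @param table a `haplo_table` (or a named vector of haplotype counts).
#' @param d_k2p `haplo_dist` of K2P distances over the haplotypes.
#' @param d_raw optional `haplo_dist` of raw difference counts; when given,
#'   `k_hat` is returned alongside `pi`.
#' @param counts optional named haplotype counts overriding the table totals
#'   (e.g. a single pooled area).
#' @return list with `pi` (substitutions/site), `pi_pct`, `k_hat`
#'   (`NA` if `d_raw` missing), `n`.
#' @export
nucleotide_diversity <- function(table, d_k2p, d_raw = NULL, counts = NULL) {
  if (is.null(counts)) counts <- haplotype_counts(table)
  counts <- counts[counts > 0]
  n <- sum(counts)
  if (n < 2) stop("need at least 2 samples", call. = FALSE)
  ids <- names(counts)
  if (!all(ids %in% rownames(d_k2p)))
    stop("distance matrix does not cover all haplotypes", call. = FALSE)
  p <- counts / n
  avg_over <- function(d) {
    dd <- d[ids, ids, drop = FALSE]
    # sum over unordered haplotype pairs of 2 p_i p_j d_ij equals the
    # frequency-weighted full double sum divided by 2, diag is zero
    as.numeric(t(p) %*% dd %*% p)
  }
  pi_hat <- n / (n - 1) * avg_over(d_k2p)
  k_hat <- if (is.null(d_raw)) NA_real_ else n / (n - 1) * avg_over(d_raw)
  list(pi = pi_hat, pi_pct = 100 * pi_hat, k_hat = k_hat, n = n)
}

#' Per-area diversity summary
#'
#' Pools samples by area (or by site or range) and reports, per group:
#' sample size, number of haplotypes, gene diversity with its standard
#' deviation, nucleotide diversity (percent) and mean pairwise differences.
#' Groups with fewer than two samples are reported with the statistics set
#' to `NA`.
#'
#' @param aln a `haplo_alignment`.
#' @param popmap a `haplo_popmap` covering the alignment.
#' @param grouping `"area"` (default), `"site_id"` or `"range"`.
#' @return data.frame, one row per group, in order of first appearance.
#' @export
summarize_populations <- function(aln, popmap, grouping = "area") {
  stopifnot(grouping %in% c("area", "site_id", "range"))
  pm <- match_popmap(aln, popmap)
  table <- collapse_haplotypes(aln, popmap)
  d_k2p <- pairwise_distances(table, "k2p")
  d_raw <- pairwise_distances(table, "raw")
  groups <- unique(pm[[grouping]])
  rows <- lapply(groups, function(g) {
    samp <- pm$sample_id[pm[[grouping]] == g]
    cnt <- group_counts(table, samp)
    rng <- unique(pm$range[pm[[grouping]] == g])
    out <- data.frame(range = paste(rng, collapse = "+"), group = g,
                      n = sum(cnt), k = sum(cnt > 0),
                      H = NA_real_, sd_H = NA_real_,
                      pi_pct = NA_real_, k_hat = NA_real_,
                      stringsAsFactors = FALSE)
    if (sum(cnt) >= 2) {
      hd <- haplotype_diversity(cnt)
      nd <- nucleotide_diversity(table, d_k2p, d_raw, counts = cnt)
      out$H <- hd$H; out$sd_H <- hd$sd_H
      out$pi_pct <- nd$pi_pct; out$k_hat <- nd$k_hat
    }
    out
  })
  res <- do.call(rbind, rows)
  names(res)[names(res) == "group"] <- grouping
  res
}

# Haplotype counts restricted to a set of samples.
group_counts <- function(table, sample_ids) {
  mem <- table$membership[names(table$membership) %in% sample_ids]
  cnt <- table(factor(mem, levels = table$haplotypes$haplotype_id))
  stats::setNames(as.integer(cnt), names(cnt))
}
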