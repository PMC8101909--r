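# Hierarchical analysis of molecular variance (AMOVA) on squared pairwise
# distances, after Excoffier, Smouse & Quattro (1992): two-level design
# (groups / populations within groups / within populations) with
# Phi-statistics and permutation p-values.
#
# Distance convention: for raw difference counts the entries of the matrix
# ARE the squared Euclidean distances between haplotype site-indicator
# vectors, so they are used as-is (`squared = TRUE`, the Arlequin
# convention). Set `squared = FALSE` to square the entries first (e.g. for
# model-corrected distances).

# Sum-of-squares pieces from a squared-distance matrix and a grouping
# factor: SS within each block = sum of the block / (2 * block size).
block_ss <- function(d2, f) {
  # rowsum over both dimensions gives per-block pair sums
  b <- rowsum(t(rowsum(d2, f)), f)          # levels x levels
  n <- as.vector(table(f)[rownames(b)])
  list(pair_sums = b, sizes = n, ss = diag(b) / (2 * n))
}

# Variance components for the two-level design.
# pop: population of each sample; grp_of_pop: group of each population.
amova_components <- function(d2, pop, grp_of_pop) {
  N <- nrow(d2)
  pop <- factor(pop)
  pops <- levels(pop)
  grp <- factor(grp_of_pop[pops])
  grp_of_sample <- grp[match(as.character(pop), pops)]
  P <- length(pops); G <- nlevels(grp)

  ss_t <- sum(d2) / (2 * N)
  bp <- block_ss(d2, pop)
  bg <- block_ss(d2, grp_of_sample)
  ssd_wp <- sum(bp$ss)
  ssd_ag <- ss_t - sum(bg$ss)
  ssd_ap <- sum(bg$ss) - sum(bp$ss)

  n_p <- stats::setNames(bp$sizes, rownames(bp$pair_sums))
  n_g <- stats::setNames(bg$sizes, rownames(bg$pair_sums))
  # coefficients of the expected mean squares (unbalanced design)
  sum_np2_by_g <- vapply(levels(grp), function(g) {
    sum(n_p[pops[grp == g]]^2) / n_g[[g]]
  }, 0)
  n1 <- (N - sum(sum_np2_by_g)) / (P - G)
  n2 <- (sum(sum_np2_by_g) - sum(n_p^2) / N) / (G - 1)
  n3 <- (N - sum(n_g^2) / N) / (G - 1)

  df <- c(ag = G - 1, ap = P - G, wp = N - P)
  ms <- c(ag = if (df[["ag"]] > 0) ssd_ag / df[["ag"]] else NA_real_,
          ap = if (df[["ap"]] > 0) ssd_ap / df[["ap"]] else NA_real_,
          wp = if (df[["wp"]] > 0) ssd_wp / df[["wp"]] else NA_real_)
  s2_c <- ms[["wp"]]
  s2_b <- if (is.na(ms[["ap"]])) 0 else (ms[["ap"]] - s2_c) / n1
  s2_a <- (ms[["ag"]] - s2_c - n2 * s2_b) / n3  # E[MS_ag] = c + n2*b + n3*a
  list(ssd = c(ag = ssd_ag, ap = ssd_ap, wp = ssd_wp), df = df, ms = ms,
       sigma2 = c(a = s2_a, b = s2_b, c = s2_c),
       n_coef = c(n1 = n1, n2 = n2, n3 = n3))
}

phi_from_sigma2 <- function(s2) {
  tot <- sum(s2)
  c(phi_CT = if (tot > 0) s2[["a"]] / tot else NA_real_,
    phi_SC = if (s2[["b"]] + s2[["c"]] > 0)
      s2[["b"]] / (s2[["b"]] + s2[["c"]]) else NA_real_,
    phi_ST = if (tot > 0) (s2[["a"]] + s2[["b"]]) / tot else NA_real_)
}

#' Hierarchical AMOVA with permutation tests
#'
#' Decomposes squared pairwise distances into among-group, among-population
#' (within group) and within-population variance components and reports the
#' fixation indices `Phi_CT`, `Phi_SC`, `Phi_ST`. p-values come from
#' permutation: whole populations among groups for `Phi_CT`, samples among
#' populations within their group for `Phi_SC`, samples among populations
#' ignoring groups for `Phi_ST`; each p counts permuted statistics greater
#' than or equal to the observed one, `(b + 1)/(B + 1)`.
#'
#' @param dm `haplo_dist` over samples (see the note on the squared-distance
#'   convention in the source header).
#' @param popmap `haplo_popmap` covering the samples in `dm`.
#' @param grouping named character vector population (area) -> group; its
#'   names define which populations enter the analysis (others dropped).
#' @param population which popmap column defines populations (default
#'   `"area"`).
#' @param n_permutations permutations per test (default 10000); 0 skips.
#' @param seed integer seed for the permutation stream.
#' @param squared is `dm` already on the squared scale? Default `TRUE`,
#'   correct for raw difference counts.
#' @param tests which fixation indices get a permutation p-value (default
#'   all three).
#' @return An `amova_result` list: `components` data.frame (sigma2,
#'   percentage, df, SSD), `phi` named vector, `p` named vector, plus the
#'   permutation counts and seed.
#' @export
amova <- function(dm, popmap, grouping, population = "area",
                  n_permutations = 10000, seed = NULL, squared = TRUE,
                  tests = c("phi_CT", "phi_SC", "phi_ST")) {
  stopifnot(is.matrix(dm))
  ids <- rownames(dm)
  pm <- popmap[match(ids, popmap$sample_id), , drop = FALSE]
  if (anyNA(pm$sample_id))
    stop("distance matrix contains samples absent from the population map",
         call. = FALSE)
  pop <- pm[[population]]
  keep <- pop %in% names(grouping)
  if (!all(keep)) {
    dm <- dm[keep, keep, drop = FALSE]
    pop <- pop[keep]
  }
  if (length(unique(grouping[unique(pop)])) < 2)
    stop("need at least two groups", call. = FALSE)
  d2 <- if (squared) unclass(dm) else unclass(dm)^2
  obs <- amova_components(d2, pop, grouping)
  phi <- phi_from_sigma2(obs$sigma2)

  p <- c(phi_CT = NA_real_, phi_SC = NA_real_, phi_ST = NA_real_)
  if (n_permutations > 0) {
    if (!is.null(seed)) set.seed(seed)
    pops <- unique(pop)
    grp_of_pop <- grouping[pops]
    ge_ct <- ge_sc <- ge_st <- 0L
    for (b in seq_len(n_permutations)) {
      if ("phi_CT" %in% tests) {
        # Phi_CT: permute populations among groups
        g_perm <- stats::setNames(sample(grp_of_pop), pops)
        phi_ct_b <- phi_from_sigma2(
          amova_components(d2, pop, g_perm)$sigma2)[["phi_CT"]]
        if (!is.na(phi_ct_b) && phi_ct_b >= phi[["phi_CT"]] - 1e-12)
          ge_ct <- ge_ct + 1L
      }
      if ("phi_SC" %in% tests) {
        # Phi_SC: permute samples among populations within groups
        pop_sc <- pop
        for (g in unique(grp_of_pop)) {
          in_g <- grouping[pop] == g
          pop_sc[in_g] <- sample(pop[in_g])
        }
        phi_sc_b <- phi_from_sigma2(
          amova_components(d2, pop_sc, grouping)$sigma2)[["phi_SC"]]
        if (!is.na(phi_sc_b) && phi_sc_b >= phi[["phi_SC"]] - 1e-12)
          ge_sc <- ge_sc + 1L
      }
      if ("phi_ST" %in% tests) {
        # Phi_ST: permute samples among populations, groups ignored
        pop_st <- sample(pop)
        phi_st_b <- phi_from_sigma2(
          amova_components(d2, pop_st, grouping)$sigma2)[["phi_ST"]]
        if (!is.na(phi_st_b) && phi_st_b >= phi[["phi_ST"]] - 1e-12)
          ge_st <- ge_st + 1L
      }
    }
    pp <- function(g, nm) if (nm %in% tests)
      (g + 1) / (n_permutations + 1) else NA_real_
    p <- c(phi_CT = pp(ge_ct, "phi_CT"), phi_SC = pp(ge_sc, "phi_SC"),
           phi_ST = pp(ge_st, "phi_ST"))
  }
  s2 <- obs$sigma2
  comp <- data.frame(
    source = c("Among groups", "Among populations within groups",
               "Within populations"),
    df = as.integer(obs$df),
    SSD = as.numeric(obs$ssd),
    sigma2 = as.numeric(s2),
    percent = 100 * as.numeric(s2) / sum(s2),
    stringsAsFactors = FALSE)
  structure(list(components = comp, phi = phi, p = p,
                 n_permutations = n_permutations, seed = seed),
            class = "amova_result")
}

#' @export
print.amova_result <- function(x, ...) {
  cat("AMOVA (", x$n_permutations, " permutations)\n", sep = "")
  print(cbind(x$components,
              phi = round(c(x$phi[["phi_CT"]], x$phi[["phi_SC"]],
                            x$phi[["phi_ST"]]), 4),
              p = signif(c(x$p[["phi_CT"]], x$p[["phi_SC"]],
                           x$p[["phi_ST"]]), 3)),
        row.names = FALSE)
  invisible(x)
}

# One-level AMOVA (populations, no groups): Phi_ST and components.
amova_one_level <- function(d2, pop) {
  N <- nrow(d2); pop <- factor(pop); P <- nlevels(pop)
  ss_t <- sum(d2) / (2 * N)
  bp <- block_ss(d2, pop)
  ssd_wp <- sum(bp$ss)
  ssd_ap <- ss_t - ssd_wp
  n_p <- bp$sizes
  s2_b <- ssd_wp / (N - P)
  n_c <- (N - sum(n_p^2) / N) / (P - 1)
  s2_a <- (ssd_ap / (P - 1) - s2_b) / n_c
  tot <- s2_a + s2_b
  list(sigma2 = c(a = s2_a, b = s2_b),
       phi_ST = if (tot > 0) s2_a / tot else NA_real_)
}

#' Pairwise Phi_ST between populations
#'
#' Two-population AMOVA for every population pair, with permutation
#' p-values (samples shuffled between the two populations).
#'
#' @inheritParams amova
#' @param population popmap column defining populations (default `"area"`).
#' @return list with matrices `phi_st` and `p`; pairs involving a
#'   population of size 1 are `NA`.
#' @export
pairwise_phist <- function(dm, popmap, population = "area",
                           n_permutations = 1000, seed = NULL,
                           squared = TRUE) {
  ids <- rownames(dm)
  pm <- popmap[match(ids, popmap$sample_id), , drop = FALSE]
  pop <- pm[[population]]
  pops <- unique(pop)
  k <- length(pops)
  if (k < 2) stop("need at least two populations", call. = FALSE)
  d2 <- if (squared) unclass(dm) else unclass(dm)^2
  phi <- p <- matrix(NA_real_, k, k, dimnames = list(pops, pops))
  diag(phi) <- 0
  if (!is.null(seed)) set.seed(seed)
  for (i in seq_len(k - 1L)) for (j in seq.int(i + 1L, k)) {
    sel <- pop %in% pops[c(i, j)]
    if (sum(pop == pops[i]) < 2 || sum(pop == pops[j]) < 2) next
    dd <- d2[sel, sel, drop = FALSE]
    pp <- pop[sel]
    obs <- amova_one_level(dd, pp)$phi_ST
    phi[i, j] <- phi[j, i] <- obs
    if (n_permutations > 0 && !is.na(obs)) {
      ge <- 0L
      for (b in seq_len(n_permutations)) {
        val <- amova_one_level(dd, sample(pp))$phi_ST
        if (!is.na(val) && val >= obs - 1e-12) ge <- ge + 1L
      }
      p[i, j] <- p[j, i] <- (ge + 1) / (n_permutations + 1)
    }
  }
  list(phi_st = phi, p = p, n_permutations = n_permutations)
}

#' Write an AMOVA report as TSV
#' @param x an `amova_result`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_amova <- function(x, path) {
  tab <- x$components
  tab$phi <- c(x$phi[["phi_CT"]], x$phi[["phi_SC"]], x$phi[["phi_ST"]])
  tab$p <- c(x$p[["phi_CT"]], x$p[["phi_SC"]], x$p[["phi_ST"]])
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
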