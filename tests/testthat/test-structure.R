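# AMOVA / Phi-statistics, pairwise Phi_ST and the exact differentiation
# test.

# helper: alignment + popmap with given per-population sequences
structured_data <- function(pop_seqs, grp_of_pop) {
  seqs <- unlist(lapply(names(pop_seqs), function(p) {
    s <- pop_seqs[[p]]
    stats::setNames(s, sprintf("%s_%02d", p, seq_along(s)))
  }))
  aln <- aln_from_strings(seqs)
  pm <- as_popmap(data.frame(
    sample_id = names(seqs),
    range = grp_of_pop[sub("_[0-9]+$", "", names(seqs))],
    area = sub("_[0-9]+$", "", names(seqs)),
    site_id = sub("_[0-9]+$", "", names(seqs)),
    stringsAsFactors = FALSE))
  list(aln = aln, popmap = pm)
}

test_that("fixation-index identities recover the reference Phi values
           from fixed variance percentages", {
  s2 <- c(a = 40.32, b = 11.75, c = 47.92)
  phi <- haplopop:::phi_from_sigma2(s2)
  expect_equal(round(phi[["phi_CT"]], 3), 0.403)
  expect_equal(round(phi[["phi_SC"]], 3), 0.197)
  expect_equal(phi[["phi_ST"]], 0.5207, tolerance = 2e-4)
})

test_that("AMOVA components match the brute-force sum-of-squares oracle
           and satisfy the index identities", {
  set.seed(19)
  for (rep in 1:4) {
    # <=12 samples, 4 populations, 2 groups, unbalanced
    sizes <- sample(2:4, 4, replace = TRUE)
    pop <- rep(paste0("p", 1:4), sizes)
    grp_of_pop <- c(p1 = "g1", p2 = "g1", p3 = "g2", p4 = "g2")
    n <- length(pop)
    # random integer "difference" matrix, symmetric, zero diagonal
    d2 <- matrix(0, n, n)
    d2[upper.tri(d2)] <- sample(0:6, n * (n - 1) / 2, replace = TRUE)
    d2 <- d2 + t(d2)
    dimnames(d2) <- list(paste0("s", 1:n), paste0("s", 1:n))
    pm <- as_popmap(data.frame(sample_id = rownames(d2),
                               range = grp_of_pop[pop], area = pop,
                               site_id = pop))
    res <- amova(d2, pm, grouping = grp_of_pop, n_permutations = 0)
    want <- oracle_amova(d2, pop, grp_of_pop)
    expect_equal(res$components$sigma2, unname(want), tolerance = 1e-10)
    # identities
    s2 <- res$components$sigma2
    expect_equal(sum(res$components$percent), 100, tolerance = 1e-6)
    expect_equal(res$phi[["phi_CT"]], s2[1] / sum(s2))
    expect_equal(res$phi[["phi_SC"]], s2[2] / (s2[2] + s2[3]))
    expect_equal(res$phi[["phi_ST"]], (s2[1] + s2[2]) / sum(s2))
  }
})

test_that("degenerate AMOVA input: identical sequences give zero variance
           and undefined indices", {
  dat <- structured_data(list(p1 = rep("ACGT", 3), p2 = rep("ACGT", 3),
                              p3 = rep("ACGT", 3), p4 = rep("ACGT", 3)),
                         c(p1 = "g1", p2 = "g1", p3 = "g2", p4 = "g2"))
  dm <- pairwise_distances(dat$aln, "raw")
  res <- amova(dm, dat$popmap,
               c(p1 = "g1", p2 = "g1", p3 = "g2", p4 = "g2"),
               n_permutations = 0)
  expect_equal(res$components$sigma2, rep(0, 3))
  expect_true(all(is.na(res$phi)))
})

test_that("two clean groups: Phi_CT matches the enumeration argument and
           the permutation p sits at the enumeration value", {
  # two groups of two populations; within groups identical sequences,
  # 5 raw differences between groups
  g1seq <- strrep("A", 20)
  g2seq <- paste0(strrep("T", 5), strrep("A", 15))
  dat <- structured_data(list(p1 = rep(g1seq, 3), p2 = rep(g1seq, 3),
                              p3 = rep(g2seq, 3), p4 = rep(g2seq, 3)),
                         c(p1 = "g1", p2 = "g1", p3 = "g2", p4 = "g2"))
  dm <- pairwise_distances(dat$aln, "raw")
  grouping <- c(p1 = "g1", p2 = "g1", p3 = "g2", p4 = "g2")
  res <- amova(dm, dat$popmap, grouping, n_permutations = 2000, seed = 5,
               tests = "phi_CT")
  want <- oracle_amova(unclass(dm), rep(paste0("p", 1:4), each = 3),
                       grouping)
  expect_equal(res$phi[["phi_CT"]], want[["a"]] / sum(want),
               tolerance = 1e-10)
  # of the 3 distinct assignments of 4 populations into 2 groups only the
  # observed one separates the clusters, but its mirror image recurs with
  # probability 1/3 under label permutation, so E[p] = 1/3
  expect_equal(res$p[["phi_CT"]], 1 / 3, tolerance = 0.04)
})

test_that("pairwise Phi_ST hits its boundary cases and matches the
           one-level decomposition oracle", {
  # identical populations -> ~0; fully fixed difference -> 1
  a <- strrep("A", 10); t10 <- strrep("T", 10)
  dat <- structured_data(list(p1 = rep(a, 4), p2 = rep(a, 4),
                              p3 = rep(t10, 4)),
                         c(p1 = "g", p2 = "g", p3 = "g"))
  dm <- pairwise_distances(dat$aln, "raw")
  pw <- pairwise_phist(dm, dat$popmap, n_permutations = 0)
  expect_true(is.na(pw$phi_st["p1", "p2"]) || pw$phi_st["p1", "p2"] <= 0)
  expect_equal(pw$phi_st["p1", "p3"], 1)
  expect_equal(pw$phi_st["p2", "p3"], 1)

  # random small case vs direct one-level computation
  set.seed(8)
  n <- 8
  d2 <- matrix(0, n, n)
  d2[upper.tri(d2)] <- sample(0:5, n * (n - 1) / 2, replace = TRUE)
  d2 <- d2 + t(d2)
  dimnames(d2) <- list(paste0("s", 1:n), paste0("s", 1:n))
  pop <- rep(c("x", "y"), each = 4)
  pm <- as_popmap(data.frame(sample_id = rownames(d2), range = "R",
                             area = pop, site_id = pop))
  got <- pairwise_phist(d2, pm, n_permutations = 0)$phi_st["x", "y"]
  ss_block <- function(idx) sum(d2[idx, idx]) / (2 * length(idx))
  ss_t <- ss_block(1:n)
  ss_w <- ss_block(1:4) + ss_block(5:8)
  s2b <- ss_w / (n - 2)
  nc <- (n - (16 + 16) / n) / 1
  s2a <- ((ss_t - ss_w) / 1 - s2b) / nc
  expect_equal(got, s2a / (s2a + s2b), tolerance = 1e-12)
})

test_that("seeded AMOVA permutation p-values are reproducible", {
  fx <- make_paper_fixture(1)
  keep <- fx$popmap$range != "Lessini"
  pm <- as_popmap(fx$popmap[keep, ])
  aln <- as_alignment(unclass(fx$alignment)[keep, ], "c")
  tb <- collapse_haplotypes(aln, pm)
  dm <- haplopop:::expand_to_samples(pairwise_distances(tb, "raw"),
                                     tb$membership)
  pops <- unique(pm$area)
  grouping <- stats::setNames(pm$range[match(pops, pm$area)], pops)
  r1 <- amova(dm, pm, grouping, n_permutations = 100, seed = 42)
  r2 <- amova(dm, pm, grouping, n_permutations = 100, seed = 42)
  expect_identical(r1$p, r2$p)
  expect_gt(r1$phi[["phi_CT"]], 0)
})

test_that("exact test agrees with full hypergeometric enumeration on 2x2
           tables", {
  # diagonal table: smallest possible p
  t1 <- matrix(c(10, 0, 0, 10), 2)
  r1 <- exact_differentiation_test(t1, steps = 20000,
                                   dememorization = 2000, seed = 1)
  expect_lt(abs(r1$p_value - oracle_exact_2x2(t1)), 0.01)

  # moderate table: p well inside (0, 1)
  t2 <- matrix(c(7, 3, 4, 9), 2)
  p_oracle <- oracle_exact_2x2(t2)
  r2 <- exact_differentiation_test(t2, steps = 40000,
                                   dememorization = 4000, seed = 2)
  expect_lt(abs(r2$p_value - p_oracle), max(0.02, 4 * r2$se))

  # identical frequency rows -> p near 1
  t3 <- matrix(c(30, 30, 20, 20), 2)
  r3 <- exact_differentiation_test(t3, steps = 20000,
                                   dememorization = 2000, seed = 3)
  expect_gt(r3$p_value, 0.8)

  # degenerate: single row
  expect_equal(exact_differentiation_test(matrix(c(5, 7), 1))$p_value, 1)
})

test_that("exact test p-values are roughly uniform under the null", {
  set.seed(13)
  probs <- c(0.5, 0.3, 0.2)
  p <- replicate(200, {
    tab <- rbind(stats::rmultinom(1, 25, probs)[, 1],
                 stats::rmultinom(1, 25, probs)[, 1])
    exact_differentiation_test(tab, steps = 4000,
                               dememorization = 400)$p_value
  })
  frac <- mean(p < 0.05)
  expect_gte(frac, 0.01)
  expect_lte(frac, 0.10)
})
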