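# Statistical-parsimony network: connection limit, agglomeration,
# loop resolution, regional summaries, exports.

test_that("parsimony probability behaves like a probability and the
           connection limit is monotone", {
  expect_equal(parsimony_probability(0, 100), 1)
  p <- vapply(1:15, parsimony_probability, 0, L = 800)
  expect_true(all(p <= 1 & p >= 0))
  expect_true(all(diff(p) < 0))            # decreasing in steps

  # Monte-Carlo re-evaluation of the same posterior integral
  set.seed(2)
  j <- 6; L <- 800
  q <- stats::rbeta(2e5, j + 1, L - j + 1)
  q <- q[q < 0.5]
  lam <- -0.5 * log(1 - 2 * q)
  mc <- mean((1 / cosh(lam))^(L - j) * (lam / sinh(lam))^j)
  expect_equal(parsimony_probability(j, L), mc, tolerance = 0.003)

  # limit is at least 1 even at a cut-off approaching 1
  expect_equal(parsimony_connection_limit(500, cutoff = 0.999999), 1)
  # non-decreasing in L at fixed cutoff
  lims <- vapply(c(200, 500, 1000, 1697, 3000),
                 parsimony_connection_limit, 0L)
  expect_true(all(diff(lims) >= 0))
  expect_gte(parsimony_connection_limit(1697), 7)  # spans the fixture
})

test_that("build_network constructs paths, stars and median nodes
           deterministically", {
  # 2 haplotypes, 1 step
  t2 <- collapse_haplotypes(aln_from_strings(c(a = "AAAA", b = "AAAT")))
  n2 <- build_network(t2, pairwise_distances(t2, "raw"), 5)
  expect_equal(igraph::vcount(n2$graph), 2L)
  expect_equal(igraph::ecount(n2$graph), 1L)

  # chain A-B-C (1,1,2): path, no intermediates
  t3 <- collapse_haplotypes(aln_from_strings(
    c(a = "AAAA", b = "AAAT", c = "AATT")))
  n3 <- build_network(t3, pairwise_distances(t3, "raw"), 5)
  expect_equal(igraph::vcount(n3$graph), 3L)
  expect_equal(igraph::ecount(n3$graph), 2L)
  expect_false(any(igraph::V(n3$graph)$inferred))

  # star: hub + 10 one-step satellites
  base <- strrep("A", 40)
  sats <- vapply(1:10, function(i) {
    s <- strsplit(base, "")[[1]]; s[i] <- "T"; paste(s, collapse = "")
  }, "")
  seqs <- c(rep(base, 10), sats)
  names(seqs) <- sprintf("s%02d", seq_along(seqs))
  ts <- collapse_haplotypes(aln_from_strings(seqs))
  ns <- build_network(ts, pairwise_distances(ts, "raw"), 10)
  hub <- ts$haplotypes$haplotype_id[1]     # most frequent
  expect_equal(unname(igraph::degree(ns$graph, hub)), 10)

  # distance-2 pair gets exactly one median node
  tm <- collapse_haplotypes(aln_from_strings(c(a = "AAAA", b = "AATT")))
  nm <- build_network(tm, pairwise_distances(tm, "raw"), 5)
  expect_equal(sum(igraph::V(nm$graph)$inferred), 1L)
  expect_equal(igraph::V(nm$graph)$count[igraph::V(nm$graph)$inferred], 0L)

  # pair beyond the limit stays disconnected
  nf <- build_network(tm, pairwise_distances(tm, "raw"), 1)
  expect_equal(igraph::count_components(nf$graph), 2L)
})

test_that("unit-distance networks reduce to a spanning tree after loop
           resolution (MST property)", {
  # three haplotypes all at mutual distance 1 (triangle before resolution)
  t3 <- collapse_haplotypes(aln_from_strings(
    c(a1 = "AA", a2 = "AA", a3 = "AA", b1 = "AT", b2 = "AT", c1 = "AC")))
  d <- pairwise_distances(t3, "raw")
  net <- build_network(t3, d, 5)
  expect_equal(igraph::ecount(net$graph), 3L)    # reticulation present
  res <- resolve_loops(net)
  h <- sum(!igraph::V(res$graph)$inferred)
  m <- sum(igraph::V(res$graph)$inferred)
  expect_equal(igraph::ecount(res$graph), h + m - 1L)
  expect_equal(igraph::count_components(res$graph), 1L)
  expect_true(is.infinite(igraph::girth(res$graph)$girth) ||
                igraph::girth(res$graph)$girth == 0)
})

test_that("loop resolution applies the frequency, topology and geography
           criteria in order and logs decisions", {
  # acyclic input unchanged
  t2 <- collapse_haplotypes(aln_from_strings(c(a = "AAAA", b = "AAAT")))
  n2 <- build_network(t2, pairwise_distances(t2, "raw"), 5)
  r2 <- resolve_loops(n2)
  expect_equal(igraph::ecount(r2$graph), 1L)
  expect_equal(nrow(r2$resolution_log), 0L)

  # square loop hub-x-y-z-hub: the lightest edge joins two rare tips and
  # must fall to the frequency criterion, never an edge at the hub
  seqs <- c(rep("AAAA", 10), rep("TAAA", 3), rep("TTAA", 2), "ATAA")
  names(seqs) <- sprintf("s%02d", seq_along(seqs))
  tb <- collapse_haplotypes(aln_from_strings(seqs))
  # distances: hub-x=1, x-y=1, y-z=1, z-hub=1, hub-y=2, x-z=2 -> 4-cycle
  net <- build_network(tb, pairwise_distances(tb, "raw"), 5)
  expect_gte(igraph::ecount(net$graph), 4L)
  res <- resolve_loops(net)
  expect_gte(nrow(res$resolution_log), 1L)
  expect_match(res$resolution_log$criterion[1], "frequency")
  # the dropped edge is between two singletons, not at the hub
  hub <- tb$haplotypes$haplotype_id[1]
  expect_false(grepl(hub, res$resolution_log$edge[1]))

  # geography tie-break: equal frequencies and degrees, one edge's
  # endpoints share a collection site
  seqs2 <- c(h1 = "AAAA", h1b = "AAAA", h2 = "TAAA", h2b = "TAAA",
             h3 = "TTAA", h3b = "TTAA", h4 = "ATAA", h4b = "ATAA")
  pm <- as_popmap(data.frame(
    sample_id = names(seqs2), range = "R",
    area = c("a1", "a1", "a1", "a1", "a2", "a2", "a2", "a2"),
    site_id = c("s1", "s1", "s1", "s1", "s2", "s2", "s3", "s3")))
  tb2 <- collapse_haplotypes(aln_from_strings(seqs2), pm)
  net2 <- build_network(tb2, pairwise_distances(tb2, "raw"), 5)
  res2 <- resolve_loops(net2, pm)
  expect_gte(nrow(res2$resolution_log), 1L)
  expect_true(is.infinite(igraph::girth(res2$graph)$girth) ||
                igraph::girth(res2$graph)$girth == 0)
  # the co-occurring pair keeps its edge; a non-co-occurring one was cut
  expect_true(igraph::are_adjacent(res2$graph, "H001", "H002"))
  expect_match(res2$resolution_log$criterion[1], "geography")
})

test_that("regional summary reproduces the fixture design and the
           brute-force tally", {
  fx <- make_paper_fixture(1)
  tb <- collapse_haplotypes(fx$alignment, fx$popmap,
                            labels = fx$truth$labels)
  rs <- regional_summary(tb, fx$popmap)
  expect_equal(nrow(rs), 32L)
  excl <- table(rs$ranges[rs$exclusive])
  expect_equal(as.integer(excl[c("Euganean", "Berici", "Lessini")]),
               c(15L, 13L, 2L))
  expect_equal(sum(!rs$exclusive), 2L)
  expect_setequal(rs$haplotype_id[!rs$exclusive], c("A1", "I1"))

  # brute-force tally over the population map
  for (h in c("A6", "I1", "A1", "N17")) {
    ids <- names(tb$membership)[tb$membership == h]
    want <- table(fx$popmap$range[match(ids, fx$popmap$sample_id)])
    for (r in names(want))
      expect_equal(rs[[r]][rs$haplotype_id == h], unname(want[[r]]))
  }

  # single-range input: everything exclusive
  sim <- simulate_coalescent(demographic_model("constant", theta = 3),
                             n = 8, L = 300, seed = 2)
  tb1 <- collapse_haplotypes(sim$alignment, sim$popmap)
  expect_true(all(regional_summary(tb1, sim$popmap)$exclusive))
})

test_that("fixture network reproduces the two-star topology and GraphML
           export is byte-stable", {
  fx <- make_paper_fixture(1)
  tb <- collapse_haplotypes(fx$alignment, fx$popmap,
                            labels = fx$truth$labels)
  dm <- pairwise_distances(tb, "raw")
  jm <- parsimony_connection_limit(1697)
  net <- resolve_loops(build_network(tb, dm, jm), fx$popmap)
  g <- net$graph
  expect_equal(igraph::count_components(g), 1L)
  expect_equal(unname(igraph::degree(g, "A6")), 11)  # ten satellites + A1
  expect_equal(igraph::distances(g, "A6", "I1")[1, 1], 2)

  f1 <- tempfile(fileext = ".graphml"); f2 <- tempfile(fileext = ".graphml")
  write_network_graphml(net, f1, fx$popmap)
  net_again <- resolve_loops(build_network(tb, dm, jm), fx$popmap)
  write_network_graphml(net_again, f2, fx$popmap)
  expect_identical(readLines(f1), readLines(f2))
})
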