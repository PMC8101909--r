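# Sequence data model: FASTA I/O, concatenation, population map,
# haplotype collapsing, site classification, NUMT screen, distances.

test_that("FASTA round-trip preserves sequences and rejects bad input", {
  seqs <- c(s1 = "ACGTACGTAC", s2 = "ACGTTCGTAC")
  aln <- aln_from_strings(seqs)
  expect_equal(ncol(aln), 10L)
  expect_equal(nrow(aln), 2L)

  path <- tempfile(fileext = ".fasta")
  write_fasta(aln, path)
  back <- read_fasta(path, marker_name = "test")
  expect_identical(unclass(back), unclass(aln))

  # wrapping on read: rewrap at width 4 and reread
  write_fasta(aln, path, width = 4)
  expect_identical(unclass(read_fasta(path, marker_name = "test")),
                   unclass(aln))

  expect_error(aln_from_strings(c(a = "ACGTACGTAC", b = "ACGTACGTA")),
               "ragged")
  expect_error(as_alignment(c(a = "ACGT", a = "ACGT")), "unique")
  expect_error(aln_from_strings(c(a = "ACGX")), "non-IUPAC")
  expect_error(read_fasta(tempfile()), "not found")
})

test_that("concatenate joins partitions and records boundaries", {
  a1 <- aln_from_strings(c(x = strrep("A", 799), y = strrep("C", 799)),
                         marker = "coi")
  a2 <- aln_from_strings(c(y = strrep("G", 898), x = strrep("T", 898)),
                         marker = "cr")
  cc <- concatenate(list(a1, a2))
  expect_equal(ncol(cc), 1697L)
  expect_equal(unname(attr(cc, "partitions")), c(799L, 898L))
  # sample order follows the first partition; rows are matched by id
  expect_equal(paste(unclass(cc)["x", 800:802], collapse = ""), "TTT")

  expect_identical(concatenate(list(a1)), a1)
  a3 <- aln_from_strings(c(x = "ACGT", z = "ACGT"))
  expect_error(concatenate(list(a1, a3)), "sample sets differ")
})

test_that("population map enforces the strict hierarchy", {
  df <- data.frame(sample_id = c("a", "b", "c"), range = "R1",
                   area = "A1", site_id = "S1", stringsAsFactors = FALSE)
  expect_s3_class(as_popmap(df), "haplo_popmap")

  path <- tempfile(fileext = ".tsv")
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  expect_s3_class(read_population_map(path), "haplo_popmap")

  dup <- rbind(df, data.frame(sample_id = "a", range = "R1", area = "A2",
                              site_id = "S2"))
  expect_error(as_popmap(dup), "more than once")
  two_areas <- df
  two_areas$area <- c("A1", "A1", "A2")     # one site under two areas
  expect_error(as_popmap(two_areas), "more than one area")
  two_ranges <- df
  two_ranges$site_id <- c("S1", "S2", "S2")
  two_ranges$area <- c("A1", "A2", "A2")
  two_ranges$range <- c("R1", "R1", "R2")   # one area under two ranges
  expect_error(as_popmap(two_ranges), "more than one range")
})

test_that("collapse_haplotypes groups identical sequences, conserves
           counts and orders ids by frequency", {
  seqs <- c(rep("AAAA", 17), rep("AAAT", 2), "AATT")
  names(seqs) <- sprintf("s%02d", 1:20)
  aln <- aln_from_strings(seqs)
  tab <- collapse_haplotypes(aln)
  expect_equal(nrow(tab$haplotypes), 3L)
  expect_equal(unname(haplotype_counts(tab)), c(17L, 2L, 1L))
  expect_equal(tab$haplotypes$haplotype_id, c("H001", "H002", "H003"))
  expect_equal(tab$n_total, 20L)
  expect_equal(sum(tab$counts), tab$n_total)

  # idempotence: collapsing the haplotype sequences again is a no-op
  aln2 <- aln_from_strings(stats::setNames(tab$haplotypes$sequence,
                                           tab$haplotypes$haplotype_id))
  tab2 <- collapse_haplotypes(aln2)
  expect_equal(tab2$haplotypes$sequence, tab$haplotypes$sequence)

  # all identical / all distinct
  expect_equal(nrow(collapse_haplotypes(
    aln_from_strings(c(a = "AC", b = "AC", c = "AC")))$haplotypes), 1L)
  expect_equal(nrow(collapse_haplotypes(
    aln_from_strings(c(a = "AC", b = "AG", c = "AT", d = "CC")))$haplotypes),
    4L)

  # missing-data policy: N does not merge
  tabN <- collapse_haplotypes(aln_from_strings(c(a = "ACGT", b = "ACGN")))
  expect_equal(nrow(tabN$haplotypes), 2L)

  # label map preserved
  lab <- stats::setNames(c(rep("I5", 17), rep("I1", 2), "I14"),
                         names(seqs))
  tabl <- collapse_haplotypes(aln, labels = lab)
  expect_equal(unname(haplotype_counts(tabl)["I5"]), 17L)
})

test_that("classify_sites matches hand enumeration and the brute-force
           oracle, and totals always add up", {
  aln <- aln_from_strings(c(a = "AAA", b = "AAT", c = "AAT", d = "ATA"))
  cls <- classify_sites(aln)
  expect_equal(cls$n_variable, 2L)
  expect_equal(cls$n_singleton, 1L)
  expect_equal(cls$n_parsimony_informative, 1L)
  expect_equal(unname(cls$labels), c("invariant", "singleton",
                                     "parsimony_informative"))

  inv <- classify_sites(aln_from_strings(c(a = "ACGT", b = "ACGT")))
  expect_equal(inv$n_variable, 0L)

  set.seed(42)
  for (rep in 1:5) {
    sim <- simulate_coalescent(demographic_model("constant", theta = 4),
                               n = 12, L = 300)
    got <- classify_sites(sim$alignment)
    want <- oracle_classify(sim$alignment)
    expect_equal(got$n_variable, want$n_variable)
    expect_equal(got$n_parsimony_informative, want$n_pi)
    expect_equal(got$n_singleton, want$n_singleton)
    expect_equal(got$n_variable,
                 got$n_parsimony_informative + got$n_singleton)
  }
})

test_that("numt_screen translates in the declared frame with the
           invertebrate mitochondrial code", {
  aln <- aln_from_strings(c(ok = "ATGGCTAAA"))
  expect_true(all(numt_screen(aln, frame = 1)$pass))   # TAA terminal only

  bad <- aln_from_strings(c(x = "ATGTAAGCT"))
  scr <- numt_screen(bad, frame = 1)
  expect_false(scr$pass)
  expect_equal(scr$n_internal_stops, 1L)

  # TAG spans codons in frame 1 but is in-frame at frame 2
  shifty <- aln_from_strings(c(x = "ATAGCACTA"))
  expect_true(numt_screen(shifty, frame = 1)$pass)
  expect_false(numt_screen(shifty, frame = 2)$pass)

  # AGA is arginine in the standard code but serine (not stop) in table 5;
  # TGA is tryptophan in table 5, never an internal stop
  expect_true(numt_screen(aln_from_strings(c(x = "ATGTGAAGAAAA")),
                          frame = 1)$pass)
  expect_error(numt_screen(aln, frame = 4), "frame")
})

test_that("K2P distance matches the closed form, dominates p-distance and
           fails on saturation", {
  expect_equal(k2p_distance("ACGT", "ACGT"), 0)

  # P = 0.1, Q = 0.05 over 100 sites
  a <- strrep("A", 100)
  b <- paste(c(rep("G", 10), rep("C", 5), rep("A", 85)), collapse = "")
  expect_equal(k2p_distance(a, b), 0.17018, tolerance = 1e-4)
  expect_equal(k2p_distance(a, b),
               -0.5 * log((1 - 2 * 0.1 - 0.05) * sqrt(1 - 2 * 0.05)))

  # pairwise deletion: sites with N or - are excluded
  expect_equal(k2p_distance("ACGTN", "ACCT-"), k2p_distance("ACGT", "ACCT"))
  expect_error(k2p_distance("NNNN", "ACGT"), "no comparable sites")
  expect_error(k2p_distance(strrep("A", 10), strrep("G", 10)),
               "saturation")

  set.seed(7)
  for (rep in 1:10) {
    n_mut <- sample(1:15, 1)
    av <- sample(c("A", "C", "G", "T"), 120, replace = TRUE)
    bv <- av
    idx <- sample(120, n_mut)
    for (i in idx) bv[i] <- sample(setdiff(c("A", "C", "G", "T"), av[i]), 1)
    p_dist <- mean(av != bv)
    expect_gte(k2p_distance(av, bv), p_dist - 1e-12)
  }
})

test_that("pairwise distance matrices are symmetric, match hand counts and
           the ape/Hamming oracles", {
  one <- pairwise_distances(aln_from_strings(c(a = "ACGT")), "raw")
  expect_equal(unclass(one), matrix(0, 1, 1, dimnames = list("a", "a")),
               ignore_attr = TRUE)

  # 1-step chain: A-B = 1, B-C = 1, A-C = 2
  chain <- aln_from_strings(c(A = "AAAA", B = "AAAT", C = "AATT"))
  d <- pairwise_distances(chain, "raw")
  expect_equal(matrix(as.numeric(d), 3),
               matrix(c(0, 1, 2, 1, 0, 1, 2, 1, 0), 3))

  set.seed(11)
  sim <- simulate_coalescent(demographic_model("constant", theta = 5),
                             n = 8, L = 400)
  d_raw <- pairwise_distances(sim$alignment, "raw")
  expect_true(isSymmetric(unclass(d_raw)))
  m <- unclass(sim$alignment)
  for (i in 1:7) for (j in (i + 1):8) {
    expect_equal(d_raw[i, j],
                 oracle_hamming(paste(m[i, ], collapse = ""),
                                paste(m[j, ], collapse = "")))
  }
  # K2P against ape's implementation
  d_k2p <- pairwise_distances(sim$alignment, "k2p")
  d_ape <- as.matrix(ape::dist.dna(ape::as.DNAbin(tolower(m)),
                                   model = "K80",
                                   pairwise.deletion = TRUE))
  expect_equal(unclass(d_k2p), d_ape, tolerance = 1e-10,
               ignore_attr = TRUE)
})
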