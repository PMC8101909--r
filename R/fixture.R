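# Deterministic synthetic dataset emulating a two-range outbreak sampling
# design: 130 individuals from 23 collection sites in three disjoint
# ranges (two large outbreak ranges plus a small outlying one), collapsing
# to 32 haplotypes of 1697 bp. Each range's haplotypes radiate star-like
# from a modal haplotype (hub E-hub with 34 samples, hub B-hub with 20);
# exactly two haplotypes are shared between ranges.
#
# The haplotype step graph: the hub A6 carries ten one-step satellites
# (A8, A9, A10, A11, B6, C6, E6, F6, G6, H6) plus the shared A1; D7 and E4
# hang one step off E6, A12 off A8 and A13 off A10 (two steps from the
# hub). The second hub I1 sits one step beyond A1 (two steps from A6) and
# carries nine one-step satellites (I2, I3, I5, I6, I14, I15, K2, L9 and
# J1); J5, J6, J8 and J16 hang one step off J1; the outlying range's N17
# sits two steps beyond I1 with O1 one further step. Steps beyond those
# fixed by the design are an arbitrary but deterministic choice; they move
# nucleotide diversity and network layout but not any haplotype count.
# Every mutational step gets its own alignment column (no homoplasy).

fixture_edges <- function() {
  # parent -> child, one row per mutational step chain (steps = 1 each,
  # chains listed explicitly)
  rbind(
    c("A6", "A1"), c("A6", "A8"), c("A6", "A9"), c("A6", "A10"),
    c("A6", "A11"), c("A6", "B6"), c("A6", "C6"), c("A6", "E6"),
    c("A6", "F6"), c("A6", "G6"), c("A6", "H6"),
    c("E6", "D7"), c("E6", "E4"), c("A8", "A12"), c("A10", "A13"),
    c("A1", "I1"),
    c("I1", "I2"), c("I1", "I3"), c("I1", "I5"), c("I1", "I6"),
    c("I1", "I14"), c("I1", "I15"), c("I1", "K2"), c("I1", "L9"),
    c("I1", "J1"),
    c("J1", "J5"), c("J1", "J6"), c("J1", "J8"), c("J1", "J16"),
    c("I1", "n1"), c("n1", "N17"), c("N17", "O1"))   # n1: unsampled step
}

fixture_counts <- function() {
  # site_id, area, range, haplotype, count
  tab <- list(
    list("s01", "Euganean_North", c("A6" = 1)),
    list("s02", "Euganean_North", c("A6" = 7, "F6" = 2, "A9" = 1)),
    list("s03", "Euganean_North", c("A1" = 1, "A6" = 4, "A8" = 2, "H6" = 1)),
    list("s04", "Euganean_North", c("G6" = 1)),
    list("s05", "Euganean_Center", c("A6" = 1)),
    list("s06", "Euganean_Center", c("A6" = 2)),
    list("s07", "Euganean_Center", c("D7" = 1)),
    list("s08", "Euganean_Center", c("A6" = 1, "A11" = 1, "A12" = 2,
                                     "B6" = 1, "E4" = 1, "E6" = 3)),
    list("s09", "Euganean_Center", c("E6" = 1, "A6" = 2)),
    list("s10", "Euganean_Center", c("A6" = 3)),
    list("s11", "Euganean_Center", c("A6" = 1)),
    list("s12", "Euganean_South", c("A6" = 8, "A10" = 2, "C6" = 2)),
    list("s13", "Euganean_South", c("A6" = 1, "A13" = 1)),
    list("s14", "Euganean_South", c("A6" = 3)),
    list("s15", "Berici_North", c("I1" = 10, "I2" = 1, "I3" = 1,
                                  "I15" = 2, "J6" = 1, "L9" = 1)),
    list("s16", "Berici_North", c("J6" = 1)),
    list("s17", "Berici_North", c("I2" = 2, "J1" = 1, "J5" = 1,
                                  "J6" = 3, "K2" = 1)),
    list("s18", "Berici_Center", c("I5" = 1)),
    list("s19", "Berici_Center", c("A1" = 1, "I1" = 3, "I5" = 1, "I6" = 3,
                                   "J1" = 3, "J5" = 1, "J8" = 2,
                                   "J16" = 1)),
    list("s20", "Berici_South", c("I5" = 17)),
    list("s21", "Berici_South", c("I1" = 2, "I14" = 1)),
    list("s22", "Lessini", c("N17" = 4, "O1" = 3)),
    list("s23", "Lessini", c("I1" = 5)))
  area_range <- c(Euganean_North = "Euganean", Euganean_Center = "Euganean",
                  Euganean_South = "Euganean", Berici_North = "Berici",
                  Berici_Center = "Berici", Berici_South = "Berici",
                  Lessini = "Lessini")
  rows <- lapply(tab, function(x)
    data.frame(site_id = x[[1]], area = x[[2]],
               range = area_range[[x[[2]]]],
               haplotype = names(x[[3]]), count = as.integer(x[[3]]),
               stringsAsFactors = FALSE))
  do.call(rbind, rows)
}

#' Deterministic two-range fixture dataset
#'
#' Builds the synthetic 130-sample, 1697-bp, 32-haplotype dataset described
#' in the source header: three disjoint ranges with star-like haplotype
#' clusters around two modal haplotypes and two range-shared haplotypes.
#' Identical seeds give byte-identical sequences.
#'
#' @param seed integer seed controlling the backbone sequence and the
#'   columns assigned to each mutational step.
#' @return A `haplo_simdata` with `alignment`, `popmap`, and `truth`
#'   containing the sample -> haplotype `labels` map (usable as the
#'   `labels` argument of [collapse_haplotypes()]) and the step edge list.
#' @export
make_paper_fixture <- function(seed = 1) {
  set.seed(seed)
  L <- 1697L
  bases <- c("A", "C", "G", "T")
  backbone <- sample(bases, L, replace = TRUE)
  edges <- fixture_edges()
  cols <- sample.int(L, nrow(edges))          # one distinct column per step
  seqs <- list(A6 = backbone)
  for (k in seq_len(nrow(edges))) {
    par <- edges[k, 1]; child <- edges[k, 2]
    s <- seqs[[par]]
    s[cols[k]] <- sample(setdiff(bases, s[cols[k]]), 1L)
    seqs[[child]] <- s
  }
  seqs$n1 <- NULL                             # unsampled intermediate
  cnt <- fixture_counts()
  sample_rows <- cnt[rep(seq_len(nrow(cnt)), cnt$count), ]
  sample_rows$sample_id <- sprintf("%s_%02d", sample_rows$site_id,
                                   stats::ave(seq_len(nrow(sample_rows)),
                                              sample_rows$site_id,
                                              FUN = seq_along))
  m <- do.call(rbind, seqs[sample_rows$haplotype])
  rownames(m) <- sample_rows$sample_id
  aln <- as_alignment(m, marker_name = "combined_1697bp",
                      partitions = c(coi_region = 799L, cr_region = 898L))
  popmap <- as_popmap(sample_rows[, c("sample_id", "range", "area",
                                      "site_id")])
  labels <- stats::setNames(sample_rows$haplotype, sample_rows$sample_id)
  structure(list(alignment = aln, popmap = popmap,
                 truth = list(tmrca = NA_real_,
                              n_mutations = nrow(edges),
                              labels = labels,
                              edges = edges,
                              seed = seed)),
            class = "haplo_simdata")
}
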