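# Haplotype collapsing, site classification and table export.

#' Collapse identical sequences into haplotypes
#'
#' Sequences are compared exactly: positions holding missing data (`N`,
#' `-` or ambiguity codes) are *not* ignored, so two sequences differing
#' only at a missing position are kept as distinct haplotypes (conservative
#' policy; merging across missing data would fabricate identity).
#'
#' Haplotype identifiers are generated as `H001`, `H002`, ... ordered by
#' descending total count, ties broken by first occurrence in the alignment.
#' The original labels can be preserved by passing `labels`, a named vector
#' mapping a representative `sample_id` (or sequence) to the desired id.
#'
#' @param aln a `haplo_alignment`.
#' @param popmap optional `haplo_popmap`; when given, counts are tabulated
#'   per collection site, otherwise a single pooled column `all` is used.
#' @param labels optional named character vector `sample_id -> haplotype_id`
#'   used instead of generated ids (every haplotype must be covered).
#' @return A `haplo_table`: list with elements
#'   \item{haplotypes}{data.frame `haplotype_id`, `sequence`}
#'   \item{counts}{integer matrix haplotype x site}
#'   \item{n_total}{number of collapsed samples}
#'   \item{membership}{named vector sample_id -> haplotype_id}
#' @export
collapse_haplotypes <- function(aln, popmap = NULL, labels = NULL) {
  stopifnot(inherits(aln, "haplo_alignment"))
  seqs <- apply(unclass(aln), 1L, paste, collapse = "")
  uniq <- unique(seqs)                      # order of first occurrence
  grp <- match(seqs, uniq)
  tot <- tabulate(grp, nbins = length(uniq))
  ord <- order(-tot, seq_along(uniq))       # descending count, then first seen
  rank <- match(seq_along(uniq), ord)       # haplotype rank of each unique seq
  ids <- sprintf("H%03d", seq_along(uniq))
  if (!is.null(labels)) {
    rep_id <- labels[match(names(seqs), names(labels))]
    lab <- rep(NA_character_, length(uniq))
    ok <- !is.na(rep_id)
    lab[grp[ok]] <- rep_id[ok]
    if (anyNA(lab))
      stop("labels do not cover every haplotype", call. = FALSE)
    if (anyDuplicated(lab))
      stop("labels map one id to two distinct haplotypes", call. = FALSE)
    ids_by_rank <- lab[ord]
  } else {
    ids_by_rank <- ids
  }
  if (!is.null(popmap)) {
    pm <- match_popmap(aln, popmap)
    sites <- unique(popmap$site_id)
    counts <- table(factor(ids_by_rank[rank[grp]], levels = ids_by_rank),
                    factor(pm$site_id, levels = sites))
  } else {
    counts <- table(factor(ids_by_rank[rank[grp]], levels = ids_by_rank),
                    rep("all", length(seqs)))
  }
  counts <- matrix(as.integer(counts), nrow = nrow(counts),
                   dimnames = dimnames(counts))
  membership <- stats::setNames(ids_by_rank[rank[grp]], rownames(aln))
  structure(list(
    haplotypes = data.frame(haplotype_id = ids_by_rank,
                            sequence = uniq[ord],
                            stringsAsFactors = FALSE),
    counts = counts,
    n_total = length(seqs),
    membership = membership),
    class = "haplo_table")
}

#' @export
print.haplo_table <- function(x, ...) {
  cat("Haplotype table:", nrow(x$haplotypes), "haplotypes,",
      x$n_total, "samples,", ncol(x$counts), "site(s)\n")
  invisible(x)
}

#' Per-haplotype total counts
#' @param table a `haplo_table`.
#' @return Named integer vector of total counts, in table order.
#' @export
haplotype_counts <- function(table) {
  stopifnot(inherits(table, "haplo_table"))
  stats::setNames(as.integer(rowSums(table$counts)),
                  table$haplotypes$haplotype_id)
}

#' Classify alignment columns
#'
#' A column is *variable* if it holds two or more distinct non-missing
#' bases; a variable column is a *singleton* if exactly one base occurs a
#' single time and all others are the majority base, and *parsimony
#' informative* if at least two distinct bases each occur at least twice.
#'
#' @param aln a `haplo_alignment`.
#' @return A list of class `site_classification`: counts `n_variable`,
#'   `n_parsimony_informative`, `n_singleton` and a per-column label vector
#'   (`invariant`, `singleton`, `parsimony_informative`).
#' @export
classify_sites <- function(aln) {
  stopifnot(inherits(aln, "haplo_alignment"))
  m <- unclass(aln)
  lab <- apply(m, 2L, function(col) {
    col <- col[is_acgt(col)]
    if (length(col) < 2L) return("invariant")
    tab <- sort(table(col), decreasing = TRUE)
    if (length(tab) < 2L) return("invariant")
    if (sum(tab >= 2L) >= 2L) return("parsimony_informative")
    # variable but not PI: all minority bases are singletons
    "singleton"
  })
  n_pi <- sum(lab == "parsimony_informative")
  n_s <- sum(lab == "singleton")
  structure(list(n_variable = n_pi + n_s,
                 n_parsimony_informative = n_pi,
                 n_singleton = n_s,
                 labels = lab),
            class = "site_classification")
}

#' @export
print.site_classification <- function(x, ...) {
  cat(x$n_variable, "variable sites:", x$n_parsimony_informative,
      "parsimony informative,", x$n_singleton, "singleton\n")
  invisible(x)
}

#' Export a haplotype table as TSV
#'
#' One row per collection site with sample size and a `haplotype(count)`
#' list, mirroring the usual per-site summary-table layout.
#'
#' @param table a `haplo_table` built with a population map.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_haplotype_table <- function(table, path) {
  stopifnot(inherits(table, "haplo_table"))
  sites <- colnames(table$counts)
  rows <- lapply(sites, function(s) {
    cnt <- table$counts[, s]
    cnt <- cnt[cnt > 0L]
    data.frame(site_id = s, n = sum(cnt),
               haplotypes = paste0(names(cnt), "(", cnt, ")",
                                   collapse = ", "),
               stringsAsFactors = FALSE)
  })
  utils::write.table(do.call(rbind, rows), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
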