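# Statistical-parsimony (TCS-style) haplotype network: connection limit
# from the probability of parsimony, stepwise agglomeration with inferred
# intermediates, and rule-based loop resolution.

#' Statistical-parsimony connection limit
#'
#' Largest number of mutational steps `j` for which the probability that
#' two haplotypes differing at `j` of `L` sites are connected parsimoniously
#' (every difference arose from a single substitution and no hidden
#' substitutions occurred elsewhere) is at least `cutoff`.
#'
#' The probability model follows the statistical-parsimony framework of
#' Templeton, Crandall and Sing (1992): sites evolve independently; a
#' site differing between the two sequences has probability
#' `lambda/sinh(lambda)` of carrying exactly one substitution and an
#' identical site has probability `1/cosh(lambda)` of carrying none, where
#' `lambda` is the expected number of substitutions per site on the path
#' separating the pair. `lambda` is integrated over its posterior given
#' `j` differing sites out of `L` (uniform prior on the per-site difference
#' probability `q`, so `q | j ~ Beta(j+1, L-j+1)` truncated to `[0, 1/2)`,
#' with `lambda = -log(1-2q)/2`).
#'
#' @param L number of aligned sites.
#' @param cutoff probability-of-parsimony cut-off (default 0.95).
#' @param j_cap search upper bound (default `L`).
#' @return Integer connection limit (at least 1).
#' @export
parsimony_connection_limit <- function(L, cutoff = 0.95, j_cap = L) {
  stopifnot(L >= 1, cutoff > 0, cutoff < 1)
  j <- 1L
  while (j < j_cap && parsimony_probability(j + 1L, L) >= cutoff)
    j <- j + 1L
  j
}

#' Probability of parsimony for j differences over L sites
#' @param j observed number of differing sites.
#' @param L number of aligned sites.
#' @return Probability in `[0, 1]` (see [parsimony_connection_limit()]).
#' @export
parsimony_probability <- function(j, L) {
  stopifnot(j >= 0, L >= j)
  if (j == 0) return(1)
  f <- function(q) {
    lam <- -0.5 * log1p(-2 * q)
    # guard q -> 0: lambda/sinh(lambda) -> 1, 1/cosh -> 1
    lp <- ifelse(lam < 1e-12, 0,
                 j * (log(lam) - log(sinh(lam))) - (L - j) * log(cosh(lam)))
    exp(lp) * stats::dbeta(q, j + 1, L - j + 1)
  }
  up <- 0.5 - 1e-10
  val <- stats::integrate(f, 0, up, rel.tol = 1e-9,
                          subdivisions = 500L)$value
  norm <- stats::pbeta(up, j + 1, L - j + 1)
  min(val / norm, 1)
}

#' Build a statistical-parsimony network
#'
#' Stepwise agglomeration: haplotype pairs are processed in order of
#' increasing raw distance (ties: larger combined sample count first, then
#' lexicographic ids). A pair at distance `d <= j_max` is connected --
#' inserting `d - 1` inferred intermediate ("median") nodes, each carrying
#' zero samples -- when the two haplotypes are in different components, or
#' when their current path through the network is longer than `d` (the
#' latter creates a reticulation, resolved by [resolve_loops()]).
#'
#' @param table a `haplo_table`.
#' @param dm_raw `haplo_dist` of integer raw distances over the haplotypes.
#' @param j_max connection limit in steps (see
#'   [parsimony_connection_limit()]).
#' @return A `haplo_network`: list with `graph` (igraph; vertex attributes
#'   `name`, `count`, `inferred`), `j_max`, and `table`.
#' @export
build_network <- function(table, dm_raw, j_max) {
  stopifnot(inherits(table, "haplo_table"))
  ids <- table$haplotypes$haplotype_id
  cnt <- haplotype_counts(table)
  d <- round(unclass(dm_raw)[ids, ids, drop = FALSE])
  h <- length(ids)
  pairs <- which(upper.tri(d), arr.ind = TRUE)
  pd <- d[pairs]
  keep <- pd <= j_max & pd > 0
  pairs <- pairs[keep, , drop = FALSE]
  pd <- pd[keep]
  comb <- cnt[pairs[, 1]] + cnt[pairs[, 2]]
  id1 <- pmin(ids[pairs[, 1]], ids[pairs[, 2]])
  id2 <- pmax(ids[pairs[, 1]], ids[pairs[, 2]])
  ord <- order(pd, -comb, id1, id2)
  pairs <- pairs[ord, , drop = FALSE]
  pd <- pd[ord]

  g <- igraph::make_empty_graph(n = h, directed = FALSE)
  igraph::V(g)$name <- ids
  igraph::V(g)$count <- as.integer(cnt)
  igraph::V(g)$inferred <- FALSE
  n_median <- 0L
  for (k in seq_len(nrow(pairs))) {
    a <- ids[pairs[k, 1]]; b <- ids[pairs[k, 2]]; dd <- pd[k]
    sp <- igraph::distances(g, v = a, to = b)[1, 1]
    if (is.finite(sp) && sp <= dd) next
    # connect a--b through dd-1 fresh median nodes
    prev <- a
    if (dd > 1L) {
      for (m in seq_len(dd - 1L)) {
        n_median <- n_median + 1L
        med <- sprintf("m%03d", n_median)
        g <- igraph::add_vertices(g, 1, name = med, count = 0L,
                                  inferred = TRUE)
        g <- igraph::add_edges(g, c(prev, med))
        prev <- med
      }
    }
    g <- igraph::add_edges(g, c(prev, b))
  }
  structure(list(graph = g, j_max = j_max, table = table),
            class = "haplo_network")
}

#' @export
print.haplo_network <- function(x, ...) {
  g <- x$graph
  cat("Parsimony network: ", sum(!igraph::V(g)$inferred), " haplotypes + ",
      sum(igraph::V(g)$inferred), " inferred nodes, ",
      igraph::ecount(g), " edges, ",
      igraph::count_components(g), " component(s), connection limit ",
      x$j_max, " steps\n", sep = "")
  invisible(x)
}

#' Resolve reticulations (loops) in a parsimony network
#'
#' Breaks every cycle by deleting its least-supported edge, judged by three
#' ordered criteria borrowed from coalescent theory: (1) frequency --
#' connections to high-frequency haplotypes are more plausible, so the edge
#' with the smallest combined endpoint sample count goes first; (2) network
#' location -- interior (high-degree) connections beat tip connections, so
#' on a frequency tie the edge with the smallest combined endpoint degree
#' goes; (3) geography -- an edge whose endpoints share no sampling area is
#' less plausible than one whose endpoints co-occur. Remaining ties break
#' lexicographically. Every removal is logged with the deciding criterion.
#'
#' @param net a `haplo_network`.
#' @param popmap optional `haplo_popmap` enabling the geography criterion
#'   (areas in which each haplotype was sampled).
#' @return A `haplo_network` with an acyclic graph and a `resolution_log`
#'   data.frame (`edge`, `criterion`).
#' @export
resolve_loops <- function(net, popmap = NULL) {
  g <- net$graph
  table <- net$table
  areas_of <- NULL
  if (!is.null(popmap)) {
    pm <- popmap[match(names(table$membership), popmap$sample_id), ]
    areas_of <- split(pm$site_id, table$membership[pm$sample_id])
  }
  log <- list()
  repeat {
    cyc <- shortest_cycle(g)
    if (is.null(cyc)) break
    scores <- lapply(cyc, function(e) {
      ends <- igraph::ends(g, e)[1, ]
      cntv <- igraph::V(g)$count[match(ends, igraph::V(g)$name)]
      degv <- igraph::degree(g, v = ends)
      share <- if (is.null(areas_of)) NA else
        length(intersect(areas_of[[ends[1]]], areas_of[[ends[2]]])) > 0
      list(freq = sum(cntv), deg = sum(degv), share = share,
           key = paste(sort(ends), collapse = "|"))
    })
    freq <- vapply(scores, `[[`, 0, "freq")
    cand <- which(freq == min(freq))
    crit <- "frequency"
    if (length(cand) > 1L) {
      deg <- vapply(scores, `[[`, 0, "deg")[cand]
      cand <- cand[deg == min(deg)]
      crit <- "network location"
    }
    if (length(cand) > 1L && !is.null(areas_of)) {
      share <- vapply(scores, `[[`, NA, "share")[cand]
      if (any(!share, na.rm = TRUE) && any(share, na.rm = TRUE)) {
        cand <- cand[!share %in% TRUE]
        crit <- "geography"
      }
    }
    if (length(cand) > 1L) {
      keys <- vapply(scores, `[[`, "", "key")[cand]
      cand <- cand[order(keys)][1L]
      crit <- paste(crit, "+ lexicographic tie-break")
    }
    drop <- cyc[cand[1L]]
    log[[length(log) + 1L]] <- data.frame(
      edge = scores[[cand[1L]]]$key, criterion = crit,
      stringsAsFactors = FALSE)
    g <- igraph::delete_edges(g, drop)
    # inferred nodes left dangling by the removal are pruned iteratively
    repeat {
      orphan <- igraph::V(g)$inferred & igraph::degree(g) <= 1
      if (!any(orphan)) break
      g <- igraph::delete_vertices(g, which(orphan))
    }
  }
  out <- net
  out$graph <- g
  out$resolution_log <- if (length(log)) do.call(rbind, log) else
    data.frame(edge = character(), criterion = character(),
               stringsAsFactors = FALSE)
  out
}

# Smallest cycle of a graph as an edge sequence, or NULL if acyclic.
shortest_cycle <- function(g) {
  gr <- igraph::girth(g)
  if (!is.finite(gr$girth) || gr$girth == 0) return(NULL)
  vs <- gr$circle
  if (length(vs) == 0) return(NULL)
  path <- c(as.vector(vs), as.vector(vs)[1])
  igraph::E(g, path = path)
}

#' Regional haplotype summary
#'
#' Tallies each haplotype by range, flags range-exclusive haplotypes and
#' lists the ranges sharing each non-exclusive one.
#'
#' @param table a `haplo_table` built with a population map.
#' @param popmap the `haplo_popmap`.
#' @return data.frame: one row per haplotype with per-range counts,
#'   `exclusive` flag, `ranges` (comma list) and `total`.
#' @export
regional_summary <- function(table, popmap) {
  by_range <- population_haplotype_counts(table, popmap, "range")
  cnt <- t(by_range)    # haplotype x range
  ranges <- colnames(cnt)
  df <- data.frame(haplotype_id = rownames(cnt),
                   stringsAsFactors = FALSE)
  for (r in ranges) df[[r]] <- as.integer(cnt[, r])
  df$total <- as.integer(rowSums(cnt))
  df$n_ranges <- as.integer(rowSums(cnt > 0))
  df$exclusive <- df$n_ranges == 1L
  df$ranges <- apply(cnt > 0, 1L, function(z)
    paste(ranges[z], collapse = ","))
  df[match(table$haplotypes$haplotype_id, df$haplotype_id), , drop = FALSE]
}

#' Export a network as GraphML
#'
#' Vertex attributes: `name`, `count`, `inferred` and one count column per
#' range when a popmap is supplied. Output is deterministic for identical
#' inputs.
#'
#' @param net a `haplo_network`.
#' @param path output path.
#' @param popmap optional `haplo_popmap` for per-range vertex counts.
#' @return `path`, invisibly.
#' @export
write_network_graphml <- function(net, path, popmap = NULL) {
  g <- net$graph
  if (!is.null(popmap)) {
    by_range <- population_haplotype_counts(net$table, popmap, "range")
    for (r in rownames(by_range)) {
      v <- by_range[r, match(igraph::V(g)$name, colnames(by_range))]
      v[is.na(v)] <- 0L
      g <- igraph::set_vertex_attr(g, paste0("count_", r),
                                   value = as.integer(v))
    }
  }
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}

#' Export network edges as TSV
#' @param net a `haplo_network`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_network_edges <- function(net, path) {
  e <- igraph::as_edgelist(net$graph)
  utils::write.table(data.frame(from = e[, 1], to = e[, 2]), path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
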