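# Pairwise sequence distances: Kimura two-parameter and raw differences.
# Sites where either sequence is not A/C/G/T are dropped pair by pair
# (pairwise deletion).

#' Kimura two-parameter distance between two sequences
#'
#' Comparison is restricted to sites where both bases are in `{A,C,G,T}`.
#' With transition proportion `P` and transversion proportion `Q` among the
#' compared sites, the distance is
#' `d = -1/2 * log((1 - 2P - Q) * sqrt(1 - 2Q))` substitutions per site.
#'
#' @param a,b character vectors of bases or single sequence strings of
#'   equal length.
#' @return Distance in substitutions per site.
#' @export
k2p_distance <- function(a, b) {
  if (is.character(a) && length(a) == 1L) a <- strsplit(toupper(a), "")[[1L]]
  if (is.character(b) && length(b) == 1L) b <- strsplit(toupper(b), "")[[1L]]
  if (length(a) != length(b))
    stop("sequences have unequal length", call. = FALSE)
  keep <- is_acgt(a) & is_acgt(b)
  n <- sum(keep)
  if (n == 0L) stop("no comparable sites", call. = FALSE)
  a <- a[keep]; b <- b[keep]
  diff <- a != b
  purine_a <- a %in% c("A", "G")
  purine_b <- b %in% c("A", "G")
  ts <- diff & (purine_a == purine_b)   # transition: within purines/pyrimidines
  P <- sum(ts) / n
  Q <- sum(diff & !ts) / n
  w1 <- 1 - 2 * P - Q
  w2 <- 1 - 2 * Q
  if (w1 <= 0 || w2 <= 0)
    stop("sequences too divergent for the K2P correction (saturation)",
         call. = FALSE)
  -0.5 * log(w1 * sqrt(w2))
}

# Raw difference count between two base vectors, pairwise deletion.
raw_difference <- function(a, b) {
  keep <- is_acgt(a) & is_acgt(b)
  sum(a[keep] != b[keep])
}

#' Pairwise distance matrix
#'
#' @param x a `haplo_alignment` (distances over samples) or a `haplo_table`
#'   (distances over haplotype sequences).
#' @param model `"k2p"` (substitutions per site) or `"raw"` (count of
#'   differing compared sites).
#' @return A `haplo_dist`: symmetric numeric matrix with identifiers as
#'   dimnames.
#' @export
pairwise_distances <- function(x, model = c("k2p", "raw")) {
  model <- match.arg(model)
  if (inherits(x, "haplo_alignment")) {
    m <- unclass(x)
    ids <- rownames(m)
  } else if (inherits(x, "haplo_table")) {
    m <- do.call(rbind, strsplit(x$haplotypes$sequence, ""))
    ids <- x$haplotypes$haplotype_id
  } else stop("x must be an alignment or a haplotype table", call. = FALSE)
  n <- nrow(m)
  d <- matrix(0, n, n, dimnames = list(ids, ids))
  if (n > 1L) {
    for (i in seq_len(n - 1L)) {
      ai <- m[i, ]
      for (j in seq.int(i + 1L, n)) {
        dij <- if (model == "k2p") k2p_distance(ai, m[j, ])
               else raw_difference(ai, m[j, ])
        d[i, j] <- d[j, i] <- dij
      }
    }
  }
  structure(d, class = c("haplo_dist", "matrix", "array"), model = model)
}

# Expand a haplotype-level distance matrix to sample level given a
# haplo_table membership vector (used by AMOVA and mismatch analyses to
# avoid recomputing sample-by-sample distances).
expand_to_samples <- function(d_hap, membership) {
  idx <- match(membership, rownames(d_hap))
  if (anyNA(idx)) stop("membership refers to unknown haplotypes")
  out <- d_hap[idx, idx, drop = FALSE]
  dimnames(out) <- list(names(membership), names(membership))
  out
}
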