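# Raymond & Rousset (1995) exact test of population differentiation:
# a Metropolis Markov chain over contingency tables (populations x
# haplotypes) with fixed margins; the p-value is the proportion of visited
# states whose conditional probability is no larger than the observed
# table's.

# log probability of a table with fixed margins, up to the constant
# involving only the margins: -sum(log(x_ij!)).
log_table_prob <- function(tab) -sum(lfactorial(tab))

#' Exact test of population differentiation
#'
#' @param tab contingency table (matrix) of haplotype counts, populations
#'   in rows, haplotypes in columns; or a `haplo_table` plus `popmap` and
#'   `population` to aggregate counts per population.
#' @param steps Markov-chain length after dememorization (default 100000).
#' @param dememorization burn-in steps (default 10000).
#' @param seed integer seed.
#' @param popmap,population used only when `tab` is a `haplo_table`.
#' @return An `exact_test_result`: `p_value`, `se` (batch-means standard
#'   error), `steps`, `dememorization`, `acceptance_rate`.
#' @details Each update draws two distinct rows and two distinct columns
#'   uniformly and proposes moving one unit around the 2x2 submatrix
#'   (direction chosen at random); the Metropolis acceptance ratio of the
#'   two hypergeometric table probabilities is `a*d / ((b+1)*(c+1))`.
#'   Degenerate tables (a single row or column) return `p = 1`.
#' @export
exact_differentiation_test <- function(tab, steps = 100000,
                                       dememorization = 10000, seed = NULL,
                                       popmap = NULL, population = "area") {
  if (inherits(tab, "haplo_table")) {
    if (is.null(popmap))
      stop("popmap required to aggregate a haplotype table", call. = FALSE)
    tab <- population_haplotype_counts(tab, popmap, population)
  }
  tab <- as.matrix(tab)
  tab <- tab[rowSums(tab) > 0, colSums(tab) > 0, drop = FALSE]
  if (nrow(tab) < 2 || ncol(tab) < 2) {
    return(structure(list(p_value = 1, se = 0, steps = 0L,
                          dememorization = 0L, acceptance_rate = NA_real_),
                     class = "exact_test_result"))
  }
  if (!is.null(seed)) set.seed(seed)
  lp_obs <- log_table_prob(tab)
  cur <- tab
  lp <- lp_obs
  nr <- nrow(tab); nc <- ncol(tab)
  total <- dememorization + steps
  hits <- logical(steps)
  acc <- 0L
  # pre-draw the random streams for speed
  ri <- matrix(replicate(2, sample.int(nr, total, replace = TRUE)), ncol = 2)
  ci <- matrix(replicate(2, sample.int(nc, total, replace = TRUE)), ncol = 2)
  dir_up <- stats::runif(total) < 0.5
  u <- stats::runif(total)
  for (s in seq_len(total)) {
    r1 <- ri[s, 1]; r2 <- ri[s, 2]; c1 <- ci[s, 1]; c2 <- ci[s, 2]
    if (r1 != r2 && c1 != c2) {
      # move one unit: (r1,c1)&(r2,c2) down, (r1,c2)&(r2,c1) up (or reverse)
      if (dir_up[s]) { a <- cur[r1, c1]; d <- cur[r2, c2]
                       b <- cur[r1, c2]; cc <- cur[r2, c1] }
      else           { a <- cur[r1, c2]; d <- cur[r2, c1]
                       b <- cur[r1, c1]; cc <- cur[r2, c2] }
      if (a > 0 && d > 0) {
        ratio <- (a * d) / ((b + 1) * (cc + 1))
        if (u[s] < ratio) {
          if (dir_up[s]) {
            cur[r1, c1] <- a - 1; cur[r2, c2] <- d - 1
            cur[r1, c2] <- b + 1; cur[r2, c1] <- cc + 1
          } else {
            cur[r1, c2] <- a - 1; cur[r2, c1] <- d - 1
            cur[r1, c1] <- b + 1; cur[r2, c2] <- cc + 1
          }
          lp <- lp + log(ratio)
          acc <- acc + 1L
        }
      }
    }
    if (s > dememorization) hits[s - dememorization] <- lp <= lp_obs + 1e-9
  }
  p <- mean(hits)
  nb <- min(100L, steps)
  batch <- split(hits, cut(seq_len(steps), nb, labels = FALSE))
  bm <- vapply(batch, mean, 0)
  se <- stats::sd(bm) / sqrt(length(bm))
  structure(list(p_value = p, se = se, steps = steps,
                 dememorization = dememorization,
                 acceptance_rate = acc / total),
            class = "exact_test_result")
}

#' @export
print.exact_test_result <- function(x, ...) {
  cat("Exact test of differentiation: p =", format(x$p_value, digits = 4),
      "+/-", format(x$se, digits = 2),
      sprintf("(%d steps, %d dememorization)\n", x$steps, x$dememorization))
  invisible(x)
}

#' Population-by-haplotype count table
#'
#' Aggregates per-site haplotype counts to the chosen population level.
#'
#' @param table a `haplo_table` built with a population map.
#' @param popmap the `haplo_popmap`.
#' @param population `"area"`, `"site_id"` or `"range"`.
#' @return integer matrix populations x haplotypes.
#' @export
population_haplotype_counts <- function(table, popmap,
                                        population = "area") {
  sites <- colnames(table$counts)
  lvl <- popmap[[population]][match(sites, popmap$site_id)]
  if (anyNA(lvl)) stop("sites in table missing from popmap", call. = FALSE)
  rowsum(t(table$counts), lvl, reorder = FALSE)
}
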