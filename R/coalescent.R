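# Coalescent simulator in mutational-time units.
#
# Time x is measured so that the expected number of differences between a
# pair of sequences whose lineages coalesce at age x is x (tau = 2*u*t
# scaling). In these units a population of scaled size theta gives each
# lineage pair a coalescence rate 1/theta, and mutations fall on every
# lineage at rate 1/2 per unit time, independent of theta. Simulator
# parameters therefore plug directly into the sudden-expansion mismatch
# expectation.
#
# Trees are stored in arrays: nodes 1..n are tips, n+1..2n-1 internal in
# coalescence order; `parent`, `child1`, `child2`, `time`. The branch of
# node v is the edge to its parent. Subtree tip sets are walked lazily,
# only for mutated branches.

#' Demographic model descriptor
#'
#' @param kind `"constant"`, `"step_expansion"` or `"two_range_split"`.
#' @param theta scaled population size (constant model).
#' @param theta0 ancestral scaled size (before the expansion, small).
#' @param theta1 current scaled size (after the expansion, large).
#' @param tau expansion age in mutational time units.
#' @param split_time split age in mutational units (two-range model).
#' @param theta_anc ancestral size after the two ranges merge (backwards in
#'   time); defaults to `theta0`.
#' @return A `demographic_model` list.
#' @export
demographic_model <- function(kind = c("constant", "step_expansion",
                                       "two_range_split"),
                              theta = 1, theta0 = 0.1, theta1 = 100,
                              tau = 3, split_time = 10, theta_anc = NULL) {
  kind <- match.arg(kind)
  stopifnot(theta >= 0, theta0 >= 0, theta1 >= 0, tau >= 0, split_time >= 0)
  structure(list(kind = kind, theta = theta, theta0 = theta0,
                 theta1 = theta1, tau = tau, split_time = split_time,
                 theta_anc = if (is.null(theta_anc)) theta0 else theta_anc),
            class = "demographic_model")
}

# Epochs (begin time, theta) for a single-population model.
model_epochs <- function(model) {
  switch(model$kind,
         constant = list(begin = 0, theta = model$theta),
         step_expansion = list(begin = c(0, model$tau),
                               theta = c(model$theta1, model$theta0)),
         stop("two_range_split has no single-population epoch table"))
}

# Fresh tree state for n tips.
new_tree_state <- function(n) {
  M <- 2L * n - 1L
  list(n = n, parent = integer(M), child1 = integer(M),
       child2 = integer(M), time = numeric(M), next_node = n)
}

# Coalesce the given active nodes under piecewise-constant theta, from
# time t until one lineage remains or t_stop. Mutates and returns the
# state, plus the surviving node set and stop time.
coalesce_nodes <- function(state, active, t, epochs, t_stop = Inf) {
  ne <- length(epochs$begin)
  ep <- 1L
  while (ep < ne && epochs$begin[ep + 1L] <= t) ep <- ep + 1L
  k <- length(active)
  while (k > 1L && t < t_stop) {
    th <- epochs$theta[ep]
    nxt <- if (ep < ne) epochs$begin[ep + 1L] else Inf
    t_next <- if (th == 0) t else
      t + stats::rexp(1L, rate = k * (k - 1) / 2 / th)
    if (t_next >= min(nxt, t_stop)) {
      if (nxt <= t_stop) { t <- nxt; ep <- ep + 1L } else t <- t_stop
      next
    }
    t <- t_next
    pair <- sample.int(k, 2L)
    i <- active[pair[1L]]; j <- active[pair[2L]]
    v <- state$next_node <- state$next_node + 1L
    state$child1[v] <- i; state$child2[v] <- j
    state$parent[i] <- state$parent[j] <- v
    state$time[v] <- t
    active[pair[1L]] <- v
    active <- active[-pair[2L]]
    k <- k - 1L
  }
  list(state = state, active = active, t = t)
}

# Branch lengths indexed by node (0 for root / unused slots).
branch_lengths <- function(state) {
  len <- numeric(length(state$parent))
  has <- state$parent > 0L
  len[has] <- state$time[state$parent[has]] - state$time[has]
  len
}

# Tips below each node: subtree sizes bottom-up (children are created
# before their parent, so a single sweep works).
subtree_sizes <- function(state) {
  n <- state$n
  size <- integer(length(state$parent))
  size[seq_len(n)] <- 1L
  for (v in seq.int(n + 1L, state$next_node)) {
    size[v] <- size[state$child1[v]] + size[state$child2[v]]
  }
  size
}

# Tip indices below node v (iterative stack walk).
tips_under <- function(state, v) {
  n <- state$n
  if (v <= n) return(v)
  out <- integer(0)
  stack <- v
  while (length(stack)) {
    u <- stack[length(stack)]
    stack <- stack[-length(stack)]
    if (u <= n) out[length(out) + 1L] <- u
    else stack <- c(stack, state$child1[u], state$child2[u])
  }
  out
}

# Full genealogy of n tips under a single-population model.
sim_genealogy <- function(n, model) {
  res <- coalesce_nodes(new_tree_state(n), seq_len(n), 0,
                        model_epochs(model))
  st <- res$state
  st$tmrca <- res$t
  st
}

# Poisson mutation counts per branch (rate 1/2 per unit mutational time).
drop_mutations <- function(branch_len) {
  stats::rpois(length(branch_len), branch_len / 2)
}

# Summary statistics straight from a mutated genealogy, without building
# sequences: segregating sites, mean pairwise differences, haplotype count.
genealogy_stats <- function(state, n_mut) {
  n <- state$n
  mutated <- which(n_mut > 0L)
  S <- sum(n_mut)
  if (S == 0L) return(list(S = 0L, k_hat = 0, k_obs = 1L))
  size <- subtree_sizes(state)[mutated]
  k_hat <- sum(n_mut[mutated] * size * (n - size)) / (n * (n - 1) / 2)
  keys <- character(n)
  for (b in mutated) {
    tips <- tips_under(state, b)
    keys[tips] <- paste0(keys[tips], b, ",")
  }
  list(S = S, k_hat = k_hat, k_obs = length(unique(keys)))
}

# Pairwise raw-difference matrix from a mutated genealogy.
genealogy_pairdiff <- function(state, n_mut) {
  n <- state$n
  mutated <- which(n_mut > 0L)
  if (!length(mutated)) return(matrix(0L, n, n))
  Z <- matrix(0L, length(mutated), n)
  for (i in seq_along(mutated)) Z[i, tips_under(state, mutated[i])] <- 1L
  w <- n_mut[mutated]
  cross <- t(Z) %*% (w * Z)
  u <- colSums(w * Z)
  d <- outer(u, u, "+") - 2 * cross
  diag(d) <- 0L
  d
}

#' Simulate sequences under the coalescent
#'
#' Simulates a standard n-coalescent under the given demographic model,
#' drops Poisson mutations on the branches (rate 1/2 per lineage per unit
#' mutational time) and writes them on distinct alignment columns
#' (infinite-sites model; each mutation replaces the ancestral base by a
#' different one). Under the step-expansion model the pairwise coalescence
#' age density is exactly the two-phase exponential used by
#' [mismatch_expected()].
#'
#' @param model a [demographic_model()] (`constant` or `step_expansion`).
#' @param n sample size.
#' @param L alignment length in sites (must exceed the realised number of
#'   mutations).
#' @param seed integer seed.
#' @param marker_name marker label for the alignment.
#' @param coding optional `list(frame, region, genetic_code)` declaring a
#'   protein-coding sub-region: the ancestral sequence is drawn stop-free
#'   there and mutations that would create an internal stop codon are
#'   redirected to another base or column, so simulated mitochondrial
#'   fragments always pass [numt_screen()].
#' @return A `haplo_simdata` list: `alignment`, `popmap` (single
#'   range/area/site), and `truth` (`tmrca`, `n_mutations`, `model`,
#'   `seed`).
#' @export
simulate_coalescent <- function(model, n, L = 1000, seed = NULL,
                                marker_name = "sim", coding = NULL) {
  stopifnot(n >= 2)
  if (!is.null(seed)) set.seed(seed)
  tree <- sim_genealogy(n, model)
  n_mut <- drop_mutations(branch_lengths(tree))
  aln <- mutations_to_alignment(tree, n_mut, L, marker_name = marker_name,
                                coding = coding)
  popmap <- as_popmap(data.frame(sample_id = rownames(aln),
                                 range = "R1", area = "A1", site_id = "S1",
                                 stringsAsFactors = FALSE))
  structure(list(alignment = aln, popmap = popmap,
                 truth = list(tmrca = tree$tmrca,
                              n_mutations = sum(n_mut),
                              model = model, seed = seed)),
            class = "haplo_simdata")
}

# Build an alignment from per-branch mutation counts: one distinct column
# per mutation, ancestral base replaced by a different base in all samples
# below the branch. When `coding` is declared, the ancestral sequence is
# drawn without stop codons in the coding region and any substitution that
# would create an internal stop in a carrier is redirected (another base,
# else another column), so the fragment stays NUMT-clean.
mutations_to_alignment <- function(state, n_mut, L,
                                   sample_ids = sprintf("ind%03d",
                                                        seq_len(state$n)),
                                   marker_name = "sim", coding = NULL) {
  n <- state$n
  M <- sum(n_mut)
  if (M > L)
    stop("alignment length L = ", L, " exhausted by ", M,
         " mutations; increase L", call. = FALSE)
  bases <- c("A", "C", "G", "T")
  anc <- sample(bases, L, replace = TRUE)
  codon_start <- NULL
  stops <- c("TAA", "TAG")   # translation table 5 (invertebrate mito)
  if (!is.null(coding)) {
    frame <- coding$frame %||% 1L
    region <- coding$region %||% c(1L, L)
    first <- region[1] + frame - 1L
    codon_start <- seq.int(first, region[2] - 2L, by = 3L)
    for (cs in codon_start) {              # stop-free ancestral backbone
      while (paste(anc[cs:(cs + 2L)], collapse = "") %in% stops)
        anc[cs:(cs + 2L)] <- sample(bases, 3L, replace = TRUE)
    }
  }
  m <- matrix(rep(anc, each = n), nrow = n)
  free <- rep(TRUE, L)
  makes_stop <- function(rows, col, base) {
    if (is.null(codon_start)) return(FALSE)
    if (col < codon_start[1] || col > codon_start[length(codon_start)] + 2L)
      return(FALSE)
    cs <- codon_start[(col - codon_start[1]) %/% 3L + 1L]
    if (is.na(cs) || col < cs || col > cs + 2L) return(FALSE)
    cod <- m[rows, cs:(cs + 2L), drop = FALSE]
    cod[, col - cs + 1L] <- base
    any(apply(cod, 1L, paste, collapse = "") %in% stops)
  }
  for (b in which(n_mut > 0L)) {
    tips <- tips_under(state, b)
    for (r in seq_len(n_mut[b])) {
      placed <- FALSE
      while (!placed) {
        avail <- which(free)
        col <- avail[sample.int(length(avail), 1L)]
        cand <- sample(setdiff(bases, anc[col]))
        for (derived in cand) {
          if (!makes_stop(tips, col, derived)) {
            m[tips, col] <- derived
            free[col] <- FALSE
            placed <- TRUE
            break
          }
        }
        if (!placed && sum(free) <= 1L)
          stop("alignment length L exhausted while avoiding stop codons; ",
               "increase L", call. = FALSE)
        if (!placed) free[col] <- FALSE    # column unusable for this branch
      }
    }
  }
  rownames(m) <- sample_ids
  as_alignment(m, marker_name = marker_name)
}

#' Simulate a two-range split scenario
#'
#' Two demes with no migration: backwards in time, each deme follows its
#' own sudden-expansion history until `split_time`, when the surviving
#' lineages of both demes merge into a single ancestral population of size
#' `theta_anc`. Samples are spread over `n_sites_per_deme` collection sites
#' per deme (sites are labels only; demes are panmictic), giving the
#' range > area > site hierarchy used by the structure analyses.
#'
#' @param n_per_deme integer vector (length 2) of deme sample sizes.
#' @param model a [demographic_model()] with `kind = "two_range_split"`;
#'   `theta0`, `theta1`, `tau` describe each deme's expansion, `split_time`
#'   and `theta_anc` the ancestral phase.
#' @param L alignment length in sites.
#' @param seed integer seed.
#' @param n_sites_per_deme number of site labels per deme (default 2).
#' @return A `haplo_simdata` (see [simulate_coalescent()]).
#' @export
simulate_two_range_scenario <- function(n_per_deme, model, L = 2000,
                                        seed = NULL, n_sites_per_deme = 2) {
  stopifnot(length(n_per_deme) == 2, all(n_per_deme >= 1))
  if (!is.null(seed)) set.seed(seed)
  n <- sum(n_per_deme)
  deme_tips <- split(seq_len(n), rep(1:2, n_per_deme))
  within <- model_epochs(demographic_model("step_expansion",
                                           theta0 = model$theta0,
                                           theta1 = model$theta1,
                                           tau = model$tau))
  state <- new_tree_state(n)
  surv <- list()
  for (d in 1:2) {
    res <- coalesce_nodes(state, deme_tips[[d]], 0, within,
                          t_stop = model$split_time)
    state <- res$state
    surv[[d]] <- res$active
  }
  anc <- coalesce_nodes(state, c(surv[[1]], surv[[2]]), model$split_time,
                        list(begin = 0, theta = model$theta_anc))
  state <- anc$state
  n_mut <- drop_mutations(branch_lengths(state))
  aln <- mutations_to_alignment(state, n_mut, L,
                                marker_name = "two_range_sim")
  site_of <- integer(n)
  for (d in 1:2) {
    tips <- deme_tips[[d]]
    site_of[tips] <- (seq_along(tips) - 1L) %% n_sites_per_deme + 1L
  }
  deme_of <- rep(1:2, n_per_deme)
  popmap <- as_popmap(data.frame(
    sample_id = rownames(aln),
    range = paste0("range", deme_of),
    area = paste0("range", deme_of, "_site", site_of),
    site_id = paste0("range", deme_of, "_site", site_of),
    stringsAsFactors = FALSE))
  structure(list(alignment = aln, popmap = popmap,
                 truth = list(tmrca = anc$t,
                              n_mutations = sum(n_mut),
                              model = model, seed = seed)),
            class = "haplo_simdata")
}

#' @export
print.haplo_simdata <- function(x, ...) {
  cat("Simulated dataset:", nrow(x$alignment), "sequences x",
      ncol(x$alignment), "sites;", x$truth$n_mutations,
      "mutations; TMRCA", format(x$truth$tmrca, digits = 4), "\n")
  invisible(x)
}

#' Write a simulated dataset to disk
#'
#' Emits FASTA, population-map TSV and a truth JSON (model parameters,
#' seed, TMRCA, mutation count).
#'
#' @param sim a `haplo_simdata`.
#' @param dir output directory (created if needed).
#' @param prefix file-name prefix.
#' @return Named character vector of the three paths, invisibly.
#' @export
write_simdata <- function(sim, dir, prefix = "sim") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  fa <- file.path(dir, paste0(prefix, ".fasta"))
  pm <- file.path(dir, paste0(prefix, "_popmap.tsv"))
  js <- file.path(dir, paste0(prefix, "_truth.json"))
  write_fasta(sim$alignment, fa)
  write_population_map(sim$popmap, pm)
  truth <- sim$truth
  truth$model <- unclass(truth$model)
  jsonlite::write_json(truth, js, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(c(fasta = fa, popmap = pm, truth = js))
}
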