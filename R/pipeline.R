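# Configuration-driven pipeline: concatenation, NUMT screen, haplotype
# collapsing, site classification, diversity, differentiation (exact test
# + AMOVA), parsimony network with regional summary, and demographic
# history (neutrality tests, mismatch fit, expansion dating), written as
# TSV/GraphML/JSON into an output directory. A run is a pure function of
# (inputs, config, seed): identical runs give identical output bytes.

#' Default run configuration
#'
#' @return Named list of defaults; see [run_pipeline()] for the keys.
#' @export
default_config <- function() {
  list(
    fasta = NULL,            # named list/vector marker -> path
    popmap = NULL,           # path to population-map TSV
    out_dir = "haplopop_out",
    seed = 1L,
    population = "area",     # popmap column defining populations
    group_by = "range",      # popmap column defining AMOVA groups
    amova_exclude = character(),   # ranges excluded from AMOVA/exact test
    demography_by = "range", # pooling level for the demographic analyses
    demography_include = NULL,     # subset of pooling levels (NULL = all)
    n_permutations = 10000,
    exact_steps = 100000,
    exact_dememorization = 10000,
    bootstrap = 10000,
    neutrality_sims = 1000,
    network_cutoff = 0.95,
    rates = c(2.3e-8, 2.6e-8),     # divergence per site per year
    numt = NULL)             # list(marker, frame, region, genetic_code)
}

#' Read a pipeline configuration from YAML
#'
#' Unknown keys are rejected; missing keys fall back to
#' [default_config()]. Relative input paths are resolved against the YAML
#' file's directory.
#'
#' @param path YAML file.
#' @return Config list.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  base <- default_config()
  unknown <- setdiff(names(cfg), names(base))
  if (length(unknown))
    stop("unknown config keys: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  out <- utils::modifyList(base, cfg)
  rel <- function(p) ifelse(startsWith(p, "/"), p,
                            file.path(dirname(path), p))
  if (!is.null(out$fasta)) out$fasta <- lapply(out$fasta, rel)
  if (!is.null(out$popmap)) out$popmap <- rel(out$popmap)
  out
}

validate_config <- function(config) {
  if (is.null(config$fasta) || length(config$fasta) < 1)
    stop("config error: no input FASTA declared", call. = FALSE)
  if (is.null(config$popmap))
    stop("config error: no population map declared", call. = FALSE)
  stopifnot(config$network_cutoff > 0, config$network_cutoff < 1,
            all(config$rates > 0), config$n_permutations >= 0,
            config$bootstrap >= 0, config$exact_steps > 0)
  invisible(config)
}

stage_msg <- function(stage, ...) {
  message("[", stage, "] ", ...)
}

#' Run the full analysis pipeline
#'
#' Executes, in order: read + concatenate markers, optional NUMT screen,
#' haplotype collapsing and site classification, per-area diversity
#' summary, exact differentiation test and hierarchical AMOVA (optionally
#' excluding ranges), parsimony network with loop resolution and regional
#' summary, and per-range demographic history (Tajima's D, Fu's Fs,
#' mismatch fit, expansion times at each configured rate). All tables are
#' written under `config$out_dir` together with a `run_meta.json` carrying
#' the seed, package version and config hash.
#'
#' @param config list as produced by [default_config()] /
#'   [read_run_config()]; alternatively a path to a YAML file.
#' @return Invisibly, a list with every stage result and `out_dir`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config) && length(config) == 1L)
    config <- read_run_config(config)
  config <- utils::modifyList(default_config(), config)
  validate_config(config)
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  set.seed(config$seed)
  out <- list(config = config, out_dir = config$out_dir)
  tsv <- function(df, name) {
    utils::write.table(df, file.path(config$out_dir, name), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }

  stage_msg("input", "reading ", length(config$fasta), " marker(s)")
  alns <- lapply(seq_along(config$fasta), function(i)
    read_fasta(config$fasta[[i]],
               marker_name = names(config$fasta)[i] %||%
                 basename(config$fasta[[i]])))
  popmap <- read_population_map(config$popmap)
  aln <- concatenate(alns)
  out$alignment <- aln

  if (!is.null(config$numt)) {
    nm <- config$numt
    stage_msg("numt", "screening marker region for internal stop codons")
    scr <- numt_screen(aln, frame = nm$frame %||% 1,
                       region = nm$region,
                       genetic_code = nm$genetic_code %||% 5)
    tsv(scr, "numt_screen.tsv")
    if (any(!scr$pass))
      warning("NUMT screen flagged: ",
              paste(scr$sample_id[!scr$pass], collapse = ", "))
    out$numt <- scr
  }

  stage_msg("haplotypes", "collapsing and classifying sites")
  table <- collapse_haplotypes(aln, popmap)
  cls <- classify_sites(aln)
  out$haplotypes <- table
  out$site_classification <- cls
  write_haplotype_table(table, file.path(config$out_dir,
                                         "haplotype_table.tsv"))

  stage_msg("diversity", "per-", config$population, " summary")
  div <- summarize_populations(aln, popmap, grouping = config$population)
  tsv(div, "diversity.tsv")
  out$diversity <- div

  stage_msg("structure", "exact test and AMOVA")
  keep_range <- !(popmap$range %in% config$amova_exclude)
  pm_kept <- as_popmap(popmap[keep_range, , drop = FALSE])
  aln_kept <- as_alignment(unclass(aln)[rownames(aln) %in%
                                          pm_kept$sample_id, ,
                                        drop = FALSE],
                           marker_name = attr(aln, "marker"),
                           partitions = attr(aln, "partitions"))
  table_kept <- collapse_haplotypes(aln_kept, pm_kept)
  ct <- population_haplotype_counts(table_kept, pm_kept,
                                    config$population)
  out$exact_test <- exact_differentiation_test(
    ct, steps = config$exact_steps,
    dememorization = config$exact_dememorization,
    seed = config$seed + 1L)
  dm_raw_kept <- expand_to_samples(
    pairwise_distances(table_kept, "raw"), table_kept$membership)
  pops <- unique(pm_kept[[config$population]])
  grouping <- stats::setNames(
    pm_kept[[config$group_by]][match(pops, pm_kept[[config$population]])],
    pops)
  out$amova <- amova(dm_raw_kept, pm_kept, grouping,
                     population = config$population,
                     n_permutations = config$n_permutations,
                     seed = config$seed + 2L)
  write_amova(out$amova, file.path(config$out_dir, "amova.tsv"))

  stage_msg("network", "parsimony network at ",
            100 * config$network_cutoff, "% cut-off")
  dm_hap <- pairwise_distances(table, "raw")
  j_max <- parsimony_connection_limit(ncol(aln), config$network_cutoff)
  net <- resolve_loops(build_network(table, dm_hap, j_max), popmap)
  out$network <- net
  write_network_graphml(net, file.path(config$out_dir, "network.graphml"),
                        popmap)
  write_network_edges(net, file.path(config$out_dir, "network_edges.tsv"))
  reg <- regional_summary(table, popmap)
  tsv(reg, "regional_summary.tsv")
  out$regional_summary <- reg

  stage_msg("demography", "neutrality, mismatch and dating per ",
            config$demography_by)
  levels_all <- unique(popmap[[config$demography_by]])
  levels_use <- config$demography_include %||% levels_all
  demo_rows <- list()
  out$demography <- list()
  for (lv in intersect(levels_use, levels_all)) {
    ids <- popmap$sample_id[popmap[[config$demography_by]] == lv]
    sub <- as_alignment(unclass(aln)[rownames(aln) %in% ids, ,
                                     drop = FALSE],
                        marker_name = lv)
    if (nrow(sub) < 4) next
    nt <- neutrality_tests(sub, n_sim = config$neutrality_sims,
                           seed = config$seed + 3L)
    mm <- mismatch_observed(pairwise_distances(sub, "raw"))
    fit <- fit_sudden_expansion(mm, n = nrow(sub), B = config$bootstrap,
                                seed = config$seed + 4L)
    times <- lapply(config$rates, function(r)
      expansion_time(fit$tau, ncol(sub), r, fit$tau_ci))
    hist_df <- data.frame(differences = seq_along(mm$freq) - 1L,
                          observed = mm$freq,
                          expected = mismatch_expected(
                            length(mm$freq) - 1L, fit$tau, fit$theta0,
                            fit$theta1))
    tsv(hist_df, paste0("mismatch_", gsub("[^A-Za-z0-9]", "_", lv),
                        ".tsv"))
    row <- data.frame(group = lv, n = nt$n, S = nt$S,
                      mean_mismatch = mm$mean,
                      D = nt$D, p_D = nt$p_D, Fs = nt$Fs, p_Fs = nt$p_Fs,
                      SSD = fit$SSD, p_SSD = fit$p_SSD,
                      raggedness = fit$raggedness, p_r = fit$p_r,
                      tau = fit$tau, tau_lo = fit$tau_ci[1],
                      tau_hi = fit$tau_ci[2], stringsAsFactors = FALSE)
    for (i in seq_along(config$rates)) {
      nm <- paste0("t_ka_rate", i)
      row[[nm]] <- times[[i]]$t_ka
      row[[paste0(nm, "_lo")]] <- times[[i]]$ci_ka[1]
      row[[paste0(nm, "_hi")]] <- times[[i]]$ci_ka[2]
    }
    demo_rows[[lv]] <- row
    out$demography[[lv]] <- list(neutrality = nt, mismatch = mm,
                                 fit = fit, times = times)
  }
  if (length(demo_rows)) {
    demo_tab <- do.call(rbind, demo_rows)
    tsv(demo_tab, "demography.tsv")
    out$demography_table <- demo_tab
  }

  meta <- list(seed = config$seed,
               package_version = as.character(
                 utils::packageVersion("haplopop")),
               config_hash = config_hash(config))
  jsonlite::write_json(meta, file.path(config$out_dir, "run_meta.json"),
                       auto_unbox = TRUE)
  stage_msg("done", "outputs in ", config$out_dir)
  invisible(out)
}

config_hash <- function(config) {
  config$out_dir <- NULL
  s <- paste(utils::capture.output(utils::str(config)), collapse = "\n")
  # small deterministic polynomial hash; avoids external digest deps
  h <- 0
  for (ch in utf8ToInt(s)) h <- (h * 31 + ch) %% 1e9
  sprintf("%09.0f", h)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
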