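# Hierarchical population map: sample -> site -> area -> range.

#' Construct a population map
#'
#' @param df data.frame with columns `sample_id`, `range`, `area`, `site_id`
#'   and optionally `lat`, `lon` (decimal degrees).
#' @return A `haplo_popmap` (a validated data.frame).
#' @details The hierarchy is strict: every sample belongs to exactly one
#'   site, every site to exactly one area, every area to exactly one range.
#' @export
as_popmap <- function(df) {
  need <- c("sample_id", "range", "area", "site_id")
  if (!all(need %in% names(df)))
    stop("population map requires columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  for (v in need) df[[v]] <- as.character(df[[v]])
  if (anyDuplicated(df$sample_id))
    stop("sample assigned more than once: ",
         paste(unique(df$sample_id[duplicated(df$sample_id)]),
               collapse = ", "), call. = FALSE)
  site_area <- unique(df[, c("site_id", "area")])
  if (anyDuplicated(site_area$site_id))
    stop("site listed under more than one area: ",
         paste(unique(site_area$site_id[duplicated(site_area$site_id)]),
               collapse = ", "), call. = FALSE)
  area_range <- unique(df[, c("area", "range")])
  if (anyDuplicated(area_range$area))
    stop("area listed under more than one range: ",
         paste(unique(area_range$area[duplicated(area_range$area)]),
               collapse = ", "), call. = FALSE)
  class(df) <- c("haplo_popmap", "data.frame")
  df
}

#' Read a population map from TSV
#'
#' Expected columns: `sample_id`, `range`, `area`, `site_id` and optionally
#' `lat`, `lon`.
#'
#' @param path path to a tab-separated file with a header line.
#' @return A `haplo_popmap`.
#' @export
read_population_map <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = "character")
  for (v in intersect(c("lat", "lon"), names(df)))
    df[[v]] <- as.numeric(df[[v]])
  as_popmap(df)
}

#' Write a population map as TSV
#' @param popmap a `haplo_popmap`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_population_map <- function(popmap, path) {
  utils::write.table(popmap, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

# Align a popmap against an alignment: every sample must be assigned.
match_popmap <- function(aln, popmap) {
  stopifnot(inherits(aln, "haplo_alignment"), inherits(popmap, "haplo_popmap"))
  miss <- setdiff(rownames(aln), popmap$sample_id)
  if (length(miss))
    stop("samples missing from population map: ",
         paste(utils::head(miss, 5L), collapse = ", "), call. = FALSE)
  popmap[match(rownames(aln), popmap$sample_id), , drop = FALSE]
}
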