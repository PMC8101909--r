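# Aligned-sequence container and FASTA I/O.
#
# An alignment is stored as an upper-case character matrix (samples x sites)
# with unique rownames; '-' and 'N' (and IUPAC ambiguity codes) are treated
# as missing data throughout, never as additional states.

IUPAC_CHARS <- c("A", "C", "G", "T", "N", "-", "R", "Y", "S", "W", "K", "M",
                 "B", "D", "H", "V", "?")

#' Construct an alignment object
#'
#' @param x character matrix (samples in rows, sites in columns) or a named
#'   character vector of equal-length sequence strings.
#' @param marker_name name of the marker the alignment covers.
#' @param partitions optional named integer vector of partition lengths
#'   (must sum to the alignment length).
#' @return An object of class `haplo_alignment`: a character matrix with
#'   attributes `marker` and `partitions`.
#' @export
as_alignment <- function(x, marker_name = "marker", partitions = NULL) {
  if (is.character(x) && !is.matrix(x)) {
    if (is.null(names(x)) || anyDuplicated(names(x)))
      stop("sequences must carry unique names", call. = FALSE)
    lens <- nchar(x)
    if (length(unique(lens)) != 1L)
      stop("ragged alignment: sequence lengths differ (",
           paste(range(lens), collapse = "-"), ")", call. = FALSE)
    m <- do.call(rbind, strsplit(toupper(x), "", fixed = TRUE))
    rownames(m) <- names(x)
    x <- m
  }
  if (!is.matrix(x) || !is.character(x))
    stop("alignment must be a character matrix", call. = FALSE)
  if (is.null(rownames(x)) || anyDuplicated(rownames(x)))
    stop("duplicate or missing sample identifiers", call. = FALSE)
  x[] <- toupper(x)
  bad <- setdiff(unique(as.vector(x)), IUPAC_CHARS)
  if (length(bad))
    stop("non-IUPAC characters in alignment: ",
         paste(bad, collapse = " "), call. = FALSE)
  if (is.null(partitions)) {
    partitions <- stats::setNames(ncol(x), marker_name)
  } else if (sum(partitions) != ncol(x)) {
    stop("partition lengths do not sum to alignment length", call. = FALSE)
  }
  structure(x, marker = marker_name, partitions = partitions,
            class = c("haplo_alignment", "matrix", "array"))
}

#' Read an aligned FASTA file
#'
#' Accepts any line wrapping. All sequences must have identical length;
#' identifiers must be unique; characters outside the IUPAC alphabet
#' (plus `-` and `?`) are rejected.
#'
#' @param path path to a FASTA file.
#' @param marker_name marker label attached to the alignment.
#' @return A `haplo_alignment`.
#' @export
read_fasta <- function(path, marker_name = basename(path)) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  dna <- ape::read.FASTA(path)
  if (length(dna) == 0L) stop("empty FASTA: ", path, call. = FALSE)
  seqs <- vapply(as.character(dna), paste, "", collapse = "")
  as_alignment(seqs, marker_name = marker_name)
}

#' Write an alignment as FASTA
#'
#' @param aln a `haplo_alignment`.
#' @param path output path.
#' @param width line-wrap width (default 70 columns).
#' @return `path`, invisibly.
#' @export
write_fasta <- function(aln, path, width = 70) {
  stopifnot(inherits(aln, "haplo_alignment"))
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(aln))) {
    s <- paste(aln[i, ], collapse = "")
    starts <- seq(1L, nchar(s), by = width)
    writeLines(c(paste0(">", rownames(aln)[i]),
                 substring(s, starts, pmin(starts + width - 1L, nchar(s)))),
               con)
  }
  invisible(path)
}

#' Concatenate per-marker alignments
#'
#' Joins partitions sample-by-sample in the order given. All partitions must
#' contain exactly the same sample identifiers; no imputation of missing
#' samples is attempted. Partition boundaries are recorded in the result.
#'
#' @param alignments list of `haplo_alignment` objects.
#' @param marker_name name for the combined alignment.
#' @return A `haplo_alignment` whose `partitions` attribute records the
#'   length of each input partition.
#' @export
concatenate <- function(alignments, marker_name = "combined") {
  stopifnot(is.list(alignments), length(alignments) >= 1L)
  lapply(alignments, function(a) stopifnot(inherits(a, "haplo_alignment")))
  if (length(alignments) == 1L) return(alignments[[1L]])
  ids <- rownames(alignments[[1L]])
  for (a in alignments[-1L]) {
    if (!setequal(rownames(a), ids))
      stop("sample sets differ between partitions; refusing to concatenate",
           call. = FALSE)
  }
  mats <- lapply(alignments, function(a) unclass(a)[ids, , drop = FALSE])
  parts <- vapply(alignments, function(a) ncol(a), 0L)
  names(parts) <- vapply(alignments, function(a) attr(a, "marker"), "")
  as_alignment(do.call(cbind, mats), marker_name = marker_name,
               partitions = parts)
}

#' @export
print.haplo_alignment <- function(x, ...) {
  cat("Alignment '", attr(x, "marker"), "': ", nrow(x), " sequences x ",
      ncol(x), " sites\n", sep = "")
  p <- attr(x, "partitions")
  if (length(p) > 1L)
    cat("Partitions:", paste(names(p), p, sep = "=", collapse = ", "), "\n")
  invisible(x)
}

# TRUE where a base is one of A/C/G/T (the only states used in analyses).
is_acgt <- function(x) x %in% c("A", "C", "G", "T")
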