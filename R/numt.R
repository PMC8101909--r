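# NUMT screening: nuclear copies of mitochondrial fragments accumulate
# in-frame stop codons, so a clean translation of the coding sub-region is
# evidence that the amplified fragment is genuinely mitochondrial.

#' Screen sequences for internal stop codons
#'
#' Translates the declared coding sub-region of every sequence in the
#' declared reading frame and flags any sequence whose peptide contains an
#' internal stop codon. The frame is never auto-detected: picking the frame
#' that minimises stops would mask real NUMTs.
#'
#' @param aln a `haplo_alignment`.
#' @param frame reading frame, 1, 2 or 3 (offset into the region).
#' @param region optional `c(start, end)` (1-based, inclusive) coding
#'   sub-region; defaults to the whole alignment.
#' @param genetic_code NCBI translation table number; default 5
#'   (invertebrate mitochondrial).
#' @return data.frame with `sample_id`, `n_internal_stops`, `pass`.
#' @export
numt_screen <- function(aln, frame = 1, region = NULL, genetic_code = 5) {
  stopifnot(inherits(aln, "haplo_alignment"))
  if (!frame %in% 1:3) stop("frame must be 1, 2 or 3", call. = FALSE)
  m <- unclass(aln)
  if (is.null(region)) region <- c(1L, ncol(m))
  stopifnot(length(region) == 2L, region[1] >= 1L, region[2] <= ncol(m))
  res <- lapply(seq_len(nrow(m)), function(i) {
    sub <- tolower(m[i, region[1]:region[2]])
    aa <- seqinr::translate(sub, frame = frame - 1L, numcode = genetic_code,
                            ambiguous = TRUE)
    n_stop <- sum(aa[-length(aa)] == "*")   # terminal stop is legitimate
    data.frame(sample_id = rownames(m)[i], n_internal_stops = n_stop,
               pass = n_stop == 0L, stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}
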