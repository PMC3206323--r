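## Transcript-coordinate machinery.
##
## "Transcript orientation" means position 1 is the transcript's 5' end:
## for minus-strand transcripts that is the exon with the highest
## chromosomal coordinates, and sequences are reverse-complemented.

tx_length <- function(tx) sum(tx$exons$end - tx$exons$start + 1)

## Spliced transcript position(s) of chromosomal position(s); NA for
## intronic / outside positions.
genomic_to_tx <- function(tx, gpos) {
  ex <- tx$exons
  w <- ex$end - ex$start + 1
  before <- c(0, cumsum(w))[seq_len(nrow(ex))]
  out <- rep(NA_real_, length(gpos))
  for (i in seq_len(nrow(ex))) {
    hit <- gpos >= ex$start[[i]] & gpos <= ex$end[[i]]
    out[hit] <- before[[i]] + gpos[hit] - ex$start[[i]] + 1
  }
  if (tx$strand == -1L) out <- tx_length(tx) - out + 1
  out
}

## Spliced transcript sequence in transcript orientation.
tx_sequence <- function(tx, genome) {
  parts <- mapply(function(s, e) fetch_slice(genome, tx$chromosome, s, e),
                  tx$exons$start, tx$exons$end)
  seq <- paste(parts, collapse = "")
  if (tx$strand == -1L) revcomp(seq) else seq
}

## [start, end] of the coding span in transcript coordinates.
cds_tx_range <- function(tx) {
  stopifnot(is_coding_tx(tx))
  sort(genomic_to_tx(tx, c(tx$coding_start, tx$coding_end)))
}

cds_sequence <- function(tx, genome) {
  r <- cds_tx_range(tx)
  substr(tx_sequence(tx, genome), r[[1L]], r[[2L]])
}

## Intron bounds (chromosomal, 1-based inclusive); zero-row frame for
## single-exon transcripts.
intron_bounds <- function(tx) {
  ex <- tx$exons
  if (nrow(ex) < 2L) return(data.frame(start = numeric(), end = numeric()))
  data.frame(start = ex$end[-nrow(ex)] + 1, end = ex$start[-1L] - 1)
}

#' Locate a variant within a transcript
#'
#' @param tx A [transcript()].
#' @param start,end Chromosomal interval of the variant (for insertions the
#'   insertion point, `start == end`).
#' @return List with `location` (`"EXONIC"`, `"INTRONIC"` or
#'   `"EXON_BOUNDARY_SPANNING"`) and coordinates of the containing feature:
#'   for EXONIC, `exon_index` (genomic order) and the exon bounds; for
#'   INTRONIC, `intron_index` and the intron bounds; for boundary-spanning
#'   variants, the indices of fully covered exons/introns and of covered
#'   exon-start / exon-end junctions (genomic orientation).
#' @export
locate_in_transcript <- function(tx, start, end = start) {
  s <- max(start, tx$start); e <- min(end, tx$end)
  ex <- tx$exons
  inside <- which(ex$start <= s & e <= ex$end)
  if (length(inside) == 1L) {
    return(list(location = "EXONIC", exon_index = inside,
                exon_start = ex$start[[inside]], exon_end = ex$end[[inside]]))
  }
  intr <- intron_bounds(tx)
  within_intron <- which(intr$start <= s & e <= intr$end)
  if (length(within_intron) == 1L) {
    return(list(location = "INTRONIC", intron_index = within_intron,
                intron_start = intr$start[[within_intron]],
                intron_end = intr$end[[within_intron]]))
  }
  covered_exons <- which(s <= ex$start & ex$end <= e)
  covered_introns <- if (nrow(intr)) which(s <= intr$start & intr$end <= e)
                     else integer()
  ## junction k at an exon's genomic start exists for exons 2..n, at an
  ## exon's genomic end for exons 1..n-1; "covered" = the deletion removes
  ## at least one base on each side of the junction.
  start_junctions <- which(seq_len(nrow(ex)) > 1L &
                             s <= ex$start - 1 & e >= ex$start)
  end_junctions <- which(seq_len(nrow(ex)) < nrow(ex) &
                           s <= ex$end & e >= ex$end + 1)
  list(location = "EXON_BOUNDARY_SPANNING",
       covered_exons = covered_exons, covered_introns = covered_introns,
       start_junctions = start_junctions, end_junctions = end_junctions)
}
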