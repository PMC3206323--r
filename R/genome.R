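#' Reference genome with per-chromosome coordinate offsets
#'
#' Holds chromosome (or chromosome-slice) sequences.  Each sequence may
#' represent a slice of a chromosome starting at an arbitrary 1-based
#' chromosomal position (`offset`), so that a short stretch of sequence can
#' be addressed with its true chromosomal coordinates.  An offset of 1
#' (the default) means the sequence is the whole chromosome.
#'
#' @param sequences Named character vector or `DNAStringSet`, one element
#'   per chromosome.
#' @param offsets 1-based chromosomal position of the first stored base of
#'   each sequence; a single value is recycled.  Default 1.
#' @return An object of class `"reference_genome"`.
#' @export
reference_genome <- function(sequences, offsets = 1) {
  if (methods::is(sequences, "DNAStringSet")) {
    sequences <- as.character(sequences)
  }
  if (is.null(names(sequences)) || any(!nzchar(names(sequences)))) {
    stop("sequences must be named by chromosome")
  }
  sequences <- toupper(sequences)
  if (length(offsets) == 1L) offsets <- rep(offsets, length(sequences))
  names(offsets) <- names(sequences)
  structure(list(sequences = sequences, offsets = offsets),
            class = "reference_genome")
}

#' Read a reference genome from a FASTA file
#'
#' Sequence names are the first whitespace-separated token of each header.
#' A header token of the form `offset=N` sets the chromosomal offset of that
#' sequence (see [reference_genome()]).
#'
#' @param path FASTA file.
#' @return A `"reference_genome"`.
#' @export
read_genome_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  ss <- Biostrings::readDNAStringSet(path)
  headers <- names(ss)
  names(ss) <- vapply(strsplit(headers, "\\s+"), `[[`, "", 1L)
  offs <- vapply(headers, function(h) {
    m <- regmatches(h, regexpr("offset=\\d+", h))
    if (length(m) == 1L && nzchar(m)) as.numeric(sub("offset=", "", m)) else 1
  }, numeric(1))
  reference_genome(ss, offsets = unname(offs))
}

#' @export
print.reference_genome <- function(x, ...) {
  cat("reference_genome:", length(x$sequences), "sequence(s)\n")
  for (nm in names(x$sequences)) {
    cat(sprintf("  %s: %d bp, chromosomal span %d-%d\n", nm,
                nchar(x$sequences[[nm]]), x$offsets[[nm]],
                x$offsets[[nm]] + nchar(x$sequences[[nm]]) - 1))
  }
  invisible(x)
}

## Chromosomal [start, end] covered by a stored sequence.
genome_bounds <- function(genome, chromosome) {
  if (!chromosome %in% names(genome$sequences)) {
    stop("chromosome '", chromosome, "' not in reference genome")
  }
  off <- genome$offsets[[chromosome]]
  c(off, off + nchar(genome$sequences[[chromosome]]) - 1)
}

#' Extract a genome slice
#'
#' @param genome A `"reference_genome"`.
#' @param chromosome Chromosome name.
#' @param start,end 1-based inclusive chromosomal coordinates.
#' @return Uppercase sequence string.  Out-of-range requests are an error,
#'   never a silent truncation.
#' @export
fetch_slice <- function(genome, chromosome, start, end = start) {
  b <- genome_bounds(genome, chromosome)
  if (start > end) stop("fetch_slice: start > end")
  if (start < b[[1]] || end > b[[2]]) {
    stop(sprintf("fetch_slice: %s:%d-%d outside stored range %d-%d",
                 chromosome, start, end, b[[1]], b[[2]]))
  }
  off <- genome$offsets[[chromosome]]
  substr(genome$sequences[[chromosome]], start - off + 1, end - off + 1)
}

#' Map a relative position to a chromosomal position
#'
#' Input variant lists carry positions relative to the reference sequence
#' used in the resequencing experiment; when that sequence is a slice of a
#' chromosome, its 1-based chromosomal start position (`ref_offset`)
#' converts relative to chromosomal coordinates.
#'
#' @param rel_pos Relative position(s), 1-based.
#' @param ref_offset Chromosomal position of the first base of the
#'   reference sequence.  `ref_offset = 1` is the identity.
#' @return Chromosomal position(s): `rel_pos + ref_offset - 1`.
#' @examples
#' chrom_pos(100, 1)     # 100
#' chrom_pos(1, 5001)    # 5001
#' @export
chrom_pos <- function(rel_pos, ref_offset = 1) {
  stopifnot(all(rel_pos >= 1), ref_offset >= 1)
  rel_pos + ref_offset - 1
}

#' Check a variant's reference allele against the genome
#'
#' A mismatching reference allele is a data condition, not an error: the
#' variant is kept in the output with all annotation fields NA and counted
#' in the run report.
#'
#' @param chromosome,start,end Chromosomal coordinates of the variant
#'   (insertions have `ref_allele = ""` and nothing to verify).
#' @param ref_allele Reference allele claimed by the input (possibly `""`).
#' @param genome A `"reference_genome"`.
#' @return List with `matched` (logical) and `genome_ref` (the slice the
#'   genome holds at that span, `""` for insertions).
#' @export
verify_ref <- function(genome, chromosome, start, end, ref_allele) {
  if (!nzchar(ref_allele)) {
    return(list(matched = TRUE, genome_ref = ""))
  }
  b <- genome_bounds(genome, chromosome)
  if (start < b[[1]] || end > b[[2]]) {
    return(list(matched = FALSE, genome_ref = NA_character_))
  }
  slice <- fetch_slice(genome, chromosome, start, end)
  list(matched = identical(slice, toupper(ref_allele)), genome_ref = slice)
}
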