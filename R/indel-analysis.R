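## Indel normalization, equivalence grouping, repeat period and genesis.
##
## A pure insertion or deletion placed inside a repeat tract can be written
## at many positions that all produce the identical edited sequence.  The
## canonical representation is the left-most equivalent placement, obtained
## by rotating the indel sequence leftwards while the flanking base allows
## it; two indel records are the same event iff their canonical forms are
## equal.

new_canonical_indel <- function(chromosome, canonical_pos, op, sequence) {
  structure(list(chromosome = chromosome, canonical_pos = canonical_pos,
                 op = op, sequence = sequence),
            class = "canonical_indel")
}

#' @export
print.canonical_indel <- function(x, ...) {
  cat(sprintf("canonical_indel %s of %s at %s:%g\n",
              x$op, x$sequence, x$chromosome, x$canonical_pos))
  invisible(x)
}

canonical_key <- function(ci) {
  paste(ci$chromosome, ci$op, ci$canonical_pos, ci$sequence, sep = "|")
}

## Trim bases shared by ref and alt (prefix then suffix); returns the pure
## ins/del remainder or errors if both sides stay non-empty.
trim_to_pure_indel <- function(pos, ref, alt) {
  while (nzchar(ref) && nzchar(alt) &&
         substr(ref, 1L, 1L) == substr(alt, 1L, 1L)) {
    ref <- substr(ref, 2L, nchar(ref))
    alt <- substr(alt, 2L, nchar(alt))
    pos <- pos + 1
  }
  while (nzchar(ref) && nzchar(alt) &&
         substr(ref, nchar(ref), nchar(ref)) ==
           substr(alt, nchar(alt), nchar(alt))) {
    ref <- substr(ref, 1L, nchar(ref) - 1L)
    alt <- substr(alt, 1L, nchar(alt) - 1L)
  }
  if (nzchar(ref) && nzchar(alt)) {
    stop("not a pure insertion or deletion after trimming shared bases")
  }
  list(pos = pos, ref = ref, alt = alt)
}

#' Left-normalize an insertion or deletion
#'
#' The indel is shifted left one base at a time while the edited chromosome
#' remains unchanged: a placement at `pos` with sequence `s` moves to
#' `pos - 1` iff the base at `pos - 1` equals the last base of `s`, in
#' which case `s` rotates (that base moves to its front).  Shifting stops
#' at the left edge of the stored genome window.
#'
#' Position conventions: a deletion at `pos` removes `pos .. pos+L-1`; an
#' insertion at `pos` places its bases between `pos - 1` and `pos`.
#'
#' @param genome A [reference_genome()].
#' @param chromosome Chromosome name.
#' @param pos Chromosomal position of the indel (see conventions above).
#' @param ref_allele,alt_allele Allele pair; after trimming shared bases
#'   exactly one side must be empty.
#' @return A `"canonical_indel"`: `chromosome`, `canonical_pos`, `op`
#'   (`"INSERTION"`/`"DELETION"`), `sequence` (at the canonical placement).
#' @export
canonicalize <- function(genome, chromosome, pos, ref_allele, alt_allele) {
  tr <- trim_to_pure_indel(pos, toupper(ref_allele), toupper(alt_allele))
  pos <- tr$pos
  if (nzchar(tr$ref)) {
    op <- "DELETION"; seq <- tr$ref
    genome_seq <- fetch_slice(genome, chromosome, pos, pos + nchar(seq) - 1)
    if (genome_seq != seq) {
      stop(sprintf("deletion allele %s does not match genome %s at %s:%g",
                   seq, genome_seq, chromosome, pos))
    }
  } else {
    op <- "INSERTION"; seq <- tr$alt
  }
  lo <- genome_bounds(genome, chromosome)[[1L]]
  L <- nchar(seq)
  while (pos - 1 >= lo) {
    prev <- fetch_slice(genome, chromosome, pos - 1)
    if (prev != substr(seq, L, L)) break
    seq <- paste0(prev, substr(seq, 1L, L - 1L))
    pos <- pos - 1
  }
  new_canonical_indel(chromosome, pos, op, seq)
}

## Canonicalize an already-canonical indel (used for the idempotence
## property and by the known-variant store).
canonicalize_ci <- function(genome, ci) {
  if (ci$op == "DELETION") {
    canonicalize(genome, ci$chromosome, ci$canonical_pos, ci$sequence, "")
  } else {
    canonicalize(genome, ci$chromosome, ci$canonical_pos, "", ci$sequence)
  }
}

#' Group equivalently placed indels
#'
#' Partitions indel records by canonical form; groups of size > 1 are
#' records that annotate one and the same event at different placements
#' within a repeat tract.
#'
#' @param indels Data frame with columns `name`, `chromosome`, `pos`,
#'   `ref_allele`, `alt_allele` (gap alleles as `""` or `"-"`).
#' @param genome A [reference_genome()].
#' @return The input data frame with added columns `canonical_pos`, `op`,
#'   `sequence` and `group` (integer group id; equal ids mean equivalent
#'   indels).  Groups are numbered by first appearance.
#' @export
group_equivalent <- function(indels, genome) {
  stopifnot(all(c("name", "chromosome", "pos", "ref_allele", "alt_allele")
                %in% names(indels)))
  norm_gap <- function(x) ifelse(x %in% c("-", "—", "."), "", toupper(x))
  keys <- character(nrow(indels))
  cpos <- numeric(nrow(indels)); op <- character(nrow(indels))
  sq <- character(nrow(indels))
  for (i in seq_len(nrow(indels))) {
    ci <- canonicalize(genome, indels$chromosome[[i]], indels$pos[[i]],
                       norm_gap(indels$ref_allele[[i]]),
                       norm_gap(indels$alt_allele[[i]]))
    keys[[i]] <- canonical_key(ci)
    cpos[[i]] <- ci$canonical_pos; op[[i]] <- ci$op; sq[[i]] <- ci$sequence
  }
  out <- indels
  out$canonical_pos <- cpos; out$op <- op; out$sequence <- sq
  out$group <- match(keys, unique(keys))
  out
}

#' Repeat period length of a sequence
#'
#' The smallest `p >= 1` with `s[i] == s[i + p]` for all valid `i` (the
#' string-combinatorics period).  A period shorter than the sequence length
#' reveals repeat-unit structure; period equal to length means no internal
#' repeat.
#'
#' @param sequence Non-empty nucleotide string.
#' @return Integer period in bp.
#' @examples
#' period_length("AAAAA")   # 1
#' period_length("TGATGA")  # 3
#' period_length("GAGGCT")  # 6
#' @export
period_length <- function(sequence) {
  if (!nzchar(sequence)) stop("period_length: empty sequence")
  s <- strsplit(toupper(sequence), NULL)[[1L]]
  n <- length(s)
  for (p in seq_len(n)) {
    if (p == n || all(s[seq_len(n - p)] == s[seq_len(n - p) + p])) return(p)
  }
  n
}

## Flank coordinates of an indel: a deletion occupies pos..pos+L-1 on the
## genome, an insertion occupies nothing (its point lies between pos-1 and
## pos).  Returns the chromosomal ranges immediately left/right of the
## event, each of width `w`.
indel_flanks <- function(pos, op, L, w) {
  right0 <- if (op == "DELETION") pos + L else pos
  list(left = c(pos - w, pos - 1), right = c(right0, right0 + w - 1))
}

fetch_clipped <- function(genome, chromosome, start, end) {
  b <- genome_bounds(genome, chromosome)
  s <- max(start, b[[1L]]); e <- min(end, b[[2L]])
  if (s > e) "" else fetch_slice(genome, chromosome, s, e)
}

#' Evolutionary genesis report for an indel
#'
#' Flags how an insertion/deletion may have arisen:
#' * `is_duplication`: its sequence equals the immediately adjacent
#'   upstream or downstream genome sequence of equal length;
#' * `is_inversion_of_flank`: it equals the inversion (character reversal
#'   by default, see [annotation_config()]) of an adjacent equal-length
#'   flank;
#' * `is_shift`: its sequence occurs elsewhere within `shift_window` bp of
#'   either flank, but not adjacently;
#' * `period_length`: repeat period of the indel sequence;
#' * `transposon_flag`: see [transposon_flag()].
#'
#' Flags are independent of each other.  A flank truncated by the edge of
#' the stored sequence sets the affected flag to `NA`.
#'
#' @param genome A [reference_genome()].
#' @param chromosome Chromosome name.
#' @param pos Indel position (conventions as in [canonicalize()]).
#' @param op `"INSERTION"` or `"DELETION"`.
#' @param sequence Inserted/deleted bases.
#' @param shift_window Scan window in bp for the shift flag (default 50).
#' @param inversion `"reverse"` or `"revcomp"`.
#' @return A list of class `"genesis_report"`.
#' @export
genesis <- function(genome, chromosome, pos, op, sequence,
                    shift_window = 50, inversion = c("reverse", "revcomp")) {
  inversion <- match.arg(inversion)
  sequence <- toupper(sequence)
  L <- nchar(sequence)
  stopifnot(L >= 1L, op %in% c("INSERTION", "DELETION"))
  fl <- indel_flanks(pos, op, L, L)
  left <- fetch_clipped(genome, chromosome, fl$left[[1L]], fl$left[[2L]])
  right <- fetch_clipped(genome, chromosome, fl$right[[1L]], fl$right[[2L]])
  full <- c(left = nchar(left) == L, right = nchar(right) == L)
  inv_seq <- if (inversion == "reverse") str_rev(sequence) else
    revcomp(sequence)

  flag_vs_flanks <- function(probe) {
    if (!any(full)) return(NA)
    hits <- c(if (full[["left"]]) left == probe,
              if (full[["right"]]) right == probe)
    if (any(hits)) TRUE else if (all(full)) FALSE else NA
  }
  is_dup <- flag_vs_flanks(sequence)
  is_inv <- flag_vs_flanks(inv_seq)

  ## shift: occurrence in a wider window that is not the adjacent placement
  sf <- indel_flanks(pos, op, L, shift_window + L)
  left_scan <- fetch_clipped(genome, chromosome, sf$left[[1L]], sf$left[[2L]])
  right_scan <- fetch_clipped(genome, chromosome, sf$right[[1L]],
                              sf$right[[2L]])
  occurs_nonadjacent <- function(scan, adjacent_at_end) {
    if (nchar(scan) < L) return(FALSE)
    occ <- gregexpr(sequence, scan, fixed = TRUE)[[1L]]
    if (occ[[1L]] == -1L) return(FALSE)
    adj <- if (adjacent_at_end) nchar(scan) - L + 1L else 1L
    any(occ != adj)
  }
  is_shift <- occurs_nonadjacent(left_scan, adjacent_at_end = TRUE) ||
    occurs_nonadjacent(right_scan, adjacent_at_end = FALSE)

  structure(list(is_duplication = is_dup, is_inversion_of_flank = is_inv,
                 is_shift = is_shift, period_length = period_length(sequence),
                 transposon_flag = transposon_flag(genome, chromosome, pos,
                                                   op, sequence,
                                                   inversion = inversion)),
            class = "genesis_report")
}

#' Transposon flank check
#'
#' An indel is flagged as a potential transposon when its sequence (or its
#' inversion) occurs as a substring of the 13 bp of flanking sequence on
#' either side.  Sequences longer than 13 bp are probed by their first and
#' last 13 bp.
#'
#' @inheritParams genesis
#' @return Logical flag.
#' @export
transposon_flag <- function(genome, chromosome, pos, op, sequence,
                            inversion = c("reverse", "revcomp")) {
  inversion <- match.arg(inversion)
  sequence <- toupper(sequence)
  L <- nchar(sequence)
  stopifnot(L >= 1L)
  probes <- if (L <= 13L) sequence else {
    c(substr(sequence, 1L, 13L), substr(sequence, L - 12L, L))
  }
  probes <- unique(c(probes, if (inversion == "reverse") str_rev(probes)
                             else revcomp(probes)))
  fl <- indel_flanks(pos, op, L, 13L)
  flanks <- c(fetch_clipped(genome, chromosome, fl$left[[1L]], fl$left[[2L]]),
              fetch_clipped(genome, chromosome, fl$right[[1L]],
                            fl$right[[2L]]))
  any(vapply(probes, function(p) {
    any(vapply(flanks, function(f) {
      nchar(f) >= nchar(p) && grepl(p, f, fixed = TRUE)
    }, logical(1)))
  }, logical(1)))
}
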