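## Functional classification of variants against transcript models.

#' Positional class relative to the nearest gene
#'
#' @param distance Signed distance from [nearest_gene()] (negative = gene
#'   before the variant in chromosome coordinates, 0 = inside the gene
#'   span).
#' @param gene_strand Strand of the nearest gene (`+1`/`-1`).
#' @param threshold Distance threshold in bp (default 5000); beyond it the
#'   variant is INTERGENIC, within it UPSTREAM or DOWNSTREAM of the gene in
#'   the gene's own orientation (upstream regions of this extent usually
#'   harbour promoters), at 0 the variant is GENIC and per-transcript
#'   classification takes over.
#' @return `"INTERGENIC"`, `"UPSTREAM"`, `"DOWNSTREAM"` or `"GENIC"`.
#' @export
region_class <- function(distance, gene_strand, threshold = 5000) {
  if (is.infinite(distance) || abs(distance) > threshold) return("INTERGENIC")
  if (distance == 0) return("GENIC")
  variant_after_gene <- distance < 0
  if (xor(variant_after_gene, gene_strand == -1L)) "DOWNSTREAM" else "UPSTREAM"
}

#' Splice-window classes for a variant near an exon/intron boundary
#'
#' The windows are symmetric in both region ends, so no strand information
#' is needed: in an intron, the first/last `essential` bases are
#' ESSENTIAL_SPLICE_SITE and bases `essential + 1 .. intron_window` from
#' either end are SPLICE_SITE; in an exon, the first/last `exon_window`
#' bases are SPLICE_SITE.  A spanning variant gets a class when any of its
#' covered bases falls into a window.  Splice classes are additive to the
#' positional class of the variant.
#'
#' @param variant_start,variant_end Covered chromosomal interval.
#' @param region_start,region_end Bounds of the containing intron or exon.
#' @param region `"intron"` or `"exon"`.
#' @param config An [annotation_config()].
#' @return Character vector: subset of
#'   `c("ESSENTIAL_SPLICE_SITE", "SPLICE_SITE")`.
#' @export
splice_class <- function(variant_start, variant_end, region_start,
                         region_end, region = c("intron", "exon"),
                         config = annotation_config()) {
  region <- match.arg(region)
  ## offsets of covered bases from the left and right region ends
  from_left <- c(variant_start - region_start + 1,
                 variant_end - region_start + 1)
  from_right <- c(region_end - variant_end + 1,
                  region_end - variant_start + 1)
  covers <- function(off, win) off[[1L]] <= win[[2L]] && off[[2L]] >= win[[1L]]
  out <- character()
  if (region == "intron") {
    ess <- c(1, config$essential_intron_window)
    spl <- c(config$essential_intron_window + 1, config$splice_intron_window)
    if (covers(from_left, ess) || covers(from_right, ess)) {
      out <- c(out, "ESSENTIAL_SPLICE_SITE")
    }
    if (covers(from_left, spl) || covers(from_right, spl)) {
      out <- c(out, "SPLICE_SITE")
    }
  } else if (config$splice_exon_window > 0) {
    win <- c(1, config$splice_exon_window)
    if (covers(from_left, win) || covers(from_right, win)) {
      out <- c(out, "SPLICE_SITE")
    }
  }
  out
}

#' UTR class of an exonic position outside the coding span
#'
#' Orientation-aware: "before the start codon" means 5' in transcript
#' direction, so the same chromosomal position is 5PRIME_UTR on a
#' plus-strand transcript and 3PRIME_UTR on a minus-strand transcript
#' whose coding span lies 5' of it.  Non-coding transcripts always yield
#' WITHIN_NON_CODING_TRANSCRIPT.
#'
#' @param tx A [transcript()].
#' @param start,end Chromosomal interval of the variant (exonic, outside
#'   the coding span).
#' @return One class name.
#' @export
utr_class <- function(tx, start, end = start) {
  if (!is_coding_tx(tx)) return("WITHIN_NON_CODING_TRANSCRIPT")
  before_cds <- end < tx$coding_start
  after_cds <- start > tx$coding_end
  stopifnot(before_cds || after_cds)
  if (xor(before_cds, tx$strand == -1L)) "5PRIME_UTR" else "3PRIME_UTR"
}

#' Codon-level consequence of a substitution variant
#'
#' Builds the spliced coding sequence in transcript orientation (minus
#' strand: reverse complement), substitutes each alternative allele and
#' compares the affected codon(s).  The reported codon string is the first
#' affected codon with an IUPAC symbol covering reference and alternative
#' bases at each variable position.  Classes: SYNONYMOUS_CODING iff every
#' alternative amino acid equals the reference; otherwise
#' NON_SYNONYMOUS_CODING, with STOP_GAINED / STOP_LOST when an alternative
#' or the reference codon is a stop (depending on which side constitutes
#' the stop), and START_LOST for a non-synonymous change in the initiation
#' codon.
#'
#' @param tx A coding [transcript()].
#' @param genome A [reference_genome()].
#' @param start,end Chromosomal interval of the substitution.
#' @param ref_allele Reference allele (plus-strand orientation).
#' @param alt_alleles Alternative alleles of the same length as the
#'   reference (plus-strand orientation); alleles equal to the reference
#'   are ignored.
#' @param code A [load_genetic_code()] result.
#' @return List with `classes`, `codon`, `amino_acid` (alternative
#'   residue(s), `/`-joined when alternatives differ), `ref_amino_acid`.
#' @export
coding_effect <- function(tx, genome, start, end, ref_allele, alt_alleles,
                          code = load_genetic_code()) {
  stopifnot(is_coding_tx(tx), nchar(ref_allele) == end - start + 1)
  alt_alleles <- setdiff(toupper(alt_alleles), toupper(ref_allele))
  stopifnot(length(alt_alleles) >= 1L,
            all(nchar(alt_alleles) == nchar(ref_allele)))
  cds <- cds_sequence(tx, genome)
  n_codon <- nchar(cds) %/% 3L
  if (nchar(cds) %% 3L != 0L) {
    warning("coding span of ", tx$transcript_id,
            " is not a multiple of 3; trailing partial codon ignored",
            call. = FALSE)
  }
  cds_start_tx <- cds_tx_range(tx)[[1L]]
  pos_all <- seq(start, end)
  cp <- genomic_to_tx(tx, pos_all) - cds_start_tx + 1
  valid <- !is.na(cp) & cp >= 1 & cp <= n_codon * 3L
  if (!any(valid)) stop("variant does not touch a complete codon")

  to_tx_char <- function(chars) {
    if (tx$strand == -1L) complement_base(chars) else chars
  }
  ref_chars_tx <- to_tx_char(strsplit(toupper(ref_allele), NULL)[[1L]])
  substitute_cds <- function(alt) {
    alt_chars_tx <- to_tx_char(strsplit(alt, NULL)[[1L]])
    s <- strsplit(cds, NULL)[[1L]]
    s[cp[valid]] <- alt_chars_tx[valid]
    paste(s, collapse = "")
  }
  codon_of <- function(seq, i) substr(seq, 3L * i - 2L, 3L * i)
  affected <- sort(unique((cp[valid] - 1L) %/% 3L + 1L))

  classes <- character()
  alt_aa <- character(length(alt_alleles))
  ref_aa <- paste(vapply(affected, function(i) aa3_of(codon_of(cds, i), code),
                         ""), collapse = "")
  for (k in seq_along(alt_alleles)) {
    alt_cds <- substitute_cds(alt_alleles[[k]])
    aa_parts <- character(length(affected))
    for (j in seq_along(affected)) {
      i <- affected[[j]]
      rc <- codon_of(cds, i); ac <- codon_of(alt_cds, i)
      aa_parts[[j]] <- aa3_of(ac, code)
      if (ac == rc) next
      ref_stop <- is_stop_codon(rc, code); alt_stop <- is_stop_codon(ac, code)
      cls <- if (ref_stop && !alt_stop) "STOP_LOST"
        else if (alt_stop && !ref_stop) "STOP_GAINED"
        else if (code$table[[ac]] != code$table[[rc]]) {
          if (i == 1L) "START_LOST" else "NON_SYNONYMOUS_CODING"
        } else "SYNONYMOUS_CODING"
      classes <- c(classes, cls)
    }
    alt_aa[[k]] <- paste(aa_parts, collapse = "")
  }
  change <- setdiff(classes, "SYNONYMOUS_CODING")
  classes <- if (length(change)) unique(change) else "SYNONYMOUS_CODING"

  ## display codon: first affected codon, IUPAC at variable positions
  i0 <- affected[[1L]]
  codon_chars <- strsplit(codon_of(cds, i0), NULL)[[1L]]
  for (p in 1L:3L) {
    cpos <- 3L * (i0 - 1L) + p
    hit <- which(valid & cp == cpos)
    if (length(hit) == 1L) {
      bases <- c(codon_chars[[p]],
                 vapply(alt_alleles, function(a) {
                   to_tx_char(substr(a, hit, hit))
                 }, ""))
      codon_chars[[p]] <- iupac_symbol(bases)
    }
  }
  list(classes = classes, codon = paste(codon_chars, collapse = ""),
       amino_acid = paste(unique(alt_aa), collapse = "/"),
       ref_amino_acid = ref_aa)
}

#' Scan for a variant-created ATG start codon
#'
#' Applied to substitution variants in the 5' UTR of a coding transcript or
#' in the exon of a non-coding transcript: the three transcript-orientation
#' trinucleotide windows covering each variant position are examined, and
#' POTENTIAL_START_GAINED is reported iff some window reads ATG with an
#' alternative allele substituted but not in the reference.  Windows
#' extending past the transcript edge are skipped.
#'
#' @inheritParams coding_effect
#' @return `TRUE` if an ATG is created, else `FALSE`.
#' @export
start_gained_scan <- function(tx, genome, start, end, ref_allele,
                              alt_alleles) {
  alt_alleles <- setdiff(toupper(alt_alleles), toupper(ref_allele))
  alt_alleles <- alt_alleles[nchar(alt_alleles) == nchar(ref_allele)]
  if (length(alt_alleles) == 0L) return(FALSE)
  txseq <- tx_sequence(tx, genome)
  tp <- genomic_to_tx(tx, seq(start, end))
  if (anyNA(tp)) return(FALSE)
  p1 <- min(tp); p2 <- max(tp)
  for (alt in alt_alleles) {
    alt_tx <- if (tx$strand == -1L) revcomp(alt) else alt
    edited <- txseq
    substr(edited, p1, p2) <- alt_tx
    for (w in max(1L, p1 - 2L):min(p2, nchar(txseq) - 2L)) {
      if (substr(edited, w, w + 2L) == "ATG" &&
          substr(txseq, w, w + 2L) != "ATG") {
        return(TRUE)
      }
    }
  }
  FALSE
}

## Frame consequence of a length-changing allele fully inside the coding
## part of an exon.
frame_class <- function(ref_allele, alt_allele) {
  if (abs(nchar(alt_allele) - nchar(ref_allele)) %% 3L == 0L) {
    "FRAMEKEEP"
  } else {
    "FRAMESHIFT"
  }
}

#' Complex-deletion subclass for a deletion spanning exon/intron structure
#'
#' * covers an entire exon (plus any flank) -> DELETE_EXONS
#' * covers an entire intron without deleting a whole exon -> MERGE_EXONS
#' * covers the junction at the transcript-orientation start of an exon
#'   (its acceptor splice site) -> ACCEPTOR
#' * covers the junction at the transcript-orientation end of an exon (its
#'   donor splice site) -> DONOR
#'
#' When a splice site is deleted the emerging splice pattern is unknown, so
#' these subclasses suppress FRAMEKEEP/FRAMESHIFT for the transcript.
#'
#' @param tx A [transcript()].
#' @param start,end Chromosomal interval of the deletion.
#' @return Character vector of subclasses (possibly several).
#' @export
indel_coding_effect <- function(tx, start, end) {
  loc <- locate_in_transcript(tx, start, end)
  if (loc$location != "EXON_BOUNDARY_SPANNING") return(character())
  if (length(loc$covered_exons) > 0L) return("DELETE_EXONS")
  if (length(loc$covered_introns) > 0L) return("MERGE_EXONS")
  out <- character()
  ## genomic exon-start junction = acceptor on plus strand, donor on minus
  if (length(loc$start_junctions) > 0L) {
    out <- c(out, if (tx$strand == 1L) "ACCEPTOR" else "DONOR")
  }
  if (length(loc$end_junctions) > 0L) {
    out <- c(out, if (tx$strand == 1L) "DONOR" else "ACCEPTOR")
  }
  unique(out)
}

## --- per-transcript annotation -------------------------------------------

## Returns list(region_label, classes, codon, amino_acid, ref_amino_acid).
annotate_transcript <- function(tx, genome, code, config,
                                start, end, ref_allele, alt_alleles) {
  classes <- character()
  codon <- aa <- ref_aa <- NA_character_
  alts <- setdiff(alt_alleles, ref_allele)
  subst_alts <- alts[nchar(alts) == nchar(ref_allele)]
  indel_alts <- alts[nchar(alts) != nchar(ref_allele)]
  noncoding <- !is_coding_tx(tx)
  loc <- locate_in_transcript(tx, start, end)
  region_label <- NA_character_

  if (loc$location == "INTRONIC") {
    region_label <- if (noncoding) "WITHIN_NON_CODING_TRANSCRIPT"
                    else "INTRONIC"
    deletes_whole_intron <- any(nchar(indel_alts) < nchar(ref_allele)) &&
      start <= loc$intron_start && end >= loc$intron_end
    if (deletes_whole_intron) {
      ## deleting an intron end-to-end fuses its flanking exons; the
      ## protein stays computable, so no splice/frame classes apply
      classes <- "MERGE_EXONS"
    } else {
      classes <- c(classes, region_label)
      classes <- c(classes, splice_class(start, end, loc$intron_start,
                                         loc$intron_end, "intron", config))
    }
  } else if (loc$location == "EXONIC") {
    classes <- c(classes, splice_class(start, end, loc$exon_start,
                                       loc$exon_end, "exon", config))
    if (noncoding) {
      region_label <- "WITHIN_NON_CODING_TRANSCRIPT"
      classes <- c(classes, region_label)
      if (length(subst_alts) &&
          start_gained_scan(tx, genome, start, end, ref_allele, subst_alts)) {
        classes <- c(classes, "POTENTIAL_START_GAINED")
      }
    } else if (end < tx$coding_start || start > tx$coding_end) {
      region_label <- utr_class(tx, start, end)
      classes <- c(classes, region_label)
      if (region_label == "5PRIME_UTR" && length(subst_alts) &&
          start_gained_scan(tx, genome, start, end, ref_allele, subst_alts)) {
        classes <- c(classes, "POTENTIAL_START_GAINED")
      }
    } else {
      region_label <- "CODING_REGION"
      cds_len <- (nchar(cds_sequence(tx, genome)) %/% 3L) * 3L
      if (length(indel_alts)) {
        for (alt in indel_alts) {
          classes <- c(classes, frame_class(ref_allele, alt))
        }
        ## a deletion taking out the annotated start or stop codon
        if (nzchar(ref_allele)) {
          cp <- genomic_to_tx(tx, seq(start, end)) - cds_tx_range(tx)[[1L]] + 1
          cp <- cp[!is.na(cp)]
          if (any(cp >= 1 & cp <= 3)) classes <- c(classes, "START_LOST")
          if (any(cp >= cds_len - 2 & cp <= cds_len)) {
            classes <- c(classes, "STOP_LOST")
          }
        }
      }
      if (length(subst_alts)) {
        eff <- coding_effect(tx, genome, start, end, ref_allele, subst_alts,
                             code)
        classes <- c(classes, eff$classes)
        codon <- eff$codon; aa <- eff$amino_acid; ref_aa <- eff$ref_amino_acid
      }
    }
  } else {  # spans exon/intron structure
    overlaps_coding <- is_coding_tx(tx) && start <= tx$coding_end &&
      end >= tx$coding_start
    region_label <- if (noncoding) "WITHIN_NON_CODING_TRANSCRIPT"
                    else if (overlaps_coding) "CODING_REGION" else "INTRONIC"
    if (length(indel_alts) && any(nchar(indel_alts) < nchar(ref_allele))) {
      classes <- c(classes, indel_coding_effect(tx, start, end))
    }
    if (noncoding) classes <- c(classes, "WITHIN_NON_CODING_TRANSCRIPT")
    if (length(classes) == 0L) {
      ## substitution across a junction: report the splice hit
      intr <- intron_bounds(tx)
      for (j in seq_len(nrow(intr))) {
        if (start <= intr$end[[j]] && end >= intr$start[[j]]) {
          classes <- c(classes, "ESSENTIAL_SPLICE_SITE")
          if (!noncoding) classes <- c(classes, "INTRONIC")
          break
        }
      }
    }
  }
  list(region_label = region_label, classes = unique(classes),
       codon = codon, amino_acid = aa, ref_amino_acid = ref_aa)
}

## Basic-table Region cell: pick the most gene-proximal label across
## transcripts.
REGION_PRIORITY <- c("CODING_REGION", "5PRIME_UTR", "3PRIME_UTR",
                     "WITHIN_NON_CODING_TRANSCRIPT", "INTRONIC")

combine_region_labels <- function(labels) {
  labels <- labels[!is.na(labels)]
  if (length(labels) == 0L) return(NA_character_)
  REGION_PRIORITY[min(match(labels, REGION_PRIORITY))]
}
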