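#' The 21-class functional classification scheme
#'
#' The classification scheme distinguishes 21 functional classes.  Positional
#' classes describe where a variant falls relative to gene structure
#' (intergenic, up/downstream, intronic, UTRs, non-coding transcripts);
#' consequence classes describe what the variant does to a transcript
#' (codon changes, frame changes, splice-site hits, complex deletions).
#'
#' @format A character vector of the 21 class names.
#' @export
FUNC_CLASSES <- c(
  "INTERGENIC",
  "UPSTREAM",
  "DOWNSTREAM",
  "WITHIN_NON_CODING_TRANSCRIPT",
  "INTRONIC",
  "5PRIME_UTR",
  "3PRIME_UTR",
  "SYNONYMOUS_CODING",
  "NON_SYNONYMOUS_CODING",
  "FRAMEKEEP",
  "FRAMESHIFT",
  "STOP_GAINED",
  "STOP_LOST",
  "POTENTIAL_START_GAINED",
  "START_LOST",
  "DELETE_EXONS",
  "MERGE_EXONS",
  "ACCEPTOR",
  "DONOR",
  "SPLICE_SITE",
  "ESSENTIAL_SPLICE_SITE"
)

## Applicability of each class per variant type (which classes a SNP, an MNP
## or an indel can, in principle, receive).  SYNONYMOUS/NON_SYNONYMOUS are
## substitution-only; FRAMEKEEP/FRAMESHIFT/DELETE_EXONS/MERGE_EXONS are
## indel-only; ACCEPTOR/DONOR require a span (MNP or indel).
.CLASS_APPLICABILITY <- local({
  m <- matrix(TRUE, nrow = length(FUNC_CLASSES), ncol = 3,
              dimnames = list(FUNC_CLASSES, c("SNP", "MNP", "INDEL")))
  m[c("FRAMEKEEP", "FRAMESHIFT", "DELETE_EXONS", "MERGE_EXONS"),
    c("SNP", "MNP")] <- FALSE
  m[c("ACCEPTOR", "DONOR"), "SNP"] <- FALSE
  m[c("SYNONYMOUS_CODING", "NON_SYNONYMOUS_CODING"), "INDEL"] <- FALSE
  m
})

#' Classes applicable to a variant type
#'
#' @param type One of `"SNP"`, `"MNP"`, `"INVERSION"`, `"INDEL"`.
#'   Inversions are length-preserving multi-base substitutions and share the
#'   MNP applicability column.
#' @return Character vector of applicable class names.
#' @examples
#' length(applicable_classes("SNP"))    # 15
#' length(applicable_classes("INDEL"))  # 19
#' @export
applicable_classes <- function(type) {
  type <- match.arg(toupper(type), c("SNP", "MNP", "INVERSION", "INDEL"))
  col <- if (type == "INVERSION") "MNP" else type
  FUNC_CLASSES[.CLASS_APPLICABILITY[, col]]
}

## Classes that only state where a variant lies.  A variant whose class set
## contains nothing beyond these gets FuncClass "NONE" in the basic table.
POSITIONAL_CLASSES <- c(
  "INTERGENIC", "UPSTREAM", "DOWNSTREAM", "WITHIN_NON_CODING_TRANSCRIPT",
  "INTRONIC", "5PRIME_UTR", "3PRIME_UTR"
)

#' Default severity ranking of the functional classes
#'
#' Used to pick the single most severe class for the basic output table.
#' The ordering follows conventional consequence-severity conventions:
#' protein-truncating first, then protein-altering, then splice and
#' regulatory, then positional classes.
#'
#' @format Character vector ordering all 21 classes from most to least severe.
#' @export
SEVERITY_RANKING <- c(
  "STOP_GAINED", "FRAMESHIFT", "START_LOST", "STOP_LOST",
  "DELETE_EXONS", "ACCEPTOR", "DONOR", "MERGE_EXONS",
  "NON_SYNONYMOUS_CODING", "FRAMEKEEP",
  "ESSENTIAL_SPLICE_SITE", "SPLICE_SITE",
  "POTENTIAL_START_GAINED", "SYNONYMOUS_CODING",
  "5PRIME_UTR", "3PRIME_UTR", "WITHIN_NON_CODING_TRANSCRIPT",
  "INTRONIC", "UPSTREAM", "DOWNSTREAM", "INTERGENIC"
)

#' Pick the single most severe class for the basic table
#'
#' Positional classes never make it into the basic FuncClass cell: a variant
#' carrying only positional classes reports `"NONE"` there (its location is
#' already in the Region column).
#'
#' @param classes Character vector of assigned class names (may be empty).
#' @param ranking Severity ordering; defaults to [SEVERITY_RANKING].
#' @return A single class name or `"NONE"`.
#' @export
most_severe_class <- function(classes, ranking = SEVERITY_RANKING) {
  classes <- setdiff(classes, POSITIONAL_CLASSES)
  if (length(classes) == 0L) return("NONE")
  hit <- ranking[ranking %in% classes]
  if (length(hit) == 0L) classes[[1L]] else hit[[1L]]
}

## Order a class set by severity (for display in detailed rows).
order_by_severity <- function(classes, ranking = SEVERITY_RANKING) {
  unique(c(ranking[ranking %in% classes], setdiff(classes, ranking)))
}

#' Annotation run configuration
#'
#' Bundles the tunable parameters of the classifier.
#'
#' @param distance_threshold Max gene distance (bp) for UPSTREAM/DOWNSTREAM;
#'   beyond it a variant is INTERGENIC.  Default 5000.
#' @param essential_intron_window Intronic bases at each intron end that are
#'   ESSENTIAL_SPLICE_SITE.  Default 2 (first/last two intronic bases); set
#'   to 3 for the wider reading.
#' @param splice_intron_window Outer bound of the intronic SPLICE_SITE
#'   window (bases `essential_intron_window + 1 .. splice_intron_window`
#'   from either intron end).  Default 8.
#' @param splice_exon_window Exonic bases at each exon end that are
#'   SPLICE_SITE.  Default 3.
#' @param genetic_code Genetic code preset name, see [load_genetic_code()].
#' @param inversion `"reverse"` (default) or `"revcomp"`: whether an
#'   inversion allele is the plain character reversal of the reference
#'   allele or its reverse complement.  Plain reversal is the default
#'   because that is what length-preserving allele pairs such as
#'   TTAG/GATT satisfy.
#' @param severity Severity ranking, see [SEVERITY_RANKING].
#' @param genesis Logical; compute indel genesis / transposon columns.
#' @param shift_window Scan window (bp) on each flank for the
#'   "shifting element" genesis flag.  Default 50.
#' @return A list with class `"annotation_config"`.
#' @export
annotation_config <- function(distance_threshold = 5000,
                              essential_intron_window = 2,
                              splice_intron_window = 8,
                              splice_exon_window = 3,
                              genetic_code = "standard",
                              inversion = c("reverse", "revcomp"),
                              severity = SEVERITY_RANKING,
                              genesis = FALSE,
                              shift_window = 50) {
  inversion <- match.arg(inversion)
  stopifnot(distance_threshold >= 0, essential_intron_window >= 1,
            splice_intron_window >= essential_intron_window,
            splice_exon_window >= 0, shift_window >= 1)
  structure(list(
    distance_threshold = distance_threshold,
    essential_intron_window = essential_intron_window,
    splice_intron_window = splice_intron_window,
    splice_exon_window = splice_exon_window,
    genetic_code = genetic_code,
    inversion = inversion,
    severity = severity,
    genesis = genesis,
    shift_window = shift_window
  ), class = "annotation_config")
}
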