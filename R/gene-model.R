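#' Construct a transcript model
#'
#' All coordinates are 1-based inclusive chromosomal positions.  Exons must
#' be non-overlapping; they are sorted by start.  A transcript without a
#' coding span is non-coding.
#'
#' @param transcript_id,gene_id,gene_name Identifiers.
#' @param chromosome Chromosome name.
#' @param strand `+1` or `-1`.
#' @param exons Data frame with columns `start`, `end`.
#' @param coding_start,coding_end Chromosomal coding span (CDS incl. stop
#'   codon), or `NA` for non-coding transcripts.  `coding_start <=
#'   coding_end` in chromosome coordinates regardless of strand.
#' @param biotype `"coding"`, `"noncoding"` or `"miRNA"`; defaults from the
#'   presence of a coding span.
#' @return A list of class `"transcript"`.
#' @export
transcript <- function(transcript_id, gene_id, gene_name = gene_id,
                       chromosome, strand, exons,
                       coding_start = NA, coding_end = NA,
                       biotype = NULL) {
  stopifnot(strand %in% c(1, -1), nrow(exons) >= 1L)
  exons <- data.frame(start = as.numeric(exons$start),
                      end = as.numeric(exons$end))
  exons <- exons[order(exons$start), , drop = FALSE]
  rownames(exons) <- NULL
  if (any(exons$start > exons$end)) stop("exon start > end")
  if (nrow(exons) > 1L &&
      any(exons$start[-1L] <= exons$end[-nrow(exons)])) {
    stop("overlapping exons in transcript ", transcript_id)
  }
  coding_start <- as.numeric(coding_start)
  coding_end <- as.numeric(coding_end)
  if (!is.na(coding_start) != !is.na(coding_end)) {
    stop("coding_start and coding_end must both be set or both NA")
  }
  if (!is.na(coding_start) && coding_start > coding_end) {
    stop("coding_start > coding_end")
  }
  if (is.null(biotype)) {
    biotype <- if (is.na(coding_start)) "noncoding" else "coding"
  }
  structure(list(
    transcript_id = as.character(transcript_id),
    gene_id = as.character(gene_id),
    gene_name = as.character(gene_name),
    chromosome = as.character(chromosome),
    start = min(exons$start), end = max(exons$end),
    strand = as.integer(strand),
    coding_start = coding_start, coding_end = coding_end,
    exons = exons, biotype = biotype
  ), class = "transcript")
}

is_coding_tx <- function(tx) !is.na(tx$coding_start)

#' Build a gene index from transcript models
#'
#' The index aggregates transcripts into genes (gene span = union of its
#' transcripts) and supports nearest-gene and overlap queries.
#'
#' @param transcripts List of [transcript()] objects.
#' @return An object of class `"gene_index"` with elements `genes`
#'   (data frame: gene_id, gene_name, chromosome, start, end, strand),
#'   `transcripts` (named list) and `tx_by_gene`.
#' @export
gene_index <- function(transcripts) {
  if (length(transcripts) == 0L) {
    return(structure(list(
      genes = data.frame(gene_id = character(), gene_name = character(),
                         chromosome = character(), start = numeric(),
                         end = numeric(), strand = integer(),
                         stringsAsFactors = FALSE),
      transcripts = list(), tx_by_gene = list()), class = "gene_index"))
  }
  names(transcripts) <- vapply(transcripts, `[[`, "", "transcript_id")
  gid <- vapply(transcripts, `[[`, "", "gene_id")
  genes <- do.call(rbind, lapply(split(transcripts, gid), function(txs) {
    data.frame(gene_id = txs[[1L]]$gene_id,
               gene_name = txs[[1L]]$gene_name,
               chromosome = txs[[1L]]$chromosome,
               start = min(vapply(txs, `[[`, 0, "start")),
               end = max(vapply(txs, `[[`, 0, "end")),
               strand = txs[[1L]]$strand,
               stringsAsFactors = FALSE)
  }))
  genes <- genes[order(genes$chromosome, genes$start, genes$gene_id), ,
                 drop = FALSE]
  rownames(genes) <- NULL
  structure(list(genes = genes, transcripts = transcripts,
                 tx_by_gene = split(names(transcripts), gid)),
            class = "gene_index")
}

#' @export
print.gene_index <- function(x, ...) {
  cat(sprintf("gene_index: %d gene(s), %d transcript(s) on %d chromosome(s)\n",
              nrow(x$genes), length(x$transcripts),
              length(unique(x$genes$chromosome))))
  invisible(x)
}

gff_attr <- function(gr, field) {
  if (field %in% names(S4Vectors::mcols(gr))) {
    S4Vectors::mcols(gr)[[field]]
  } else {
    rep(NA_character_, length(gr))
  }
}

first_or_na <- function(x) {
  if (length(x) >= 1L && !is.na(x[[1L]])) x[[1L]] else NA_character_
}

#' Load transcript models from a GFF3 file
#'
#' Expects gene / mRNA-or-transcript / exon / CDS features linked by
#' `Parent` attributes (GFF3 coordinates are already 1-based inclusive).
#' CDS features define the coding span of their transcript; transcripts
#' without CDS are non-coding.  Exons whose parent is unknown are dropped
#' with a warning; unsorted files are tolerated.
#'
#' @param path GFF3 file.
#' @return A [gene_index()].
#' @export
load_gff <- function(path) {
  if (!file.exists(path)) stop("GFF file not found: ", path)
  gr <- rtracklayer::import(path)
  type <- as.character(gff_attr(gr, "type"))
  ids <- as.character(gff_attr(gr, "ID"))
  parents <- lapply(S4Vectors::mcols(gr)$Parent, as.character)
  if (is.null(parents)) parents <- rep(list(character()), length(gr))
  names_attr <- as.character(gff_attr(gr, "Name"))
  chrom <- as.character(GenomicRanges::seqnames(gr))
  starts <- GenomicRanges::start(gr); ends <- GenomicRanges::end(gr)
  strands <- ifelse(as.character(GenomicRanges::strand(gr)) == "-", -1L, 1L)

  gene_rows <- which(type == "gene")
  gene_meta <- list()
  for (i in gene_rows) {
    gene_meta[[ids[[i]]]] <- list(
      gene_id = ids[[i]],
      gene_name = if (!is.na(names_attr[[i]])) names_attr[[i]] else ids[[i]])
  }

  tx_types <- c("mRNA", "transcript", "miRNA", "ncRNA", "lnc_RNA", "tRNA",
                "rRNA", "snoRNA", "snRNA", "pseudogenic_transcript")
  tx_rows <- which(type %in% tx_types)
  tx_meta <- list()
  for (i in tx_rows) {
    tid <- if (!is.na(ids[[i]])) ids[[i]] else paste0("tx", i)
    parent <- first_or_na(parents[[i]])
    gm <- if (!is.na(parent) && !is.null(gene_meta[[parent]])) {
      gene_meta[[parent]]
    } else {
      list(gene_id = if (!is.na(parent)) parent else tid,
           gene_name = if (!is.na(names_attr[[i]])) names_attr[[i]] else tid)
    }
    tx_meta[[tid]] <- list(
      transcript_id = tid, gene_id = gm$gene_id, gene_name = gm$gene_name,
      chromosome = chrom[[i]], strand = strands[[i]],
      miRNA = type[[i]] == "miRNA",
      exons = data.frame(start = numeric(), end = numeric()),
      cds = data.frame(start = numeric(), end = numeric()))
  }

  n_orphan <- 0L
  for (i in which(type %in% c("exon", "CDS"))) {
    for (parent in parents[[i]]) {
      if (is.null(tx_meta[[parent]])) { n_orphan <- n_orphan + 1L; next }
      slot <- if (type[[i]] == "exon") "exons" else "cds"
      tx_meta[[parent]][[slot]] <- rbind(
        tx_meta[[parent]][[slot]],
        data.frame(start = starts[[i]], end = ends[[i]]))
    }
  }
  if (n_orphan > 0L) {
    warning(n_orphan, " exon/CDS feature(s) without a known parent ",
            "transcript were dropped", call. = FALSE)
  }

  txs <- lapply(tx_meta, function(m) {
    exons <- m$exons
    if (nrow(exons) == 0L) {
      if (nrow(m$cds) == 0L) return(NULL)
      exons <- m$cds
    }
    has_cds <- nrow(m$cds) > 0L
    transcript(m$transcript_id, m$gene_id, m$gene_name, m$chromosome,
               m$strand, exons,
               coding_start = if (has_cds) min(m$cds$start) else NA,
               coding_end = if (has_cds) max(m$cds$end) else NA,
               biotype = if (m$miRNA) "miRNA"
                         else if (has_cds) "coding" else "noncoding")
  })
  gene_index(Filter(Negate(is.null), txs))
}

#' Load transcript models from a BED12 file
#'
#' Each line is one transcript; blocks are the exons.  BED's 0-based
#' half-open coordinates are converted to 1-based inclusive.
#' `thickStart == thickEnd` marks a non-coding transcript, otherwise the
#' thick range is the coding span.  The `name` column doubles as gene and
#' transcript identifier.
#'
#' @param path BED12 file.
#' @return A [gene_index()].
#' @export
load_bed <- function(path) {
  if (!file.exists(path)) stop("BED file not found: ", path)
  gr <- rtracklayer::import(path, format = "bed")
  bl <- rtracklayer::blocks(gr)  # absolute 1-based exon ranges
  thick <- S4Vectors::mcols(gr)$thick
  txs <- vector("list", length(gr))
  for (i in seq_along(gr)) {
    nm <- S4Vectors::mcols(gr)$name[[i]]
    if (is.null(nm) || is.na(nm)) nm <- paste0("bed_tx_", i)
    exr <- bl[[i]]
    coding <- !is.null(thick) && IRanges::width(thick)[[i]] > 0L
    txs[[i]] <- transcript(
      transcript_id = nm, gene_id = nm,
      chromosome = as.character(GenomicRanges::seqnames(gr))[[i]],
      strand = if (as.character(GenomicRanges::strand(gr))[[i]] == "-")
        -1L else 1L,
      exons = data.frame(start = IRanges::start(exr),
                         end = IRanges::end(exr)),
      coding_start = if (coding) IRanges::start(thick)[[i]] else NA,
      coding_end = if (coding) IRanges::end(thick)[[i]] else NA)
  }
  gene_index(txs)
}

#' Nearest gene and signed distance
#'
#' Distance 0 means the query interval overlaps the gene span.  Otherwise
#' the distance is the bp gap to the closest gene boundary, negative when
#' the gene lies before the variant in chromosome coordinates and positive
#' when it lies after.  The sign convention is chromosome-based and
#' strand-independent; strand-aware UPSTREAM/DOWNSTREAM labelling happens
#' in [region_class()].  Ties break deterministically (smaller gene start,
#' then lexicographic gene id).
#'
#' @param index A [gene_index()].
#' @param chromosome Chromosome name.
#' @param start,end Query interval (chromosomal, 1-based inclusive).
#' @return List with `gene_id`, `gene_name`, `strand`, `distance`
#'   (`Inf` and NA ids when the chromosome holds no gene).
#' @export
nearest_gene <- function(index, chromosome, start, end = start) {
  g <- index$genes[index$genes$chromosome == chromosome, , drop = FALSE]
  if (nrow(g) == 0L) {
    return(list(gene_id = NA_character_, gene_name = NA_character_,
                strand = NA_integer_, distance = Inf))
  }
  d <- numeric(nrow(g))
  before <- g$end < start   # gene entirely before the variant
  after <- g$start > end    # gene entirely after the variant
  d[before] <- -(start - g$end[before])
  d[after] <- g$start[after] - end
  ord <- order(abs(d), g$start, g$gene_id)
  best <- ord[[1L]]
  list(gene_id = g$gene_id[[best]], gene_name = g$gene_name[[best]],
       strand = g$strand[[best]], distance = d[[best]])
}

#' Genes overlapping an interval
#'
#' @inheritParams nearest_gene
#' @return Data frame of overlapping gene rows (possibly several, e.g.
#'   genes overlapping on opposite strands).
#' @export
genes_overlapping <- function(index, chromosome, start, end = start) {
  g <- index$genes
  g[g$chromosome == chromosome & g$start <= end & g$end >= start, ,
    drop = FALSE]
}

#' Transcripts overlapping an interval
#'
#' @inheritParams nearest_gene
#' @return List of [transcript()] objects whose span overlaps the interval.
#' @export
transcripts_overlapping <- function(index, chromosome, start, end = start) {
  Filter(function(tx) {
    tx$chromosome == chromosome && tx$start <= end && tx$end >= start
  }, index$transcripts)
}
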