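## Orchestration: per-variant classification and the full run.

BASIC_COLS <- c("Name", "Chr", "Start", "End", "ChromStart", "ChromEnd",
                "Region", "Type", "FuncClass", "NearestGene", "Distance",
                "Status", "ID", "Insertion")

DETAILED_COLS <- c("Name", "Chr", "Start", "End", "AltAllele1", "AltAllele2",
                   "AltAllele3", "RefAllele", "Codon", "AminoAcid",
                   "RefAminoAcid", "FuncClass", "Transcript", "Strand", "ID",
                   "ConsScore", "ProteinDomain")

GENESIS_COLS <- c("IsDuplication", "IsInversionOfFlank", "IsShift",
                  "PeriodLength", "TransposonFlag")

na_or <- function(x, default = NA) if (is.null(x) || length(x) == 0L)
  default else x

#' Classify one variant
#'
#' Runs the per-variant pipeline: relative-to-chromosomal coordinate
#' mapping, reference verification, allele typing, nearest-gene search,
#' known/novel status, positional classification and, for variants inside
#' a gene, per-transcript functional annotation (optionally followed by
#' indel genesis characterization).
#'
#' @param record A [variant_record()].
#' @param index A [gene_index()].
#' @param genome A [reference_genome()].
#' @param known Optional [load_known()] store.
#' @param code A [load_genetic_code()] result.
#' @param config An [annotation_config()].
#' @param ref_offset Chromosomal start of the relative coordinate system.
#' @param scores Optional data frame (`chromosome`, `pos`, `cons_score`,
#'   `protein_domain`) supplying the conservation-score / protein-domain
#'   columns; positions without an entry stay NA.
#' @return List with `basic` (named list of basic-row fields), `details`
#'   (list of per-transcript rows), `classes` (character vector of all
#'   assigned classes) and optionally `genesis`.
#' @export
classify_variant <- function(record, index, genome, known = NULL,
                             code = load_genetic_code(),
                             config = annotation_config(),
                             ref_offset = 1, scores = NULL) {
  cs <- chrom_pos(record$rel_start, ref_offset)
  ce <- chrom_pos(record$rel_end, ref_offset)
  is_insertion_rec <- !is.na(record$ref_allele) && !nzchar(record$ref_allele)

  base_basic <- list(
    Name = record$name, Chr = record$chromosome,
    Start = record$rel_start, End = record$rel_end,
    ChromStart = cs, ChromEnd = ce,
    Region = NA_character_, Type = NA_character_,
    FuncClass = NA_character_, NearestGene = NA_character_,
    Distance = NA_real_, Status = NA_character_, ID = NA_character_,
    Insertion = is_insertion_rec)

  ## reference check (pgSnp records resolve their reference here)
  if (is.na(record$ref_allele)) {
    record$ref_allele <- fetch_slice(genome, record$chromosome, cs, ce)
    record$alt_alleles <- setdiff(record$alt_alleles, record$ref_allele)
    if (length(record$alt_alleles) == 0L) {
      stop("all alleles equal the reference at ", record$chromosome, ":", cs)
    }
  }
  ver <- tryCatch(
    verify_ref(genome, record$chromosome, cs, ce, record$ref_allele),
    error = function(e) list(matched = FALSE, genome_ref = NA_character_))
  if (!ver$matched) {
    base_basic$Status <- "REF_MISMATCH"
    return(list(basic = base_basic, details = list(),
                classes = character(), ref_mismatch = TRUE))
  }

  type <- variant_type(record, config$inversion)
  ng <- nearest_gene(index, record$chromosome, cs, ce)
  region0 <- region_class(ng$distance, ng$strand, config$distance_threshold)
  st <- status_of(known, genome, record$chromosome, cs, ce,
                  record$ref_allele, record$alt_alleles)

  details <- list()
  all_classes <- character()
  detail_template <- list(
    Name = record$name, Chr = record$chromosome,
    Start = record$rel_start, End = record$rel_end,
    AltAllele1 = na_or(record$alt_alleles[1], NA_character_),
    AltAllele2 = na_or(record$alt_alleles[2], NA_character_),
    AltAllele3 = na_or(record$alt_alleles[3], NA_character_),
    RefAllele = if (nzchar(record$ref_allele)) record$ref_allele else "-",
    Codon = NA_character_, AminoAcid = NA_character_,
    RefAminoAcid = NA_character_, FuncClass = NA_character_,
    Transcript = NA_character_, Strand = NA_integer_,
    ID = paste(st$ids, collapse = ", "),
    ConsScore = NA_real_, ProteinDomain = NA_character_)
  if (!is.null(scores)) {
    hit <- which(scores$chromosome == record$chromosome & scores$pos == cs)
    if (length(hit) >= 1L) {
      detail_template$ConsScore <- scores$cons_score[[hit[[1L]]]]
      detail_template$ProteinDomain <- scores$protein_domain[[hit[[1L]]]]
    }
  }

  region_label <- region0
  if (region0 == "GENIC") {
    txs <- transcripts_overlapping(index, record$chromosome, cs, ce)
    labels <- character()
    for (tx in txs) {
      ann <- tryCatch(
        annotate_transcript(tx, genome, code, config, cs, ce,
                            record$ref_allele, record$alt_alleles),
        error = function(e) {
          warning("transcript ", tx$transcript_id, " skipped for ",
                  record$name, ": ", conditionMessage(e), call. = FALSE)
          NULL
        })
      if (is.null(ann)) next
      all_classes <- union(all_classes, ann$classes)
      labels <- c(labels, ann$region_label)
      row <- detail_template
      row$Codon <- ann$codon; row$AminoAcid <- ann$amino_acid
      row$RefAminoAcid <- ann$ref_amino_acid
      row$FuncClass <- paste(order_by_severity(ann$classes, config$severity),
                             collapse = ",")
      row$Transcript <- tx$transcript_id
      row$Strand <- tx$strand
      details[[length(details) + 1L]] <- row
    }
    region_label <- combine_region_labels(labels)
    if (is.na(region_label)) {  # inside the gene span, between transcripts
      region_label <- "INTRONIC"
      all_classes <- union(all_classes, "INTRONIC")
    }
  } else {
    all_classes <- region0
    row <- detail_template
    row$FuncClass <- region0
    row$Transcript <- na_or(ng$gene_name, NA_character_)
    row$Strand <- na_or(ng$strand, NA_integer_)
    details[[1L]] <- row
  }

  out <- list()
  if (type == "INDEL" && isTRUE(config$genesis)) {
    alt <- record$alt_alleles[nchar(record$alt_alleles) !=
                                nchar(record$ref_allele)][1L]
    gen <- tryCatch({
      ci <- canonicalize(genome, record$chromosome, cs, record$ref_allele,
                         alt)
      genesis(genome, ci$chromosome, ci$canonical_pos, ci$op, ci$sequence,
              shift_window = config$shift_window,
              inversion = config$inversion)
    }, error = function(e) NULL)
    out$genesis <- gen
  }

  basic <- base_basic
  basic$Region <- region_label
  basic$Type <- type
  basic$FuncClass <- most_severe_class(all_classes, config$severity)
  basic$NearestGene <- na_or(ng$gene_name, NA_character_)
  basic$Distance <- if (is.infinite(ng$distance)) NA_real_ else ng$distance
  basic$Status <- st$status
  basic$ID <- if (length(st$ids)) paste(st$ids, collapse = ", ") else
    NA_character_
  c(list(basic = basic, details = details, classes = all_classes,
         ref_mismatch = FALSE), out)
}

rows_to_frame <- function(rows, cols) {
  if (length(rows) == 0L) {
    out <- lapply(cols, function(x) logical(0))
    names(out) <- cols
    return(as.data.frame(out, stringsAsFactors = FALSE))
  }
  out <- lapply(cols, function(col) {
    vals <- lapply(rows, function(r) na_or(r[[col]], NA))
    unlist(vals, use.names = FALSE)
  })
  names(out) <- cols
  as.data.frame(out, stringsAsFactors = FALSE)
}

#' Annotate a list of variant records
#'
#' Applies [classify_variant()] to every record.  Per-record problems are
#' logged as warnings and yield an NA row with the variant's name, so the
#' basic table always has exactly one row per input record (plus one NA
#' row per unparseable input line, taken from the `"skipped"` attribute of
#' the parsers).
#'
#' @inheritParams classify_variant
#' @param records List of [variant_record()]s (possibly carrying a
#'   `"skipped"` attribute from a parser).
#' @return List with `basic` and `detailed` data frames, `report` list,
#'   and `class_sets` (per-variant class vectors, for downstream
#'   summaries).
#' @export
annotate_variants <- function(records, index, genome, known = NULL,
                              code = load_genetic_code(),
                              config = annotation_config(),
                              ref_offset = 1, scores = NULL) {
  skipped <- attr(records, "skipped")
  n_skipped <- if (is.null(skipped)) 0L else nrow(skipped)
  basic_rows <- list(); detail_rows <- list(); class_sets <- list()
  genesis_rows <- list()
  n_mismatch <- 0L
  for (rec in records) {
    res <- tryCatch(
      classify_variant(rec, index, genome, known, code, config, ref_offset,
                       scores),
      error = function(e) {
        warning("variant ", rec$name, " skipped: ", conditionMessage(e),
                call. = FALSE)
        NULL
      })
    if (is.null(res)) {
      basic_rows[[length(basic_rows) + 1L]] <- list(
        Name = rec$name, Chr = rec$chromosome,
        Start = rec$rel_start, End = rec$rel_end)
      class_sets[[length(class_sets) + 1L]] <- character()
      next
    }
    if (res$ref_mismatch) n_mismatch <- n_mismatch + 1L
    basic_rows[[length(basic_rows) + 1L]] <- res$basic
    class_sets[[length(class_sets) + 1L]] <- res$classes
    for (d in res$details) {
      if (isTRUE(config$genesis)) {
        g <- res$genesis
        d$IsDuplication <- na_or(g$is_duplication)
        d$IsInversionOfFlank <- na_or(g$is_inversion_of_flank)
        d$IsShift <- na_or(g$is_shift)
        d$PeriodLength <- na_or(g$period_length)
        d$TransposonFlag <- na_or(g$transposon_flag)
      }
      detail_rows[[length(detail_rows) + 1L]] <- d
    }
  }
  if (n_skipped > 0L) {
    for (i in seq_len(n_skipped)) {
      basic_rows[[length(basic_rows) + 1L]] <- list(
        Name = skipped$name[[i]])
      class_sets[[length(class_sets) + 1L]] <- character()
    }
  }
  basic <- rows_to_frame(basic_rows, BASIC_COLS)
  det_cols <- c(DETAILED_COLS, if (isTRUE(config$genesis)) GENESIS_COLS)
  detailed <- rows_to_frame(detail_rows, det_cols)

  all_classes <- unlist(class_sets)
  report <- list(
    n_input = length(records) + n_skipped,
    n_processed = length(records),
    n_ref_mismatch = n_mismatch,
    n_skipped = n_skipped,
    class_counts = if (length(all_classes)) table(all_classes) else
      integer(),
    type_counts = table(basic$Type[!is.na(basic$Type)]),
    status_counts = table(basic$Status[!is.na(basic$Status)]),
    config_echo = list(
      distance_threshold = config$distance_threshold,
      genetic_code = code$name,
      inversion = config$inversion,
      ref_offset = ref_offset,
      genesis = config$genesis))
  list(basic = basic, detailed = detailed, report = report,
       class_sets = class_sets)
}

#' Run the full annotation pipeline
#'
#' One call from input files (or in-memory objects) to output tables.
#' Reruns with identical inputs and configuration are byte-identical:
#' the pipeline has no hidden randomness.
#'
#' @param variants Path to a variant list, or a list of
#'   [variant_record()]s.
#' @param variant_format `"table"` (six-column), `"vcf"` or `"pgsnp"`.
#' @param annotation Path to a GFF3 or BED12 file, or a [gene_index()].
#' @param annotation_format `"gff"` or `"bed"` (ignored for an index).
#' @param genome Path to a FASTA file, or a [reference_genome()].
#' @param known Optional path to a known-variants VCF, or a
#'   [load_known()] store.
#' @param ref_offset Chromosomal start position of the reference sequence
#'   the variant coordinates are relative to (default 1).
#' @param genetic_code Preset name, see [load_genetic_code()].
#' @param config An [annotation_config()]; `genesis = TRUE` appends indel
#'   genesis columns to the detailed table.
#' @param scores Optional per-position annotation table (data frame or TSV
#'   path with columns `chromosome`, `pos`, `cons_score`,
#'   `protein_domain`).
#' @param out_prefix If non-NULL, writes `<prefix>_basic.txt`,
#'   `<prefix>_detailed.txt` and `<prefix>_report.txt` (plus `.html` /
#'   `.gff` when requested).
#' @param html,gff Logical: also write HTML tables / a GFF3 export.
#' @param url_template URL template for HTML identifier links.
#' @return An object of class `"annotation_run"`: `basic`, `detailed`,
#'   `report`, `class_sets`, `config`, `paths`.
#' @export
run_annotation <- function(variants, variant_format = c("table", "vcf",
                                                        "pgsnp"),
                           annotation = NULL,
                           annotation_format = c("gff", "bed"),
                           genome, known = NULL, ref_offset = 1,
                           genetic_code = NULL,
                           config = annotation_config(),
                           scores = NULL, out_prefix = NULL,
                           html = FALSE, gff = FALSE,
                           url_template = NULL) {
  variant_format <- match.arg(variant_format)
  annotation_format <- match.arg(annotation_format)
  if (!is.null(genetic_code)) config$genetic_code <- genetic_code
  code <- load_genetic_code(config$genetic_code)

  if (is.character(genome)) genome <- read_genome_fasta(genome)
  stopifnot(inherits(genome, "reference_genome"))
  index <- if (is.null(annotation)) {
    gene_index(list())
  } else if (inherits(annotation, "gene_index")) {
    annotation
  } else if (annotation_format == "gff") {
    load_gff(annotation)
  } else {
    load_bed(annotation)
  }
  records <- if (is.character(variants)) {
    switch(variant_format,
           table = parse_variant_table(variants),
           vcf = parse_vcf(variants),
           pgsnp = parse_pgsnp(variants))
  } else {
    variants
  }
  db <- if (is.null(known)) NULL
        else if (inherits(known, "known_variant_db")) known
        else load_known(known, genome)
  if (is.character(scores)) {
    scores <- utils::read.delim(scores, stringsAsFactors = FALSE)
  }

  res <- annotate_variants(records, index, genome, db, code, config,
                           ref_offset, scores)
  run <- structure(c(res, list(config = config, paths = character())),
                   class = "annotation_run")

  if (!is.null(out_prefix)) {
    paths <- c(basic = paste0(out_prefix, "_basic.txt"),
               detailed = paste0(out_prefix, "_detailed.txt"),
               report = paste0(out_prefix, "_report.txt"))
    write_basic(run$basic, paths[["basic"]])
    write_detailed(run$detailed, paths[["detailed"]])
    write_report(run$report, paths[["report"]])
    if (html) {
      paths[["basic_html"]] <- paste0(out_prefix, "_basic.html")
      paths[["detailed_html"]] <- paste0(out_prefix, "_detailed.html")
      write_basic(run$basic, paths[["basic_html"]], "html", url_template)
      write_detailed(run$detailed, paths[["detailed_html"]], "html",
                     url_template)
    }
    if (gff) {
      paths[["gff"]] <- paste0(out_prefix, ".gff3")
      export_gff(run, paths[["gff"]])
    }
    run$paths <- paths
  }
  run
}

#' @export
print.annotation_run <- function(x, ...) {
  cat(sprintf("annotation_run: %d variant(s), %d detailed row(s)\n",
              nrow(x$basic), nrow(x$detailed)))
  cat(sprintf("  ref mismatches: %d, skipped: %d\n",
              x$report$n_ref_mismatch, x$report$n_skipped))
  invisible(x)
}
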