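## Deterministic synthetic fixtures: genome, annotation, variant list,
## known-variants VCF and truth labels, covering every one of the 21
## functional classes without any external download.

#' Specification for the default synthetic fixture
#'
#' The default layout is a 20 kb chromosome carrying three genes — a
#' plus-strand 3-exon coding gene, a minus-strand mirror (with two
#' identical transcripts, so multi-transcript output rows are exercised)
#' and a 2-exon non-coding gene — plus a poly-A tract (24 bp) and a
#' trinucleotide tract (GAT x 9) for indel-ambiguity tests.  Filler
#' sequence is seeded random; every planted feature is written
#' explicitly, so the truth labels hold for any seed.
#'
#' @param seed Integer seed driving the filler sequence.
#' @param chromosome Chromosome name.
#' @param length Chromosome length in bp (>= 20000).
#' @return A list of class `"fixture_spec"`.
#' @export
fixture_spec <- function(seed = 101, chromosome = "1", length = 20000) {
  stopifnot(length >= 20000)
  structure(list(seed = seed, chromosome = chromosome, length = length),
            class = "fixture_spec")
}

random_bases <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

## Write a string into a character vector of single bases at 1-based pos.
plant_seq <- function(bases, pos, s) {
  ch <- strsplit(s, NULL)[[1L]]
  bases[pos:(pos + length(ch) - 1L)] <- ch
  bases
}

## Write GFF3 for a list of transcript objects (computes per-exon CDS
## segments and phases).
write_gff_annotation <- function(transcripts, path) {
  lines <- "##gff-version 3"
  genes <- list()
  for (tx in transcripts) {
    g <- genes[[tx$gene_id]]
    if (is.null(g)) {
      g <- list(gene_id = tx$gene_id, gene_name = tx$gene_name,
                chromosome = tx$chromosome, start = tx$start, end = tx$end,
                strand = tx$strand)
    } else {
      g$start <- min(g$start, tx$start); g$end <- max(g$end, tx$end)
    }
    genes[[tx$gene_id]] <- g
  }
  strand_chr <- function(s) if (s == -1L) "-" else "+"
  for (g in genes) {
    lines <- c(lines, paste(
      g$chromosome, "fixture", "gene", g$start, g$end, ".",
      strand_chr(g$strand), ".",
      sprintf("ID=%s;Name=%s", g$gene_id, g$gene_name), sep = "\t"))
  }
  for (tx in transcripts) {
    type <- if (is_coding_tx(tx)) "mRNA" else "transcript"
    lines <- c(lines, paste(
      tx$chromosome, "fixture", type, tx$start, tx$end, ".",
      strand_chr(tx$strand), ".",
      sprintf("ID=%s;Parent=%s", tx$transcript_id, tx$gene_id), sep = "\t"))
    for (i in seq_len(nrow(tx$exons))) {
      lines <- c(lines, paste(
        tx$chromosome, "fixture", "exon", tx$exons$start[[i]],
        tx$exons$end[[i]], ".", strand_chr(tx$strand), ".",
        sprintf("Parent=%s", tx$transcript_id), sep = "\t"))
    }
    if (is_coding_tx(tx)) {
      seg <- tx$exons
      seg$start <- pmax(seg$start, tx$coding_start)
      seg$end <- pmin(seg$end, tx$coding_end)
      seg <- seg[seg$start <= seg$end, , drop = FALSE]
      seg <- seg[if (tx$strand == 1L) order(seg$start) else
        rev(order(seg$start)), , drop = FALSE]
      done <- 0
      for (i in seq_len(nrow(seg))) {
        phase <- (3 - (done %% 3)) %% 3
        lines <- c(lines, paste(
          tx$chromosome, "fixture", "CDS", seg$start[[i]], seg$end[[i]],
          ".", strand_chr(tx$strand), phase,
          sprintf("Parent=%s", tx$transcript_id), sep = "\t"))
        done <- done + seg$end[[i]] - seg$start[[i]] + 1
      }
    }
  }
  writeLines(lines, path)
  invisible(path)
}

write_minimal_vcf <- function(df, path) {
  writeLines(c(
    "##fileformat=VCFv4.2",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO"),
          collapse = "\t"),
    vapply(seq_len(nrow(df)), function(i) {
      paste(df$chrom[[i]], format(df$pos[[i]], scientific = FALSE),
            df$id[[i]], df$ref[[i]], df$alt[[i]], ".", ".", ".",
            sep = "\t")
    }, "")), path)
  invisible(path)
}

#' Generate the synthetic truth fixture
#'
#' Writes FASTA, GFF3, six-column variant table, known-variants VCF and a
#' truth TSV (`name`, `type`, `region`, `class`, `status`, `codon`, `aa`,
#' `ref_aa`) into `dir`.  The same spec always produces byte-identical
#' files.  Every one of the 21 functional classes is planted at least
#' once; two of the planted coding SNPs sit on the minus-strand gene in
#' contexts whose expected codon strings (`GCS`, `MAA`) exercise the
#' IUPAC codon notation on the reverse strand.
#'
#' @param dir Output directory (created if needed).
#' @param spec A [fixture_spec()].
#' @return List with the file paths (`fasta`, `gff`, `variants`, `known`,
#'   `truth`), the `spec`, and the planted `transcripts`.
#' @export
make_fixture <- function(dir = tempfile("snpclassify_fixture"),
                         spec = fixture_spec()) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  chrom <- spec$chromosome
  set.seed(spec$seed)
  bases <- strsplit(random_bases(spec$length), NULL)[[1L]]

  ## --- gene A: plus strand, 3 exons, CDS 3041..3460 ----------------------
  codonsA <- rep("GCT", 80)
  codonsA[1] <- "ATG"; codonsA[40] <- "TAT"; codonsA[80] <- "TAA"
  cdsA <- paste(codonsA, collapse = "")
  bases <- plant_seq(bases, 3041, substr(cdsA, 1, 60))
  bases <- plant_seq(bases, 3201, substr(cdsA, 61, 180))
  bases <- plant_seq(bases, 3401, substr(cdsA, 181, 240))
  txA <- transcript("GA1.t1", "GA1", "GENEA", chrom, 1L,
                    data.frame(start = c(3001, 3201, 3401),
                               end = c(3100, 3320, 3500)),
                    coding_start = 3041, coding_end = 3460)

  ## --- gene B: minus strand mirror, two identical transcripts ------------
  ## CDS in transcript orientation; codon 10 = GCC (variable 3rd base ->
  ## codon GCS), codon 30 = AAA (variable 1st base -> codon MAA)
  codonsB <- rep("GCT", 80)
  codonsB[1] <- "ATG"; codonsB[10] <- "GCC"; codonsB[30] <- "AAA"
  codonsB[80] <- "TAA"
  plusB <- revcomp(paste(codonsB, collapse = ""))
  bases <- plant_seq(bases, 8041, substr(plusB, 1, 60))
  bases <- plant_seq(bases, 8201, substr(plusB, 61, 180))
  bases <- plant_seq(bases, 8401, substr(plusB, 181, 240))
  exB <- data.frame(start = c(8001, 8201, 8401), end = c(8100, 8320, 8500))
  txB1 <- transcript("GB1.t1", "GB1", "GENEB", chrom, -1L, exB,
                     coding_start = 8041, coding_end = 8460)
  txB2 <- transcript("GB1.t2", "GB1", "GENEB", chrom, -1L, exB,
                     coding_start = 8041, coding_end = 8460)

  ## --- gene C: non-coding, plus strand -----------------------------------
  txC <- transcript("GC1.t1", "GC1", "GENEC", chrom, 1L,
                    data.frame(start = c(12001, 12251),
                               end = c(12150, 12400)))

  ## --- planted point contexts --------------------------------------------
  bases <- plant_seq(bases, 2501, "T")      # upstream of gene A
  bases <- plant_seq(bases, 3700, "G")      # downstream of gene A
  bases <- plant_seq(bases, 8700, "C")      # upstream of gene B (minus)
  bases <- plant_seq(bases, 17500, "A")     # intergenic
  bases <- plant_seq(bases, 3015, "A")      # 5' UTR
  bases <- plant_seq(bases, 3022, "CCACGCC")  # 5'-UTR ATG-creation context
  bases <- plant_seq(bases, 3102, "T")      # intron 1 offset 2
  bases <- plant_seq(bases, 3105, "C")      # intron 1 offset 5
  bases <- plant_seq(bases, 3150, "G")      # mid-intron
  bases <- plant_seq(bases, 3160, "AC")     # MNP context
  bases <- plant_seq(bases, 3165, "TTAG")   # inversion context
  bases <- plant_seq(bases, 3480, "G")      # 3' UTR
  bases <- plant_seq(bases, 3499, "C")      # last-3-exonic splice window
  bases <- plant_seq(bases, 12050, "G")     # non-coding exon
  bases <- plant_seq(bases, 12098, "CCACGCC")  # non-coding ATG creation
  ## repeat tracts (intergenic, > 5 kb from the nearest gene)
  bases <- plant_seq(bases, 17800, paste0("C", strrep("A", 24), "G"))
  bases <- plant_seq(bases, 17900, paste0("C", strrep("GAT", 9), "C"))

  seq <- paste(bases, collapse = "")
  genome <- reference_genome(stats::setNames(seq, chrom))
  slice <- function(s, e) substr(seq, s, e)

  ## --- variant list with truth labels ------------------------------------
  v <- function(name, s, e, alt, ref, type, region, class, status,
                codon = NA, aa = NA, ref_aa = NA) {
    data.frame(name = name, start = s, end = e, alt = alt, ref = ref,
               type = type, region = region, class = class,
               status = status, codon = codon, aa = aa, ref_aa = ref_aa,
               stringsAsFactors = FALSE)
  }
  vars <- rbind(
    v("v_intergenic", 17500, 17500, "G", "A", "SNP", "INTERGENIC",
      "INTERGENIC", "NOVEL"),
    v("v_upstream_plus", 2501, 2501, "C", "T", "SNP", "UPSTREAM",
      "UPSTREAM", "NOVEL"),
    v("v_downstream_plus", 3700, 3700, "A", "G", "SNP", "DOWNSTREAM",
      "DOWNSTREAM", "NOVEL"),
    v("v_upstream_minus", 8700, 8700, "T", "C", "SNP", "UPSTREAM",
      "UPSTREAM", "NOVEL"),
    v("v_intronic", 3150, 3150, "A", "G", "SNP", "INTRONIC", "INTRONIC",
      "NOVEL"),
    v("v_5utr", 3015, 3015, "G", "A", "SNP", "5PRIME_UTR", "5PRIME_UTR",
      "NOVEL"),
    v("v_3utr", 3480, 3480, "A", "G", "SNP", "3PRIME_UTR", "3PRIME_UTR",
      "NOVEL"),
    v("v_wnct", 12050, 12050, "C", "G", "SNP",
      "WITHIN_NON_CODING_TRANSCRIPT", "WITHIN_NON_CODING_TRANSCRIPT",
      "NOVEL"),
    v("v_syn", 3070, 3070, "C", "T", "SNP", "CODING_REGION",
      "SYNONYMOUS_CODING", "KNOWN", "GCY", "Ala", "Ala"),
    v("v_nonsyn", 3228, 3228, "A", "G", "SNP", "CODING_REGION",
      "NON_SYNONYMOUS_CODING", "ALTERNATIVE", "RCT", "Thr", "Ala"),
    v("v_stopgain", 3260, 3260, "A", "T", "SNP", "CODING_REGION",
      "STOP_GAINED", "NOVEL"),
    v("v_stoplost", 3460, 3460, "C", "A", "SNP", "CODING_REGION",
      "STOP_LOST", "NOVEL"),
    v("v_startlost", 3042, 3042, "C", "T", "SNP", "CODING_REGION",
      "START_LOST", "NOVEL"),
    v("v_startgain", 3025, 3025, "T", "C", "SNP", "5PRIME_UTR",
      "POTENTIAL_START_GAINED", "NOVEL"),
    v("v_startgain_nc", 12101, 12101, "T", "C", "SNP",
      "WITHIN_NON_CODING_TRANSCRIPT", "POTENTIAL_START_GAINED", "NOVEL"),
    v("v_ess_splice", 3102, 3102, "A", "T", "SNP", "INTRONIC",
      "ESSENTIAL_SPLICE_SITE", "NOVEL"),
    v("v_splice_intron", 3105, 3105, "A", "C", "SNP", "INTRONIC",
      "SPLICE_SITE", "NOVEL"),
    v("v_splice_exon", 3499, 3499, "T", "C", "SNP", "3PRIME_UTR",
      "SPLICE_SITE", "NOVEL"),
    v("v_syn_minus", 8431, 8431, "C", "G", "SNP", "CODING_REGION",
      "SYNONYMOUS_CODING", "NOVEL", "GCS", "Ala", "Ala"),
    v("v_nonsyn_minus", 8293, 8293, "G", "T", "SNP", "CODING_REGION",
      "NON_SYNONYMOUS_CODING", "NOVEL", "MAA", "Gln", "Lys"),
    v("v_mnp", 3160, 3161, "GT", "AC", "MNP", "INTRONIC", "INTRONIC",
      "NOVEL"),
    v("v_inversion", 3165, 3168, "GATT", "TTAG", "INVERSION", "INTRONIC",
      "INTRONIC", "NOVEL"),
    v("v_frameshift", 3270, 3271, "-", slice(3270, 3271), "INDEL",
      "CODING_REGION", "FRAMESHIFT", "NOVEL"),
    v("v_framekeep", 3280, 3282, "-", slice(3280, 3282), "INDEL",
      "CODING_REGION", "FRAMEKEEP", "NOVEL"),
    v("v_del_exon", 3190, 3330, "-", slice(3190, 3330), "INDEL",
      "CODING_REGION", "DELETE_EXONS", "NOVEL"),
    v("v_merge_exons", 3321, 3400, "-", slice(3321, 3400), "INDEL",
      "INTRONIC", "MERGE_EXONS", "NOVEL"),
    v("v_acceptor", 3195, 3205, "-", slice(3195, 3205), "INDEL",
      "CODING_REGION", "ACCEPTOR", "NOVEL"),
    v("v_donor", 3315, 3325, "-", slice(3315, 3325), "INDEL",
      "CODING_REGION", "DONOR", "NOVEL"),
    v("v_polyA_del", 17810, 17810, "-", "A", "INDEL", "INTERGENIC",
      "INTERGENIC", "KNOWN"),
    v("v_ins_dup", 17812, 17812, "A", "-", "INDEL", "INTERGENIC",
      "INTERGENIC", "NOVEL")
  )

  ## --- files --------------------------------------------------------------
  paths <- list(
    fasta = file.path(dir, "genome.fa"),
    gff = file.path(dir, "annotation.gff3"),
    variants = file.path(dir, "variants.txt"),
    known = file.path(dir, "known.vcf"),
    truth = file.path(dir, "truth.tsv"))
  Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(stats::setNames(seq, chrom)), paths$fasta)
  transcripts <- list(txA, txB1, txB2, txC)
  write_gff_annotation(transcripts, paths$gff)
  writeLines(c(
    paste(c("Name", "Chromosome", "RelStart", "RelEnd", "AltAlleles",
            "RefAllele"), collapse = "\t"),
    vapply(seq_len(nrow(vars)), function(i) {
      paste(vars$name[[i]], chrom,
            format(vars$start[[i]], scientific = FALSE),
            format(vars$end[[i]], scientific = FALSE),
            vars$alt[[i]], vars$ref[[i]], sep = "\t")
    }, "")), paths$variants)
  write_minimal_vcf(data.frame(
    chrom = chrom, pos = c(3070, 3228, 17804, 17819),
    id = c("rsK1", "rsK2", "rsK3", "rsK4"),
    ref = c("T", "G", slice(17804, 17805), slice(17819, 17820)),
    alt = c("C", "C", slice(17804, 17804), slice(17819, 17819)),
    stringsAsFactors = FALSE), paths$known)
  truth <- vars[, c("name", "type", "region", "class", "status", "codon",
                    "aa", "ref_aa")]
  utils::write.table(truth, paths$truth, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")

  c(paths, list(dir = dir, spec = spec, genome = genome,
                transcripts = transcripts))
}

#' Synthetic single-gene chromosome for threshold scans
#'
#' Builds, in memory, a random chromosome carrying exactly one coding
#' gene, suitable for exhaustive positional scans (e.g. locating the
#' UPSTREAM/DOWNSTREAM to INTERGENIC flip).
#'
#' @param seed Integer seed for the filler sequence.
#' @param chrom_length Chromosome length in bp.
#' @param gene_start,gene_end Gene span (single exon).
#' @param strand `+1` or `-1`.
#' @return List with `genome` ([reference_genome()]), `index`
#'   ([gene_index()]) and the gene bounds.
#' @export
make_single_gene_genome <- function(seed = 1, chrom_length = 20000,
                                    gene_start = 9001, gene_end = 11000,
                                    strand = 1L) {
  stopifnot(gene_start > 1, gene_end < chrom_length)
  set.seed(seed)
  seq <- random_bases(chrom_length)
  cds_len <- ((gene_end - gene_start + 1) %/% 3) * 3
  tx <- transcript("SG1.t1", "SG1", "SINGLEGENE", "1", strand,
                   data.frame(start = gene_start, end = gene_end),
                   coding_start = gene_start,
                   coding_end = gene_start + cds_len - 1)
  list(genome = reference_genome(c("1" = seq)),
       index = gene_index(list(tx)),
       gene_start = gene_start, gene_end = gene_end)
}
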