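test_that("distance-based region classification is strand-aware", {
  expect_equal(region_class(5001, 1L), "INTERGENIC")
  expect_equal(region_class(-5001, -1L), "INTERGENIC")
  expect_equal(region_class(0, 1L), "GENIC")
  ## variant before a plus-strand gene sits on its promoter side
  expect_equal(region_class(500, 1L), "UPSTREAM")
  expect_equal(region_class(-500, 1L), "DOWNSTREAM")
  ## minus-strand gene: the 5' side is the higher-coordinate side
  expect_equal(region_class(-500, -1L), "UPSTREAM")
  expect_equal(region_class(500, -1L), "DOWNSTREAM")
  expect_equal(region_class(5000, 1L), "UPSTREAM")  # boundary inclusive
  expect_equal(region_class(Inf, NA), "INTERGENIC")
})

test_that("splice windows follow the intron 2/3-8 and exon 1-3 arithmetic", {
  cfg <- annotation_config()
  sc <- function(p, rs, re, region) splice_class(p, p, rs, re, region, cfg)
  expect_equal(sc(101, 101, 200, "intron"), "ESSENTIAL_SPLICE_SITE")
  expect_equal(sc(199, 101, 200, "intron"), "ESSENTIAL_SPLICE_SITE")
  expect_equal(sc(103, 101, 200, "intron"), "SPLICE_SITE")
  expect_equal(sc(108, 101, 200, "intron"), "SPLICE_SITE")
  expect_equal(sc(109, 101, 200, "intron"), character())
  expect_equal(sc(3, 1, 100, "exon"), "SPLICE_SITE")
  expect_equal(sc(4, 1, 100, "exon"), character())
  ## a deletion spanning both windows reports both classes
  expect_setequal(splice_class(101, 105, 101, 200, "intron", cfg),
                  c("ESSENTIAL_SPLICE_SITE", "SPLICE_SITE"))
  ## the wider essential window is available through configuration
  cfg3 <- annotation_config(essential_intron_window = 3)
  expect_equal(splice_class(103, 103, 101, 200, "intron", cfg3),
               "ESSENTIAL_SPLICE_SITE")
})

test_that("exhaustive per-position scan of a 3-exon transcript matches the window arithmetic", {
  env <- default_fixture()
  idx_one <- gene_index(list(env$index$transcripts[["GA1.t1"]]))
  tx <- idx_one$transcripts[[1]]
  exons <- tx$exons
  introns <- data.frame(start = exons$end[-3] + 1, end = exons$start[-1] - 1)
  oracle <- function(p) {
    out <- character()
    for (i in seq_len(nrow(introns))) {
      if (p >= introns$start[i] && p <= introns$end[i]) {
        off <- min(p - introns$start[i] + 1, introns$end[i] - p + 1)
        if (off <= 2) out <- c(out, "ESSENTIAL_SPLICE_SITE")
        if (off >= 3 && off <= 8) out <- c(out, "SPLICE_SITE")
      }
    }
    for (i in seq_len(nrow(exons))) {
      if (p >= exons$start[i] && p <= exons$end[i]) {
        off <- min(p - exons$start[i] + 1, exons$end[i] - p + 1)
        if (off <= 3) out <- c(out, "SPLICE_SITE")
      }
    }
    sort(unique(out))
  }
  for (p in tx$start:tx$end) {
    ref <- fetch_slice(env$genome, "1", p)
    rec <- variant_record("scan", "1", p, p, other_base(ref), ref)
    got <- classify_variant(rec, idx_one, env$genome)$classes
    expect_equal(
      sort(intersect(got, c("ESSENTIAL_SPLICE_SITE", "SPLICE_SITE"))),
      oracle(p), info = paste("position", p))
  }
})

test_that("UTR classes are orientation-aware", {
  env <- default_fixture()
  txA <- env$index$transcripts[["GA1.t1"]]   # plus strand
  txB <- env$index$transcripts[["GB1.t1"]]   # minus strand
  txC <- env$index$transcripts[["GC1.t1"]]   # non-coding
  expect_equal(utr_class(txA, 3015), "5PRIME_UTR")
  expect_equal(utr_class(txA, 3480), "3PRIME_UTR")
  ## same relative geometry, minus strand: sides flip
  expect_equal(utr_class(txB, 8480), "5PRIME_UTR")
  expect_equal(utr_class(txB, 8020), "3PRIME_UTR")
  expect_equal(utr_class(txC, 12050), "WITHIN_NON_CODING_TRANSCRIPT")
})

test_that("codon effects: stop gain/loss, start loss, het residues, MNPs", {
  env <- default_fixture()
  txA <- env$index$transcripts[["GA1.t1"]]
  ## TAT -> TAA at the third codon base (plus strand)
  eff <- coding_effect(txA, env$genome, 3260, 3260, "T", "A")
  expect_equal(eff$classes, "STOP_GAINED")
  expect_equal(eff$codon, "TAW")
  ## terminal TAA -> TAC
  eff <- coding_effect(txA, env$genome, 3460, 3460, "A", "C")
  expect_equal(eff$classes, "STOP_LOST")
  expect_equal(eff$ref_amino_acid, "Ter")
  ## ATG -> ACG in the initiation codon
  eff <- coding_effect(txA, env$genome, 3042, 3042, "T", "C")
  expect_equal(eff$classes, "START_LOST")
  ## heterozygous SNP with two differing residues joins them with "/"
  eff <- coding_effect(txA, env$genome, 3228, 3228, "G", c("A", "T"))
  expect_equal(eff$classes, "NON_SYNONYMOUS_CODING")
  expect_equal(eff$codon, "DCT")
  expect_equal(eff$amino_acid, "Thr/Ser")
  expect_equal(eff$ref_amino_acid, "Ala")
  ## an MNP spanning two codons reports both residues
  ref2 <- fetch_slice(env$genome, "1", 3245, 3246)  # codon 35/36 boundary
  eff <- coding_effect(txA, env$genome, 3245, 3246, ref2, "AA")
  expect_equal(eff$ref_amino_acid, "AlaAla")
  expect_equal(eff$classes, "NON_SYNONYMOUS_CODING")
})

test_that("synonymy matches independent translation of the edited coding sequence", {
  env <- default_fixture()
  for (tx_id in c("GA1.t1", "GB1.t1")) {
    tx <- env$index$transcripts[[tx_id]]
    cds_coords <- unlist(lapply(seq_len(nrow(tx$exons)), function(i) {
      seq(max(tx$exons$start[i], tx$coding_start),
          min(tx$exons$end[i], tx$coding_end))
    }))
    translate_at <- function(edit_pos = NULL, alt = NULL) {
      chrom_seq <- env$genome$sequences[["1"]]
      if (!is.null(edit_pos)) substr(chrom_seq, edit_pos, edit_pos) <- alt
      cds_plus <- paste(vapply(cds_coords, function(p)
        substr(chrom_seq, p, p), ""), collapse = "")
      dna <- Biostrings::DNAString(cds_plus)
      if (tx$strand == -1L) dna <- Biostrings::reverseComplement(dna)
      as.character(Biostrings::translate(dna))
    }
    ref_prot <- translate_at()
    set.seed(13)
    for (rep in 1:75) {
      p <- sample(cds_coords, 1)
      ref <- fetch_slice(env$genome, "1", p)
      alt <- sample(setdiff(c("A", "C", "G", "T"), ref), 1)
      eff <- coding_effect(tx, env$genome, p, p, ref, alt)
      same_protein <- identical(translate_at(p, alt), ref_prot)
      expect_equal("SYNONYMOUS_CODING" %in% eff$classes, same_protein,
                   info = sprintf("%s %d %s>%s", tx_id, p, ref, alt))
    }
  }
})

test_that("ATG-creation scan covers all three windows and creation only", {
  env <- default_fixture()
  txA <- env$index$transcripts[["GA1.t1"]]
  ## planted 5'-UTR context: ACG at 3024-3026
  expect_true(start_gained_scan(txA, env$genome, 3025, 3025, "C", "T"))
  ## enumeration oracle over the UTR portion of exon 1
  utr_pos <- 3003:3038  # stay clear of the transcript edge
  exon1_seq <- fetch_slice(env$genome, "1", 3001, 3100)
  for (p in utr_pos) {
    ref <- fetch_slice(env$genome, "1", p)
    for (alt in setdiff(c("A", "C", "G", "T"), ref)) {
      edited <- exon1_seq
      substr(edited, p - 3000, p - 3000) <- alt
      expected <- FALSE
      for (w in (p - 3002):(p - 3000)) {
        if (w < 1 || w + 2 > nchar(exon1_seq)) next
        if (substr(edited, w, w + 2) == "ATG" &&
            substr(exon1_seq, w, w + 2) != "ATG") expected <- TRUE
      }
      expect_equal(start_gained_scan(txA, env$genome, p, p, ref, alt),
                   expected, info = sprintf("pos %d alt %s", p, alt))
    }
  }
})

test_that("coding indels keep or shift the frame by length modulo 3", {
  env <- default_fixture()
  run <- default_run()
  sets <- setNames(run$class_sets, run$basic$Name)
  expect_true("FRAMESHIFT" %in% sets[["v_frameshift"]])
  expect_false("FRAMEKEEP" %in% sets[["v_frameshift"]])
  expect_true("FRAMEKEEP" %in% sets[["v_framekeep"]])
  ## a 1 bp coding insertion shifts the frame
  rec <- variant_record("ins1", "1", 3230, 3230, "G", "")
  res <- classify_variant(rec, env$index, env$genome)
  expect_true("FRAMESHIFT" %in% res$classes)
})

test_that("complex deletions subclassify and suppress frame classes", {
  env <- default_fixture()
  txA <- env$index$transcripts[["GA1.t1"]]
  txB <- env$index$transcripts[["GB1.t1"]]
  expect_equal(indel_coding_effect(txA, 3190, 3330), "DELETE_EXONS")
  expect_equal(indel_coding_effect(txA, 3195, 3205), "ACCEPTOR")
  expect_equal(indel_coding_effect(txA, 3315, 3325), "DONOR")
  ## the same genomic junction geometry flips on the minus strand
  expect_equal(indel_coding_effect(txB, 8195, 8205), "DONOR")
  expect_equal(indel_coding_effect(txB, 8315, 8325), "ACCEPTOR")
  run <- default_run()
  sets <- setNames(run$class_sets, run$basic$Name)
  expect_equal(intersect(sets[["v_del_exon"]],
                         c("FRAMESHIFT", "FRAMEKEEP")), character(0))
  expect_true("MERGE_EXONS" %in% sets[["v_merge_exons"]])
})

test_that("genetic-code presets map to the right translation tables", {
  std <- load_genetic_code("standard")
  expect_equal(unname(std$table[["ATG"]]), "M")
  expect_true("TAA" %in% std$stop_codons)
  expect_true("ATG" %in% std$start_codons)
  expect_equal(unname(load_genetic_code("mycoplasma")$table[["TGA"]]), "W")
  expect_true("AGA" %in% load_genetic_code("mitochondria")$stop_codons)
  expect_equal(load_genetic_code("prokaryotes")$ncbi_id, "11")
  expect_error(load_genetic_code("klingon"), "valid names")
  ## a TGA stop under the standard code is tryptophan under mycoplasma:
  ## plant TGA by mutating codon 40 TAT -> TGA (two steps not needed;
  ## compare classification of T->G at codon position 2 with A at 3)
  env <- default_fixture()
  txA <- env$index$transcripts[["GA1.t1"]]
  eff_std <- coding_effect(txA, env$genome, 3259, 3260, "AT", "GA",
                           code = std)
  expect_equal(eff_std$classes, "STOP_GAINED")
  eff_myc <- coding_effect(txA, env$genome, 3259, 3260, "AT", "GA",
                           code = load_genetic_code("mycoplasma"))
  expect_equal(eff_myc$classes, "NON_SYNONYMOUS_CODING")
})

test_that("annotation is strand-symmetric under genome mirroring", {
  env <- default_fixture()
  L <- nchar(env$genome$sequences[["1"]])
  mirror_seq <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(env$genome$sequences[["1"]])))
  mgenome <- reference_genome(c("1" = mirror_seq))
  mirror <- function(x) L - x + 1
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  revcomp_str <- function(s) if (nzchar(s))
    as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
  else ""
  mtx <- function(tx) {
    transcript(tx$transcript_id, tx$gene_id, tx$gene_name, "1",
               -tx$strand,
               data.frame(start = mirror(tx$exons$end),
                          end = mirror(tx$exons$start)),
               coding_start = if (is_coding_tx(tx)) mirror(tx$coding_end)
                 else NA,
               coding_end = if (is_coding_tx(tx)) mirror(tx$coding_start)
                 else NA)
  }
  midx <- gene_index(lapply(env$index$transcripts, mtx))
  recs <- parse_variant_table(env$fx$variants)
  for (rec in recs) {
    mrec <- rec
    mrec$rel_start <- mirror(rec$rel_end)
    mrec$rel_end <- mirror(rec$rel_start)
    mrec$ref_allele <- revcomp_str(rec$ref_allele)
    mrec$alt_alleles <- vapply(rec$alt_alleles, revcomp_str, "")
    got <- classify_variant(rec, env$index, env$genome)
    mgot <- classify_variant(mrec, midx, mgenome)
    ## inversion alleles are reversal-defined, so their type (hence MNP
    ## vs INVERSION) is not mirror-invariant; classes of positional and
    ## coding consequences must be
    expect_setequal(got$classes, mgot$classes)
    expect_equal(got$basic$Region, mgot$basic$Region)
  }
})
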