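test_that("six-column parsing handles het alleles, IUPAC codes and gaps", {
  recs <- parse_variant_table(table2_lines)
  expect_length(recs, 7L)
  expect_equal(recs[[5]]$alt_alleles, c("A", "G"))
  expect_equal(recs[[5]]$ref_allele, "T")
  expect_equal(recs[[7]]$alt_alleles, "")
  expect_equal(recs[[7]]$ref_allele, "CA")
  expect_equal(recs[[7]]$rel_start, 12588586)
  expect_equal(recs[[7]]$rel_end, 12588587)
  expect_equal(recs[[3]]$ref_allele, "")  # insertion, em-dash reference

  iupac <- parse_variant_table("varX\t1\t100\t100\tR\tT", has_header = FALSE)
  expect_equal(iupac[[1]]$alt_alleles, c("A", "G"))

  tri <- parse_variant_table("varY\t1\t100\t100\tA/C/G\tT",
                             has_header = FALSE)
  expect_equal(tri[[1]]$alt_alleles, c("A", "C", "G"))
})

test_that("header detection and malformed lines", {
  no_header <- parse_variant_table(table2_lines[-1])
  expect_length(no_header, 7L)

  lines <- c(table2_lines[1:3], "broken line with wrong columns",
             "varZ\t1\t500\t400\tA\tC",   # start > end
             table2_lines[4])
  warns <- capture_warnings(recs <- parse_variant_table(lines))
  expect_length(warns, 2L)
  expect_match(warns, "skipped", all = TRUE)
  expect_length(recs, 3L)
  skipped <- attr(recs, "skipped")
  expect_equal(nrow(skipped), 2L)
  expect_true(any(grepl("rel_start", skipped$reason)))
})

test_that("writing then re-parsing the six-column format is the identity", {
  recs <- parse_variant_table(table2_lines)
  path <- tempfile(fileext = ".txt")
  write_variant_table(recs, path)
  back <- parse_variant_table(path)
  expect_length(back, length(recs))
  for (i in seq_along(recs)) {
    expect_equal(unclass(back[[i]]), unclass(recs[[i]]))
  }
})

test_that("VCF parsing converts anchored indels to the gap convention", {
  path <- tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO",
    "12\t12588585\t.\tTCA\tT\t.\t.\t.",
    "1\t100\t.\tA\tG\t.\t.\t.",
    "1\t100\trs1\tA\tG,T\t.\t.\t.",
    "12\t12506183\t.\tA\tAT\t.\t.\t."), path)
  recs <- parse_vcf(path)
  expect_length(recs, 4L)
  ## deletion must equal the gap-convention record of the worked example
  expect_equal(recs[[1]]$rel_start, 12588586)
  expect_equal(recs[[1]]$rel_end, 12588587)
  expect_equal(recs[[1]]$ref_allele, "CA")
  expect_equal(recs[[1]]$alt_alleles, "")
  expect_equal(recs[[2]]$alt_alleles, "G")
  expect_equal(recs[[3]]$alt_alleles, c("G", "T"))
  expect_equal(recs[[3]]$name, "rs1")
  ## insertion: T inserted after the anchor base
  expect_equal(recs[[4]]$rel_start, 12506184)
  expect_equal(recs[[4]]$rel_end, 12506184)
  expect_equal(recs[[4]]$ref_allele, "")
  expect_equal(recs[[4]]$alt_alleles, "T")
})

test_that("VCF conversion agrees with the apply-edit oracle", {
  genome <- reference_genome(c(z = "ACGTACCCCGTTTAGC"))
  cases <- list(
    list(pos = 4, ref = "TACCC", alt = "T"),     # deletion
    list(pos = 6, ref = "C", alt = "CCGT"),      # insertion
    list(pos = 11, ref = "TTT", alt = "TAG"))    # block substitution
  path <- tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO",
    vapply(cases, function(cs) {
      paste("z", cs$pos, ".", cs$ref, cs$alt, ".", ".", ".", sep = "\t")
    }, "")), path)
  recs <- parse_vcf(path)
  for (i in seq_along(cases)) {
    cs <- cases[[i]]; r <- recs[[i]]
    vcf_edit <- apply_edit(genome, "z", cs$pos, cs$ref, cs$alt)
    rec_edit <- apply_edit(genome, "z", r$rel_start, r$ref_allele,
                           r$alt_alleles[[1]])
    expect_identical(rec_edit, vcf_edit)
  }
})

test_that("pgSnp records carry alleles but defer the reference", {
  path <- tempfile(fileext = ".pgsnp")
  writeLines(c("track type=pgSnp",
               "1\t99\t100\tA/G\t2\t10,12\t90,90"), path)
  recs <- parse_pgsnp(path)
  expect_length(recs, 1L)
  expect_equal(recs[[1]]$rel_start, 100)
  expect_equal(recs[[1]]$alt_alleles, c("A", "G"))
  expect_true(is.na(recs[[1]]$ref_allele))
})

test_that("table writers emit headers, NA literals and joined IDs", {
  run <- default_run()
  base_path <- tempfile(fileext = ".txt")
  write_basic(run$basic, base_path)
  lines <- readLines(base_path)
  expect_equal(length(lines), nrow(run$basic) + 1L)
  expect_match(lines[[1]], "^Name\tChr\t")
  ## the poly-A deletion carries two comma-joined known identifiers
  polyA <- lines[grepl("^v_polyA_del\t", lines)]
  expect_match(polyA, "rsK3, rsK4")
  expect_match(lines[[2]], "\tNA($|\t)")  # NA cells written literally

  empty <- run$basic[0, ]
  empty_path <- tempfile(fileext = ".txt")
  write_basic(empty, empty_path)
  expect_equal(length(readLines(empty_path)), 1L)

  det_path <- tempfile(fileext = ".txt")
  write_detailed(run$detailed, det_path)
  det_lines <- readLines(det_path)
  ## one detailed row per (variant, transcript): the two-transcript gene
  ## yields two rows per coding variant
  expect_equal(sum(grepl("^v_syn_minus\t", det_lines)), 2L)
})

test_that("HTML output wraps the same cells and hyperlinks identifiers", {
  run <- default_run()
  path <- tempfile(fileext = ".html")
  write_basic(run$basic, path, format = "html",
              url_template = "https://example.org/variant/%s")
  html <- paste(readLines(path), collapse = "\n")
  expect_match(html, "<table")
  expect_match(html, "href=\"https://example.org/variant/rsK3\"")
  expect_match(html, ">rsK4</a>")
})

test_that("the run report counts variants, classes and mismatches", {
  env <- default_fixture()
  recs <- parse_variant_table(table2_lines)
  run <- run_annotation(recs, genome = table2_genome())
  path <- tempfile(fileext = ".txt")
  write_report(run$report, path)
  txt <- paste(readLines(path), collapse = "\n")
  expect_match(txt, "variations processed: 7")
  expect_match(txt, "reference mismatches: 0")

  ## plant one mismatching reference allele
  recs2 <- recs
  recs2[[1]]$ref_allele <- other_base(recs2[[1]]$ref_allele)
  run2 <- run_annotation(recs2, genome = table2_genome())
  expect_equal(run2$report$n_ref_mismatch, 1L)

  ## class membership is additive: totals over classes can exceed the
  ## number of classified variants
  run3 <- default_run()
  expect_gte(sum(run3$report$class_counts),
             sum(!is.na(run3$basic$Region)))
})

test_that("GFF export is valid GFF3 with classes and status in column 9", {
  run <- default_run()
  path <- tempfile(fileext = ".gff3")
  export_gff(run, path)
  gr <- rtracklayer::import(path)
  expect_equal(length(gr), sum(!is.na(run$basic$ChromStart)))
  syn <- gr[gr$ID == "v_syn"]
  expect_equal(GenomicRanges::start(syn), 3070)
  expect_equal(syn$func_class, "SYNONYMOUS_CODING")
  expect_equal(syn$status, "KNOWN")
  ## insertions become width-1 features flagged as insertions
  ins <- gr[gr$ID == "v_ins_dup"]
  expect_equal(GenomicRanges::width(ins), 1L)
  expect_equal(ins$insertion, "true")
})

test_that("row conservation: one basic row per input line, always", {
  env <- default_fixture()
  lines <- readLines(env$fx$variants)
  lines <- c(lines, "garbled line")
  expect_warning(recs <- parse_variant_table(lines), "skipped")
  run <- run_annotation(recs, "table", env$index, genome = env$genome)
  expect_equal(nrow(run$basic), length(lines) - 1L)  # minus header
  expect_true("garbled" %in% run$basic$Name)
})
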