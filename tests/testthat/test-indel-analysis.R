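## Printed repeat contexts used as fixtures: a 20-A homopolymer run, a
## GAGGCT hexamer repeat and a TGA/ATG trinucleotide repeat, each stored as
## an offset chromosome slice.
polyA_genome <- function() {
  reference_genome(c("12" = "TCTCAAAAAAAAAAAAAAAAAAAAGAAC"),
                   offsets = 6551615)
}
hexamer_genome <- function() {
  reference_genome(c("14" = "GTGGAGGCTGAGGCTGAGGCTGAGGCGG"),
                   offsets = 21560750)
}
trinuc_genome <- function() {
  reference_genome(c("19" = "AGTGATGATGATGATGATGATGATGATGACG"),
                   offsets = 30500117)
}

test_that("scattered single-A deletions in a poly-A run are one indel", {
  g <- polyA_genome()
  dels <- data.frame(
    name = c("rs71918324", "rs71702364", "rs5796236", "rs35226411",
             "rs72397401", "rs35471040"),
    chromosome = "12",
    pos = c(6551619, 6551627, 6551628, 6551629, 6551630, 6551638),
    ref_allele = "A", alt_allele = "-", stringsAsFactors = FALSE)
  grouped <- group_equivalent(dels, g)
  expect_equal(unique(grouped$group), 1L)
  expect_equal(unique(grouped$canonical_pos), 6551619)
  expect_equal(unique(grouped$sequence), "A")
})

test_that("hexamer-repeat deletions share one 6 bp canonical form", {
  g <- hexamer_genome()
  dels <- data.frame(
    name = c("rs3841049", "rs71814523", "rs72383174", "rs7179484"),
    chromosome = "14",
    pos = c(21560753, 21560759, 21560762, 21560764),
    ref_allele = c("GAGGCT", "GAGGCT", "GCTGAG", "TGAGGC"),
    alt_allele = "-", stringsAsFactors = FALSE)
  grouped <- group_equivalent(dels, g)
  expect_equal(unique(grouped$group), 1L)
  expect_equal(nchar(unique(grouped$sequence)), 6L)
  expect_equal(unique(grouped$canonical_pos), 21560753)
})

test_that("five trinucleotide-deletion identifiers unite in one group", {
  g <- trinuc_genome()
  dels <- data.frame(
    name = c("rs3840928", "rs71645759", "rs67383412", "rs10559374",
             "rs58360763"),
    chromosome = "19",
    pos = c(30500119, 30500127, 30500129, 30500130, 30500143),
    ref_allele = c("TGA", "ATG", "GAT", "ATG", "TGA"),
    alt_allele = "-", stringsAsFactors = FALSE)
  grouped <- group_equivalent(dels, g)
  expect_equal(unique(grouped$group), 1L)
  expect_equal(length(unique(grouped$name)), 5L)
})

test_that("canonicalization basics: no repeat, mismatch, anchored input", {
  g <- reference_genome(c(c1 = "ATGCA"))
  ci <- canonicalize(g, "c1", 3, "G", "")
  expect_equal(ci$canonical_pos, 3)
  expect_equal(ci$sequence, "G")
  expect_equal(ci$op, "DELETION")
  expect_error(canonicalize(g, "c1", 3, "T", ""), "does not match")
  ## VCF-style anchored alleles are trimmed before shifting
  ci2 <- canonicalize(g, "c1", 2, "TG", "T")
  expect_equal(ci2$canonical_pos, 3)
  expect_equal(ci2$sequence, "G")
  ## mixed-length pairs that are not pure indels are rejected
  expect_error(canonicalize(g, "c1", 1, "ATG", "CC"), "pure")
})

test_that("canonicalization is idempotent on random repeat-region indels", {
  set.seed(23)
  tract <- paste0(paste(sample(c("A", "C", "G", "T"), 20, TRUE),
                        collapse = ""),
                  strrep("A", 15), strrep("TG", 8), strrep("GAT", 6),
                  paste(sample(c("A", "C", "G", "T"), 20, TRUE),
                        collapse = ""))
  g <- reference_genome(c(r = tract))
  for (rep in 1:200) {
    L <- sample(1:4, 1)
    pos <- sample(21:(nchar(tract) - 25), 1)
    if (runif(1) < 0.5) {
      ci <- canonicalize(g, "r", pos, fetch_slice(g, "r", pos, pos + L - 1),
                         "")
    } else {
      ins <- paste(sample(c("A", "T", "G"), L, TRUE), collapse = "")
      ci <- canonicalize(g, "r", pos, "", ins)
    }
    again <- if (ci$op == "DELETION") {
      canonicalize(g, "r", ci$canonical_pos, ci$sequence, "")
    } else {
      canonicalize(g, "r", ci$canonical_pos, "", ci$sequence)
    }
    expect_identical(again, ci)
  }
})

test_that("grouping is equivalent to comparing edited strings (1000 random indels)", {
  set.seed(29)
  tract <- paste0("CCGT", strrep("A", 30), "CT", strrep("AG", 12), "T",
                  strrep("CAT", 10), "GGAC")
  g <- reference_genome(c(r = tract))
  n <- 1000
  lo <- 2L; hi <- nchar(tract) - 6L
  recs <- data.frame(name = paste0("i", seq_len(n)),
                     chromosome = "r",
                     pos = sample(lo:hi, n, TRUE),
                     ref_allele = "", alt_allele = "",
                     stringsAsFactors = FALSE)
  for (i in seq_len(n)) {
    L <- sample(1:3, 1)
    if (runif(1) < 0.5) {
      recs$ref_allele[i] <- fetch_slice(g, "r", recs$pos[i],
                                        recs$pos[i] + L - 1)
      recs$alt_allele[i] <- "-"
    } else {
      recs$ref_allele[i] <- "-"
      recs$alt_allele[i] <- paste(sample(c("A", "G", "CAT"), 1))
    }
  }
  grouped <- group_equivalent(recs, g)
  norm <- function(x) ifelse(x == "-", "", x)
  edited <- vapply(seq_len(n), function(i) {
    apply_edit(g, "r", recs$pos[i], norm(recs$ref_allele[i]),
               norm(recs$alt_allele[i]))
  }, "")
  ## same group <=> byte-identical edited chromosome
  expect_identical(grouped$group, match(edited, unique(edited)))
})

test_that("period length finds the smallest repeat unit", {
  expect_equal(period_length("AAAAA"), 1L)
  expect_equal(period_length("GAGGCT"), 6L)
  expect_equal(period_length("TGATGA"), 3L)
  expect_error(period_length(""), "empty")
  ## brute-force oracle over random strings
  set.seed(31)
  brute <- function(s) {
    ch <- strsplit(s, NULL)[[1]]
    for (p in seq_along(ch)) {
      if (p == length(ch)) return(p)
      if (all(ch[seq_len(length(ch) - p)] == ch[seq_len(length(ch) - p) + p]))
        return(p)
    }
  }
  for (rep in 1:200) {
    s <- paste(sample(c("A", "C"), sample(1:12, 1), TRUE), collapse = "")
    expect_equal(period_length(s), brute(s), info = s)
  }
  ## primitive unit repeated k times has period |unit|
  for (unit in c("AT", "GAT", "ACGT")) {
    expect_equal(period_length(strrep(unit, 5)), nchar(unit))
  }
  expect_lte(period_length("ACGTAC"), 6L)
})

test_that("genesis flags duplication, flank inversion and shift independently", {
  ## insertion of A immediately after an A is a duplication
  g <- reference_genome(c(x = "CCTACGG"))
  rep_a <- genesis(g, "x", 5, "INSERTION", "A")  # left flank = "A"
  expect_true(rep_a$is_duplication)
  ## insertion GATT next to flank TTAG is an inversion of the flank
  g2 <- reference_genome(c(x = "CCCCTTAGCCCC"))
  rep_i <- genesis(g2, "x", 9, "INSERTION", "GATT")
  expect_true(rep_i$is_inversion_of_flank)
  expect_false(rep_i$is_duplication)
  ## insertion of C between A and G: nothing flags
  g3 <- reference_genome(c(x = "TTTTAGTTTT"))
  rep_n <- genesis(g3, "x", 6, "INSERTION", "C")
  expect_false(rep_n$is_duplication)
  expect_false(rep_n$is_inversion_of_flank)
  expect_false(rep_n$is_shift)
  ## shifted copy within the scan window but not adjacent
  g4 <- reference_genome(c(x = paste0("TTTTTTTTTT", "GGCA", "CCCCC",
                                      "GGCA", "TTTTTTTTTT")))
  rep_s <- genesis(g4, "x", 11, "DELETION", "GGCA")
  expect_true(rep_s$is_shift)
  expect_false(rep_s$is_duplication)
  ## flank truncated by the chromosome edge -> NA flags
  g5 <- reference_genome(c(x = "ACGTACGT"))
  rep_e <- genesis(g5, "x", 1, "DELETION", "ACG")
  expect_true(is.na(rep_e$is_duplication))
})

test_that("transposon check searches both flanks and both orientations", {
  ## copy of the inserted 4-mer sits 5 bp into the right flank
  g <- reference_genome(c(x = paste0(strrep("T", 15), strrep("C", 5),
                                     "GAAT", strrep("T", 10))))
  expect_true(transposon_flag(g, "x", 16, "INSERTION", "GAAT"))
  ## reversal of the sequence in the left flank counts too
  g2 <- reference_genome(c(x = paste0(strrep("C", 10), "TAAG",
                                      strrep("C", 15))))
  expect_true(transposon_flag(g2, "x", 15, "INSERTION", "GAAT"))
  ## homopolymer insertions inside their own run always flag
  g3 <- reference_genome(c(x = paste0(strrep("C", 5), strrep("A", 10),
                                      strrep("C", 5))))
  expect_true(transposon_flag(g3, "x", 10, "INSERTION", "A"))
  ## no occurrence anywhere near: not flagged
  g4 <- reference_genome(c(x = strrep("C", 40)))
  expect_false(transposon_flag(g4, "x", 20, "INSERTION", "GAAT"))
})
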