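## Shared fixtures, built once per test run.

.fixture_cache <- new.env()

default_fixture <- function() {
  if (is.null(.fixture_cache$fx)) {
    fx <- make_fixture(file.path(tempdir(), "snpclassify-default-fixture"))
    .fixture_cache$fx <- fx
    .fixture_cache$index <- load_gff(fx$gff)
    .fixture_cache$genome <- read_genome_fasta(fx$fasta)
    .fixture_cache$truth <- utils::read.delim(fx$truth,
                                              stringsAsFactors = FALSE)
  }
  .fixture_cache
}

default_run <- function() {
  if (is.null(.fixture_cache$run)) {
    env <- default_fixture()
    .fixture_cache$run <- run_annotation(
      env$fx$variants, "table", env$index, genome = env$genome,
      known = env$fx$known, config = annotation_config(genesis = TRUE))
  }
  .fixture_cache$run
}

## The printed seven-variation worked example (em-dash gap alleles).
table2_lines <- c(
  "Name\tChromosome\tRelStart\tRelEnd\tAltAllele\tRefAllele",
  "var1\t12\t12483171\t12483171\tC\tG",
  "var2\t12\t12483200\t12483200\tG\tT",
  "var3\t12\t12506184\t12506184\tT\t—",
  "var4\t12\t12527105\t12527108\tGATT\tTTAG",
  "var5\t12\t12550471\t12550471\tA/G\tT",
  "var6\t12\t12588583\t12588583\tA\tC",
  "var7\t12\t12588586\t12588587\t—\tCA")

## Genome slice of chromosome 12 covering the worked example, with the
## printed reference alleles planted (filler elsewhere).
table2_genome <- function() {
  if (is.null(.fixture_cache$t2genome)) {
    off <- 12480001
    set.seed(42)
    n <- 12600000 - off + 1
    bases <- sample(c("A", "C", "G", "T"), n, replace = TRUE)
    put <- function(pos, s) {
      ch <- strsplit(s, NULL)[[1L]]
      bases[(pos - off + 1):(pos - off + length(ch))] <<- ch
    }
    put(12483171, "G"); put(12483200, "T"); put(12527105, "TTAG")
    put(12550471, "T"); put(12588583, "C"); put(12588586, "CA")
    .fixture_cache$t2genome <- reference_genome(
      c("12" = paste(bases, collapse = "")), offsets = off)
  }
  .fixture_cache$t2genome
}

## Apply an indel (gap convention) to a stored chromosome; the independent
## oracle for equivalence grouping and VCF conversion.
apply_edit <- function(genome, chromosome, pos, ref, alt) {
  s <- genome$sequences[[chromosome]]
  off <- genome$offsets[[chromosome]]
  i <- pos - off + 1
  if (nzchar(ref)) {
    stopifnot(substr(s, i, i + nchar(ref) - 1) == ref)
    paste0(substr(s, 1, i - 1), alt, substr(s, i + nchar(ref), nchar(s)))
  } else {
    paste0(substr(s, 1, i - 1), alt, substr(s, i, nchar(s)))
  }
}

## A base different from `ref` (deterministic).
other_base <- function(ref) c(A = "C", C = "A", G = "T", T = "G")[[ref]]
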