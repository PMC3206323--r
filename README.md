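# snpclassify

Offline functional annotation of sequence variants — SNPs, multi-nucleotide
polymorphisms (MNPs), inversions and indels — against transcript models, for
resequencing projects that produce long variant lists and need to know, per
variant and per transcript, *what it does*: is it known or novel, where does
it fall relative to gene structure, and what is its consequence for the
protein?

Everything runs from local files (variant list, GFF3/BED12 annotation, FASTA
reference, optional known-variants VCF); no database connection is ever
required, which makes runs reproducible and species-agnostic.

## What it computes

For each input variant the pipeline:

1. maps relative positions to chromosomal coordinates
   (`chrom = rel + offset − 1`) and verifies the claimed reference allele
   against the genome — mismatches are kept in the output as `REF_MISMATCH`
   rows with NA annotations, never silently dropped;
2. types the alleles: **SNP** (both length 1), **inversion** (alternative
   allele is the reversal of the reference allele, length > 1), **MNP**
   (equal length, neither of the above), **indel** (lengths differ);
3. resolves **KNOWN / NOVEL / ALTERNATIVE** status against a local
   known-variants VCF — indels are left-normalized first, so records that
   annotate the same event at different placements inside a repeat tract
   match each other;
4. finds the nearest gene and signed distance, and assigns one or more of
   **21 functional classes** per overlapping transcript: positional classes
   (INTERGENIC, UPSTREAM/DOWNSTREAM within 5 kb, INTRONIC, 5′/3′ UTR,
   WITHIN_NON_CODING_TRANSCRIPT), splice windows (ESSENTIAL_SPLICE_SITE for
   the first/last two intronic bases, SPLICE_SITE for intronic bases 3–8 and
   exonic bases 1–3 from a boundary), codon-level consequences under a
   selectable genetic code (SYNONYMOUS/NON_SYNONYMOUS_CODING, STOP_GAINED,
   STOP_LOST, START_LOST, POTENTIAL_START_GAINED for variants creating an
   ATG in a 5′ UTR or non-coding exon), frame consequences for coding indels
   (FRAMEKEEP/FRAMESHIFT by length change modulo 3) and complex-deletion
   subclasses (DELETE_EXONS, MERGE_EXONS, ACCEPTOR, DONOR) — 15 classes can
   apply to an SNP, 19 to an indel;
5. optionally characterizes each indel's evolutionary genesis: duplication
   of the adjacent sequence, inversion of a flank, shifted copy within a
   scan window, repeat period length, and a 13 bp transposon flank check.

Outputs are a basic table (one row per variant), a detailed table (one row
per variant × transcript, with IUPAC-coded codons and amino acids), a text
report, and optional HTML tables and a GFF3 export.

## Worked example

The package ships a deterministic fixture generator that writes a synthetic
genome, annotation, variant list and known-variants VCF covering every
class:

```r
library(snpclassify)
fx  <- make_fixture(tempfile())
run <- run_annotation(fx$variants, "table", fx$gff,
                      genome = fx$fasta, known = fx$known)
run$basic[run$basic$Name %in%
  c("v_syn", "v_nonsyn", "v_startgain", "v_frameshift", "v_polyA_del"), ]
```

```
         Name        Region  Type              FuncClass NearestGene Distance      Status         ID
        v_syn CODING_REGION   SNP      SYNONYMOUS_CODING       GENEA        0       KNOWN       rsK1
     v_nonsyn CODING_REGION   SNP  NON_SYNONYMOUS_CODING       GENEA        0 ALTERNATIVE       rsK2
  v_startgain    5PRIME_UTR   SNP POTENTIAL_START_GAINED       GENEA        0       NOVEL         NA
 v_frameshift CODING_REGION INDEL             FRAMESHIFT       GENEA        0       NOVEL         NA
  v_polyA_del    INTERGENIC INDEL                   NONE       GENEC    -5410       KNOWN rsK3, rsK4
```

Reading the rows: `v_syn` is a known coding SNP that leaves the amino acid
unchanged; `v_nonsyn` collides with a known variant at the same position but
with a different allele (`ALTERNATIVE`); `v_startgain` creates an ATG in the
5′ UTR; the 2 bp deletion `v_frameshift` breaks the reading frame; and the
single-A deletion `v_polyA_del`, although submitted at a different position
than either database record, is recognized as the same event as *both*
known deletions in the poly-A run (two rsIDs) thanks to left-normalization.

The detailed table shows per-transcript consequences with the variable codon
position IUPAC-coded (here on a minus-strand gene with two transcripts):

```r
run$detailed[run$detailed$Name == "v_syn_minus", ]
```

```
        Name Codon AminoAcid RefAminoAcid         FuncClass Transcript Strand
 v_syn_minus   GCS       Ala          Ala SYNONYMOUS_CODING     GB1.t1     -1
 v_syn_minus   GCS       Ala          Ala SYNONYMOUS_CODING     GB1.t2     -1
```

Equivalently placed indels in repeat tracts collapse onto one canonical
form:

```r
g <- reference_genome(c("12" = "TCTCAAAAAAAAAAAAAAAAAAAAGAAC"),
                      offsets = 6551615)
dels <- data.frame(name = c("rs71918324", "rs71702364", "rs5796236"),
                   chromosome = "12", pos = c(6551619, 6551627, 6551628),
                   ref_allele = "A", alt_allele = "-")
group_equivalent(dels, g)
```

```
       name     pos canonical_pos sequence group
 rs71918324 6551619       6551619        A     1
 rs71702364 6551627       6551619        A     1
  rs5796236 6551628       6551619        A     1
```

## Command line

A thin wrapper over the same functions:

```sh
Rscript inst/scripts/annotate_variants.R \
    --variants input.txt --gff genes.gff3 --fasta genome.fa \
    --known dbsnp.vcf --out results/run1 --genesis --export-gff
```

## Vignette

`vignettes/variant-classification.Rmd` documents the classification model,
its parameters and defaults, the synthetic-fixture design, numerical
conventions and known limitations.
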