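---
title: "Variant functional classification: model, parameters and design"
author: "snpclassify"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Variant functional classification: model, parameters and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

# The problem

Resequencing projects yield long lists of differences between a sample and
a reference genome. Two questions dominate the downstream analysis: *is a
variant already known* (e.g. carries an rsID in a local dbSNP extract), and
*what does it do* — where does it fall relative to gene structure, and what
is its consequence for transcripts and proteins? `snpclassify` answers both
offline, from a variant list, a GFF3/BED12 gene annotation, a FASTA
reference and an optional known-variants VCF.

# The classification model

## Variant types

Each reference/alternative allele pair is typed by pure string comparison:

* **SNP** — both alleles exactly one base;
* **inversion** — equal length > 1 and the alternative allele equals the
  *character reversal* of the reference allele;
* **MNP** — equal length, neither SNP nor inversion;
* **indel** — different lengths.

Whether "inversion" should mean plain reversal or biological reverse
complement is genuinely ambiguous in this classification tradition; allele
pairs such as `TTAG`/`GATT` satisfy reversal but not reverse complement, so
plain reversal is the default, with `annotation_config(inversion =
"revcomp")` switching to the reverse-complement reading everywhere the
notion is used (typing and flank-inversion genesis). With several
alternative alleles (heterozygous or pooled-DNA calls, up to three) the
most complex per-allele type is reported (`INDEL > INVERSION > MNP > SNP`),
because the basic table has a single Type cell.

## Positional classes

The nearest gene is found per chromosome with a signed,
chromosome-coordinate distance: negative when the gene lies before the
variant, positive when after, 0 on overlap. This sign convention is
deliberately strand-*independent* — it makes Distance testable against a
brute-force scan and stable across annotation strand errors. Strand
awareness enters only in the labels: within the distance threshold
(default **5000 bp**, the scale at which promoters are expected) the
variant is UPSTREAM if it lies 5′ of the gene *in the gene's orientation*,
DOWNSTREAM otherwise; beyond the threshold it is INTERGENIC; at distance 0
the per-transcript logic below takes over, for every transcript of every
overlapping gene (genes overlapping on opposite strands both contribute).
When two genes are equidistant the tie breaks deterministically (smaller
gene start, then lexicographic gene id); the choice is arbitrary but
reproducible.

## Per-transcript classes

Inside a transcript, a variant is located in an exon, an intron, or
spanning a boundary.

* **Intronic** variants of coding transcripts are INTRONIC; splice windows
  are additive: the first/last **2** intronic bases are
  ESSENTIAL_SPLICE_SITE, intronic bases **3–8** from either end and exonic
  bases **1–3** from either exon end are SPLICE_SITE. The essential window
  is configurable to 3 (`essential_intron_window`) for the wider reading
  used by some annotation schemes; 2 is the default because it matches the
  canonical GT/AG dinucleotides. The windows are symmetric in both region
  ends, so no strand information is needed.
* **Exonic, non-coding transcript**: WITHIN_NON_CODING_TRANSCRIPT (the
  label also applies to introns of non-coding genes — INTRONIC is reserved
  for coding genes).
* **Exonic, outside the coding span**: 5PRIME_UTR or 3PRIME_UTR, decided in
  transcript orientation.
* **Exonic, coding, substitution**: the spliced coding sequence is built in
  transcript orientation (minus strand ⇒ reverse complement), each
  alternative allele substituted, and the affected codons compared:
  SYNONYMOUS_CODING iff every alternative residue equals the reference;
  otherwise NON_SYNONYMOUS_CODING, with STOP_GAINED / STOP_LOST when the
  alternative / reference codon is a stop, and START_LOST for a
  non-synonymous change in the initiation codon. Stop and start classes
  *replace* the synonymous/non-synonymous label for that transcript — they
  are the more informative statement about the same codon. MNPs evaluate
  every affected codon and are non-synonymous if any residue changes. The
  reported codon string carries an IUPAC symbol covering reference and
  alternative bases at each variable position (e.g. `GCS` for a C/G
  third-position polymorphism on the minus strand); heterozygous calls with
  two differing residues report them `/`-joined.
* **POTENTIAL_START_GAINED** applies to substitution variants in the 5′ UTR
  of a coding transcript or the exon of a non-coding transcript: the three
  transcript-orientation trinucleotide windows covering the variant are
  scanned, and the class is assigned iff some window becomes ATG that was
  not ATG in the reference (creation only). Translation-initiation context
  strength (Kozak scoring) is out of scope — the class is a *potential*
  start, by design.
* **Coding indels** contained in an exon: FRAMEKEEP if the length change is
  a multiple of 3, else FRAMESHIFT; a deletion that removes the annotated
  initiation or termination codon additionally reports START_LOST /
  STOP_LOST.
* **Complex deletions** spanning exon/intron structure: DELETE_EXONS
  (an entire exon removed), MERGE_EXONS (an entire intron removed — whether
  the deletion matches the intron exactly or also takes flanking exonic
  bases, the two exons fuse), ACCEPTOR / DONOR (the junction at the
  transcript-orientation start / end of an exon removed). Because the
  emerging splice pattern is unknown once a splice site is gone, these
  subclasses suppress FRAMEKEEP/FRAMESHIFT for that transcript.

This yields 21 classes; 15 can apply to an SNP and 19 to an indel
(substitution-only codon classes are never assigned to indels; frame and
whole-feature deletion classes are indel-only).

## Severity ranking

The basic table compresses a variant's class set into one cell. The
ranking (configurable) follows conventional consequence-severity
orderings: truncating > frame-disrupting > start/stop loss > complex
deletions > missense > in-frame > splice > potential start > synonymous.
Purely positional classes (UTRs, INTRONIC, UPSTREAM, …) never enter this
cell — a variant carrying only positional classes reports `NONE`, since
its location is already in the Region column.

## Known / novel / alternative status

A variant is KNOWN when a record in the known-variants store shares its
coordinates and at least one alternative allele; ALTERNATIVE when the
coordinates collide but no allele matches; NOVEL otherwise. A heterozygous
call counts as KNOWN if *any* of its alleles matches — the matching allele
is the known polymorphism. Indels are compared by **canonical form**: the
left-most equivalent placement, obtained by shifting the event leftwards
one base at a time while the edited chromosome is unchanged (the standard
left-alignment convention; any placement convention would do for the
equivalence decision, but left-shift gives deterministic group
representatives). Two indels are the same event iff their canonical forms
are equal — this is what makes scattered placements of one deletion inside
a homopolymer or microsatellite run collapse onto a single record, and it
is exercised in the tests against an independent apply-the-edit-and-compare
oracle. Indels colliding at the canonical position with different content
are reported ALTERNATIVE.

## Indel genesis

Optionally each indel is characterized by: duplication of the immediately
adjacent equal-length flank; inversion of such a flank (reversal semantics
as above); a shifted copy within a scan window (default **50 bp**, an
implementation default chosen to cover the typical microhomology scale) on
either side but not adjacent; the repeat **period length** of its sequence
(smallest `p` with `s[i] = s[i+p]`; a period shorter than the sequence
length reveals multi-step mutational history); and a **transposon flank
check**: the indel sequence (or its inversion; long sequences probed by
their first/last 13 bp) searched as a substring of the 13 bp flank on
either side. The original description of the flank comparison does not fix
a match criterion; substring search in both flanks and both orientations is
the implemented operationalization.

# Input conventions

* Coordinates are **1-based with inclusive ends** everywhere; an SNP has
  `start = end`. Deletions carry the deleted bases as reference allele and
  an empty ("-"/"—") alternative; insertions the mirror image, placed
  between `start − 1` and `start` with `end = start`.
* VCF anchor bases are stripped (position advanced) on input, so VCF
  records and gap-convention records of the same event are
  interchangeable; this is tested with an apply-edit oracle.
* Relative coordinates are mapped by `chrom = rel + ref_offset − 1`, where
  `ref_offset` is the chromosomal start of the reference sequence used in
  the experiment; genome FASTA headers may carry `offset=N` tokens so that
  a short chromosome slice can be addressed with true chromosomal
  coordinates.
* Whether the six-column format has a header line is auto-detected by
  testing whether the third column of the first line is numeric.
* pgSnp carries no reference allele; it is resolved from the genome at
  run time and alleles equal to the reference are dropped from the
  alternative set.
* Malformed lines are skipped with a warning rather than aborting the run —
  batch robustness matters more than strictness for million-line inputs —
  but each skipped line still contributes an NA row, so the basic table
  always has one row per input line. Reference mismatches likewise stay in
  the output (`REF_MISMATCH`, all annotations NA) and are counted in the
  report.

# Genetic codes

`load_genetic_code()` exposes five presets backed by the NCBI translation
tables: standard → 1, prokaryotes → 11, yeasts → 12, mycoplasma → 4,
mitochondria → 2 (vertebrate mitochondrial). The presets name code
*families* rather than tables, so this mapping is a design decision; it
changes real consequences (e.g. TGA is tryptophan, not stop, under the
mycoplasma code). A coding span whose length is not a multiple of three
triggers a warning and the trailing partial codon is ignored.

# The synthetic fixture

`make_fixture()` writes a deterministic 20 kb chromosome with a plus-strand
3-exon coding gene, a minus-strand mirror gene with two identical
transcripts (so multi-transcript output rows are exercised), a non-coding
gene, a 24 bp poly-A tract and a GAT×9 microsatellite, plus a variant list
and known-VCF planting all 21 classes and all three statuses. Filler
sequence is seeded random, but every context a truth label depends on is
written explicitly, so the labels hold for any seed. Two minus-strand
coding SNPs are planted in contexts chosen so that their codon strings
exercise the IUPAC notation (`GCS` with Ala/Ala, `MAA` with Lys→Gln).

What the fixture does *not* emulate: realistic base composition and repeat
landscapes, overlapping genes, alternative splicing with differing reading
frames, very long genes, or realistic variant density. Passing the recall
test therefore demonstrates that every classification path is implemented
correctly on clean inputs, not that performance or accuracy on messy real
annotations (truncated CDS, trans-spliced genes, contig-edge features) is
guaranteed.

`make_single_gene_genome()` builds the one-gene chromosome used for
exhaustive positional scans; the acceptance script classifies an SNP at
every one of the 18,000 positions outside the gene to locate the
UPSTREAM/DOWNSTREAM → INTERGENIC flip empirically rather than reading the
threshold back from the configuration.

# Numerical and degenerate-input choices

* All computations are exact integer/string operations; there are no
  tolerances to tune and reruns are byte-identical.
* Problem sizes in the test suite (a 20 kb fixture chromosome, 1,000
  random repeat-region indels, exhaustive per-position transcript scans,
  100-gene nearest-gene randomizations) were chosen as the smallest sizes
  that still exercise every code path and boundary.
* Left-normalization stops at the edge of the stored genome window;
  equality of canonical forms is therefore decided within the window, which
  is sufficient whenever compared records share the stored context.
* An empty chromosome in the gene index yields `(no gene, +Inf)` and the
  variant is INTERGENIC with NA NearestGene.
* Genesis flags whose flank is truncated by the sequence edge are NA, not
  false — absence of evidence is reported as such.
* Insertions cannot be encoded as zero-width GFF3 spans; the export anchors
  them as width-1 features with an `insertion=true` attribute.

# Known limitations

* Conservation scores and protein-domain membership are *columns*, filled
  from an optional user-supplied per-position table; the package does not
  compute them.
* Substitutions spanning an exon/intron junction receive splice/intron
  classes only; no codon consequence is attempted for the exonic part.
* Insertions at an exon/intron junction are located by their insertion
  point; junction-disrupting insertions are not given ACCEPTOR/DONOR
  (those subclasses are deletion-defined).
* The inversion type is a string-level notion (see above), not a
  breakpoint-level structural-variant call.
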