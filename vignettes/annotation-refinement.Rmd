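---
title: "Refining draft genome annotations with annorefine"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Refining draft genome annotations with annorefine}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(annorefine)
```

## The problem

Ab initio gene predictors run on large, repeat-rich plant genomes
(conifer genomes are the extreme case: tens of gigabases, >70%
repetitive, introns that can exceed hundreds of kilobases) massively
over-predict. A raw prediction set can carry several times more "genes"
than the plant plausibly has, dominated by fragmented models,
monoexonic false positives, and unmasked transposable-element ORFs.
`annorefine` implements the post-prediction refinement cascade that
turns such a draft into a defensible gene set: structural validation,
duplicate collapsing, evidence-based merging against transcriptome
alignments, repeat and transposable-element removal, and a functional
annotation requirement — with every removal logged to a per-gene
rejection record so the provenance of the final set is auditable.

## The refinement model

A *gene model* is a chain of CDS segments on one genome sequence and
strand. Internally all coordinates are 0-based half-open; the GFF3
surface is 1-based inclusive and the conversion lives only at the I/O
boundary, which keeps the interval arithmetic free of off-by-one cases.
Each mRNA in the input becomes an independent model; locus structure is
recovered later by span overlap, which matches inputs that are already
one model per gene.

The cascade applies the following stages in fixed order. Each stage is
a pure set-to-set function that logs one `(gene_id, stage, reason)`
record per removal, so `|input| = |kept| + |removals|` holds at every
stage, and every stage is idempotent.

1. **Structural filters.** Spliced CDS at least 300 bp; every exon and
   every intron at least 9 bp (inclusive minima); spliced CDS must
   begin with `ATG` and end with `TAA`/`TAG`/`TGA`; zero in-frame stop
   codons before the terminal codon. Codon tests are case-insensitive
   (softmask lowercase is not sequence-meaningful) but strict about
   ambiguity: an `N` anywhere in the codon fails the test — a
   conservative, deterministic choice. Translation always starts at CDS
   position 0; a non-zero phase on the transcript-first segment marks
   the model start-absent rather than shifting the frame, which treats
   predictor dialects that encode incompleteness in the phase column as
   incomplete models, not errors.
2. **Deduplication.** Models with identical coordinates collapse to
   the lexicographically smallest id. Among same-strand span-overlap
   clusters one representative survives: greatest CDS length, then
   greatest span, then smallest id. The representative rule is this
   package's documented stand-in for "unique genes only" semantics
   whose exact tie-breaking upstream tools do not publish.
3. **Evidence merge.** Trusted transcriptome-alignment models (first
   pushed through this same cascade) displace ab initio models that
   are span-nested in or identical to them; one alignment spanning
   several predictions collapses the whole cluster to the single
   supported gene; partial overlaps go to the better model under the
   completeness key (start/stop tier, then CDS length, then span, then
   id — completeness dominates length). Opposite-strand overlap is
   ignored: antisense nesting is biologically legitimate. Chained
   partial overlaps are resolved greedily in descending key order,
   iterated to a fixpoint, each model displacing or being displaced at
   most once per pass; this makes the merge deterministic and
   input-order-invariant. Evidence models that displace nothing and
   overlap nothing are excluded by default (a configuration flag admits
   them as novel loci); the rationale is that additions to the final
   set should come from the evidence set's own filtered survivors, not
   from every stray alignment.
4. **Softmask filter.** Models *more than* 80% lowercase are removed —
   the inequality is strict, so exactly 0.80 survives. The fraction is
   computed over the spliced CDS, not the genomic span: long-intron
   conifer genes legitimately sit inside oceans of masked repeat, and a
   span-based rule would discard exactly the long genes the evidence
   merge recovers. A `mask_mode = "span"` switch is provided since the
   alternative reading is defensible.
5. **Transposable-element keywords.** Any domain or functional-hit
   description containing (case-insensitive substring, list order)
   `gag-polypeptide`, `retrotransposon`, `reverse transcriptase`,
   `retrovirus`, `copia`, or `gypsy` removes the gene. Matching is
   hyphen-sensitive and the list is configurable.
6. **Monoexonic domain gate.** Monoexonic genes — the dominant
   false-positive class — must additionally carry at least one protein
   domain whose text matches no TE keyword.
7. **Functional 50/50 filter.** A gene survives only with a similarity
   hit covering at least 50% of both query and target (inclusive:
   "at least"). The stricter 80/80 level never removes anything; it
   only labels survivors for reporting. This split — membership at
   50/50, stringency 80/80 as a statistic — is the only reading
   consistent with a final set that is 100% annotated at 50/50 but
   only partially at 80/80. Hits are reduced to one best hit per gene
   first (lowest e-value, ties by higher query coverage, then target
   id) so the filter is deterministic.

After the cascade the final set carries three checkable guarantees:
every retained gene is complete (start and stop), the 50/50 annotation
rate is exactly 100%, and no same-strand nested pair survives.

## Parameters

| parameter | default | unit | meaning |
|---|---|---|---|
| `min_cds` | 300 | bp | minimum spliced CDS length (inclusive) |
| `min_exon`, `min_intron` | 9 | bp | minimum feature lengths (inclusive) |
| `allowed_inframe_stops` | 0 | codons | internal stops tolerated |
| `max_mask_fraction` | 0.80 | fraction | removal strictly above this |
| `coverage_query/target` | 50 | % | membership coverage threshold |
| `strict_query/target` | 80 | % | reporting-only stringency |
| `monoexonic_requires_domain` | TRUE | — | domain gate for monoexonic genes |

Summary statistics follow the conventions used for annotation
comparison tables: gene length is the genomic span including introns
(which is why a set can have a ~18 kbp mean but a ~2 kbp median), and
the median is the lower middle value for even counts so integer lengths
stay integers.

## The synthetic fixture generator

`generate_fixture()` is first-class, tested code, not a throwaway: it
builds a toy softmasked genome plus GFF3/TSV inputs in which every gene
is planted to violate exactly one rule (or none), together with a truth
table of expected fates. CDS synthesis draws internal codons from the
61 sense codons so no accidental in-frame stop contaminates a class;
defects are then injected surgically (a 297-bp CDS, one 8-bp exon, one
8-bp intron, a `GTG` start, a sense final codon, a planted `TGA`, an
85% lowercase tract, a TE-labelled domain, a missing domain or hit).
Nested clusters embed complete mini-genes inside a spanning evidence
model's intron; partial overlaps thread a primary model's intron across
the evidence model's terminal exon, so both models are simultaneously
valid on the shared genome sequence. Generation is fully seeded and
byte-deterministic.

The canonical fixture (default spec) plants ten genes per defect class,
five nested clusters of 3–20 models, ten partial-overlap pairs and ten
duplicate pairs: about 200 genes in total, sized so the whole pipeline
runs in seconds. What passing it shows is that every filtering and
merging rule fires exactly where intended and nowhere else; what it
does not show is performance on real repeat landscapes, splice-site
realism, or the behaviour of coverage values computed by real aligners
— the generator emulates the *contract* of those inputs, not their
noise structure.

## Numerical and degenerate-input choices

* Empty annotation sets are legal everywhere and produce all-zero
  summaries, not errors.
* CDS lengths that are not codon multiples are judged on their complete
  codons; the last complete codon is treated as terminal for the
  in-frame stop count.
* Monoexonic models have no intron, so their minimum intron length is
  undefined (`NA`) and the intron filter does not apply to them.
* All orderings (gene output order, best-hit selection, dedup
  representatives, merge processing order) are total orders ending in a
  lexicographic id tie-break, which is what makes byte-identical reruns
  and input-order invariance testable properties rather than hopes.
* Thresholds are pinned by construction tests at 299/300/301 bp CDS,
  8/9 bp features, 0.79/0.80/0.81 mask and 49.9/50.0/80.0% coverage.

## Known limitations

* Splice-site (GT–AG) validation and BUSCO-style completeness scoring
  are out of scope; the structural tier only sees codon structure.
* The redundant-isoform representative rule and the fixpoint resolution
  of chained partial overlaps are documented package choices where
  upstream tools leave behaviour unspecified.
* Whether the softmask threshold should read the CDS or the whole span
  is genuinely ambiguous; both are implemented, CDS is the default for
  the biological reason above.
* The merge operates on genomic spans, not exon-level intersection; it
  will not build chimeras or reconcile exon boundaries.
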