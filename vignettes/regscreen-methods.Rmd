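---
title: "Methods: a stringent comparative screen for dimeric SOX10 response elements"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a stringent comparative screen for dimeric SOX10 response elements}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(regscreen)
```

# The screening model

SOX10, the SOXE-family transcription factor atop the Schwann-cell
transcriptional hierarchy, binds a degenerate pentamer — `ACACA` or `ACAAD`
with D ∈ {G, T, A} — either as a monomer or as a head-to-head dimer: on the
plus strand, a forward monomer followed after a short intervening sequence
(the *spacer*) by the reverse complement of a monomer, `TGTGT` or `HTTGT`
with H ∈ {A, C, T}. Degeneracy this severe makes the raw motif almost
uninformative on its own: at human-like base composition the expected
two-strand monomer density is

$$ 2 \sum_{w \in \{\mathtt{ACACA},\mathtt{ACAAG},\mathtt{ACAAT},\mathtt{ACAAA}\}} \; \prod_{j=1}^{5} p_{w_j} \approx 0.0105\ \text{per bp}, $$

i.e. tens of millions of genome-wide occurrences. The screen therefore
treats the motif call as the *first* of a chain of independent predicates,
each of which a functional response element should satisfy:

* **dimeric architecture** with a spacer of 5–10 bp;
* **exact-identity conservation** across human, mouse and chicken of the
  *entire* element, spacer included;
* **non-coding position** (no overlap with CDS-exon sequence — UTR exons
  and introns qualify);
* **gene proximity** (inside a transcript span ± 2.5 kb);
* **chromatin support** (≥ 1 bp overlap with an open-chromatin peak whose
  F-Seq-style score meets a threshold, and with a TF-occupancy ChIP peak).

Each stage is a pure subset operation on the previous one, so the row-count
funnel the pipeline logs is a complete description of where candidates die.

# Motif grammar and scanning

The grammar is data, not code (`motif_grammar()`): a set of equal-length
forward IUPAC patterns, a spacer range, and reverse patterns that are
*always derived* by reverse complement, never user-supplied — a grammar
whose reverse set drifted out of sync with its forward set could silently
call non-dimers. Scanning is a single plus-strand pass with regex
lookahead, so overlapping matches are all reported and one forward monomer
can participate in several dimers at different spacers (all pairings are
reported; exact duplicates removed). Two choices deserve justification:

* **Monomer default `strand_mode = "both"`.** A two-strand monomer count
  at genome scale is what reproduces the published tens-of-millions
  magnitude; a one-strand scan gives roughly half. Both modes are exposed.
* **Dimers scan one strand only.** The dimer pattern family is closed
  under reverse complement (the mirror of a forward–spacer–reverse
  arrangement is again such an arrangement), so a both-strand dimer pass
  would double-count every site. The acceptance suite asserts the mirror
  identity explicitly.

`N` matches no consensus position (assembly padding must never produce
calls) but is permitted inside spacers, whose content is unconstrained.
Note the validated-site catalogue contains two sites whose *second*
monomer degenerates from the strict reverse consensus (`TCTGT`, `TTTCT`);
the grammar is deliberately not widened to cover them — they enter the
spacer statistics as curated data, not as scanner output.

# Exact-identity conservation

`extract_identical_segments()` is an exact-match phylogenetic-footprinting
primitive: a column of an alignment block qualifies when every species in
the set is present and carries the same nucleotide (case-insensitive); a
gap *in any species* or an `N` disqualifies the column. Maximal runs of
qualifying columns at reference length ≥ 5 bp (the monomer length) are
emitted in reference coordinates. Policy decisions where reasonable tools
differ:

* any-species gaps disqualify (identity requires a nucleotide in each
  species);
* lowercase (repeat-masked) residues count — masking is orthogonal to
  identity;
* `N` is absence of information, never identity;
* book-ended segments from adjacent blocks are unioned
  (`merge_segments()`), since multiz-style block boundaries are artifacts
  of the alignment, not of the sequence.

Minus-strand reference rows are flipped to plus coordinates at MAF read
time so that all output is reference-coordinate BED.

# Prioritization semantics

* **Containment, not overlap**: conservation must cover the full dimer
  including the spacer. A partially conserved dimer fails.
* **Non-coding** means no CDS-exon overlap, computed as the per-transcript
  intersection of the CDS span with the exon structure. This keeps 5′/3′
  UTR exons and introns eligible, which matters because functional
  elements concentrate in introns and proximal flanks.
* **Gene proximity** is overlap with transcript span ± 2.5 kb; relation
  labels (intronic, exonic-noncoding, upstream-/downstream-flank,
  strand-aware) make the stricter "intron or directly flanking" reading
  recoverable from the output without re-running.
* **Peak support** is any-overlap (≥ 1 bp) with a per-set score
  threshold — the defaults (DNase ≥ 0.08, ChIP ≥ 0) mirror F-Seq-scored
  open-chromatin practice. The best supporting score per set is recorded.
* **Nearest gene** measures distance to the transcript *span* (distance 0
  when overlapping), signed negative when the element lies 5′ of the
  transcript in transcript orientation; ties break by distance then
  alphabetically, for determinism.

# Overrepresentation test

The classic binomial overrepresentation test: with a list of $n$ genes, a
category of $K$ genes in a universe of $N$, $q = K/N$,

$$ \text{expected} = n q, \qquad p = \sum_{i=k}^{n} \binom{n}{i} q^i (1-q)^{n-i}, $$

with the inclusive upper tail and Bonferroni correction over all $m$
tested categories. The binomial (sampling with replacement from the
universe) rather than the hypergeometric was chosen because it is the
test behind the classic geneontology.org/PANTHER-era overrepresentation
output whose column semantics the result table mirrors (category size,
observed, expected, fold, corrected p); the hypergeometric is available
via `method = "hypergeometric"`. $N$ and $m$ are properties of the
annotation input, never hard-coded. A consistency check in the acceptance
suite verifies that a *single* universe size ($N = 22{,}920$, derived from
the best-anchored published expected count, $191 \cdot 60 / N = 0.5$)
reproduces all ten published expected counts for a 191-gene list to one
decimal. The published p-values themselves are not numeric targets: the
exact annotation release, universe and category count behind them are
unrecoverable, so they are checked only for consistency of magnitude.

Numerical note: the implementation uses `pbinom(k-1, n, q, lower.tail =
FALSE)`; tests verify it against direct summation to $10^{-12}$ relative
error and against the complement identity to $10^{-12}$ *absolute* error —
beyond that, $1 - P(X \le k-1)$ cancels catastrophically for tiny tails.

# Spacer statistics and the n = 7 validated set

The GC content of a *group* of spacers is pooled — total G+C over total
unambiguous bases — because that is the statistic under which the seven
validated active-and-required spacers (`CAAGC`, `GAACATT`, `CTGTTCTT`,
`GGGGCC`, `GGCCCCTC`, `GGCCTC`, `AAACAC`; 28 G/C of 46 bases) round to the
published 61%; the per-site mean (61.5%) is reported alongside. The
seven-element set itself is a reconstruction: of the eight validated
sites whose consensus deletion reduced activity, the one with a 20-bp
spacer is excluded because its two monomers were shown to act
independently rather than as a spaced dimer, and the published length
bound ("five to eight nucleotides") only holds for the remaining seven.
`validated_sites(active_only = TRUE)` encodes exactly this rule. Group
comparison is deliberately descriptive (ΔGC, Δ mean length); an optional
Wilcoxon rank-sum utility is labelled as an extension because the original
analysis reported no inferential test.

# What the synthetic data emulate — and what they do not

`simulation_config()` fixes the study conditions everything is tested
under:

* **background**: 100-kb i.i.d. genomes at base composition
  (0.295, 0.205, 0.205, 0.295) — AT-rich like the human genome, so that
  background scan rates extrapolate to genome-scale magnitudes;
* **gene models**: six transcripts in a deterministic three-exon geometry
  with UTR sequence on both sides of the CDS, on alternating strands, with
  a pitch wide enough to leave genuinely intergenic corridors;
* **planted sites**: five fully supported dimer positives across intronic
  and flank compartments, plus decoys that each violate exactly one
  predicate (CDS placement, missing peaks, missing conservation,
  intergenic position) and two conserved monomers;
* **alignment**: mouse at 0.25 and chicken at 0.40 per-base divergence
  outside declared identity blocks — representative of human–mouse and
  human–chicken neutral identity levels. The generator *guarantees* that
  exact-identity runs ≥ 5 bp exist only where declared: it forces a
  mismatch into any chance run and at the flanking column of every
  declared block. This makes truth records exact, at the cost of making
  the alignment slightly less random than a pure substitution process;
* **peaks**: covering peaks with scores drawn above threshold for
  supported sites, sub-threshold peaks over unsupported sites (so score
  filtering is exercised), and decoy peaks away from truth sites;
* **annotation**: a 20,000-gene universe, 100 categories of 50, a
  191-gene designated list with 10 members planted into one category —
  sized to match the published screen's list size.

Dimer placement uses rejection: a window around each planted site is
re-drawn until it scans to exactly the planted call, so recovery tests can
demand sensitivity *and* precision 1.0 rather than "at least the planted
sites". All generators are bit-reproducible from one integer seed; output
files record the seed and a config digest.

What passing these tests does *not* show about real data: i.i.d.
backgrounds have no repeats, CpG islands or compositional domains, so real
false-positive rates will differ; gapless toy alignments sidestep indel
ambiguity in reference-coordinate mapping; and planted enrichment has
none of the correlation structure of a real GO DAG (no term ancestry,
no gene multi-membership bias).

# Problem sizes and numerical choices

The shipped test and acceptance runs use 200 random 10-kb sequences for
scanner/oracle equivalence, 100 toy alignments for the conservation
oracle, 20 seeded 100-kb bundles for full-screen recovery, and 20
background genomes (2 Mb total) for rate checks — sizes chosen so the
statistical assertions (3σ bands on counts, Monte-Carlo agreement within
3 standard errors) are meaningful while the whole suite stays
desk-scale. Degenerate inputs are defined, not avoided: empty FASTA
records, zero-residue headers, `start ≥ end` BED lines, exon-count
mismatches and undersized MAF rows are all hard errors naming the
offending location; empty match lists flow through every filter as empty
data frames.

# Known limitations

* The grammar covers strict consensus families only — no PWM scoring, so
  near-consensus sites (as observed at two validated loci) are invisible
  to the scanner by design.
* Conservation is exact identity; substitution-model scores (phastCons,
  phyloP) would rank partially conserved elements the screen discards.
* Cross-assembly coordinate conversion (liftOver) is out of scope;
  intervals from different assemblies must be pre-converted.
* The genome-scale published counts (tens of millions of monomers,
  ~549k dimers, >2M conserved segments) require hg18 and the 44-way
  multiz alignment; the package reports extrapolations from its i.i.d.
  background instead, which reproduce the magnitudes but not the exact
  figures, since a real genome is not i.i.d.
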