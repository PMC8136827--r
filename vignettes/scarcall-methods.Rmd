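---
title: "Break-anchored scar calling: model, parameters and design notes"
author: "scarcall"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Break-anchored scar calling: model, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scarcall)
```

## The problem

A Cas9-induced double-strand break (DSB) at a chromosomal locus is repaired
by one of several pathways, each leaving a characteristic scar in the
sequence: non-homologous end joining (NHEJ) leaves small deletions or
insertions; polymerase-theta-mediated end joining (TMEJ, also called MMEJ
or alt-EJ) leaves deletions of 4 bp or more joined at short direct repeats
(microhomology, MH); other end joining leaves larger deletions without MH;
and homologous recombination (HR) copies a donor-specific marker into the
locus. Deep paired-end amplicon sequencing across the cut site therefore
records pathway utilization — if each read's junction can be decomposed
correctly.

Whole-read alignment to the uncut reference handles this poorly: gap
penalties scatter large or asymmetric deletions, and combined
insertion+deletion junctions are frequently mislocated. The decomposition
implemented here instead anchors everything to the one position that is
known *a priori*: the cut site.

## The decomposition model

A `target_locus` holds the reference amplicon, the 0-based cut index
(bases 5′ of the blunt cut), and a k-mer window size (default **k = 10**).
Two dictionaries are derived from it:

* upstream entries: for each deletion size $d = 0, 1, 2, \dots$, the k-mer
  of reference ending $d$ bases 5′ of the cut;
* downstream entries: the k-mer starting $d$ bases 3′ of the cut.

For each consensus read the caller finds the **upstream flank** (UF): the
dictionary entry with the *least* deletion $d_u$ that occurs in the read
(rightmost qualifying occurrence, ending position $p_u$). It then finds
the **downstream flank** (DF): the entry with least $d_d$ occurring at or
after $p_u - k + 2$, so anchor overlaps up to $k - 1$ are visible
(leftmost occurrence, starting position $p_d$). The anchor relationship
determines the call:

| relationship            | interpretation                             |
|-------------------------|--------------------------------------------|
| $p_d = p_u + 1$, $d_u = d_d = 0$ | unedited read (`NO_SCAR`)          |
| $p_d = p_u + 1$, deletion > 0    | simple deletion                    |
| $p_d \le p_u$           | MH-associated deletion; the overlap *is* the microhomology |
| $p_d > p_u + 1$         | insertion of the intervening sequence      |

Because each flank search retains its own copy of the microhomology (each
minimizes its own deletion), $d_u$ and $d_d$ are already MH-exclusive and
the total deletion is $d_u + d_d + |\mathrm{MH}|$. Reads carrying the
donor gene-conversion marker (exact substring; recommended length
$\ge 12$ nt) are called `HR` before any anchor search; reads where either
flank is not found at any deletion depth are `UNRESOLVED` and excluded
from frequency denominators but kept in the read accounting.

The method's key robustness property follows directly: substitution
sequencing errors affect a call only if they land inside one of the two
matched 10-mers (or, for the error to matter at all, inside the junction
itself); errors distal to those 20 nucleotides are invisible. The
property-style tests verify this with hundreds of randomized distal
mutations.

```{r fix-a}
loc <- make_mh_locus(seed = 1, motif_len = 6, left_gap = 9, right_gap = 8,
                     anchor_len = c(15, 16))
read <- apply_scar(loc, left_del = 9, right_del = 8, mh_len = 6)
classify_scars(call_junctions(read, loc))
```

## Pathway classification

Scarred reads are binned by three numbers — total deletion, MH length,
insertion length — applied in this order:

1. insertion ≥ 5 nt → **INSERTION** (regardless of associated deletion);
2. total deletion ≥ 4 nt and MH ≥ 2 nt → **TMEJ**;
3. total deletion ≥ 4 nt and MH < 2 nt → **NON_MH_EJ**;
4. otherwise (deletion < 4 nt, insertion < 5 nt) → **NHEJ**.

HR reads keep their `HR` label. The rules partition the scar space with no
gaps or overlaps (tested by exhaustive enumeration). One boundary is
genuinely ambiguous in the method's published description: the non-MH
end-joining insertion bound appears once as < 4 nt and once as < 5 nt; this
package uses **< 5 nt** everywhere so that the INSERTION class (≥ 5 nt) is
the exact complement. Users comparing against other tools should check
which convention those tools adopt.

Frequencies are computed over scarred reads only (`SCAR` + `HR` by
default): a large fraction of unedited reads come from chromosomes that
were never cut, so including them would dilute every pattern by an unknown
cutting efficiency. HR can be dropped from the denominator with
`include_hr = FALSE`. Pol θ-dependency ratios divide each pattern's
frequency by its frequency in a Polq-deficient control, flooring the
control at a pseudocount (default one read over the control's scarred
total) so that products absent from the control get a finite, flagged
ratio; ratios ≥ 2 mark Pol θ-dependent products.

## Read merging

Read 2 is reverse-complemented and slid ungapped against read 1; the
highest-identity offset with overlap ≥ `min_overlap` (default 20 nt, the
width of the junction-defining 20-mer) and mismatch fraction ≤
`max_mismatch_frac` (default 0.1) defines the consensus. Disagreements
take the higher-Phred base (ties: read-1 base at the minimum of the two
qualities). Exact prefix seeds of either mate in the other propose
candidate offsets first; the exhaustive scan runs only when no candidate
qualifies, so results match the brute-force scorer while staying fast.
Pairs with no qualifying overlap are counted as unmerged and excluded —
no N-gap concatenation is attempted, since junction calling on a gapped
consensus would need different guarantees. Variable-length 5′ phasing
offsets from phased amplicon primers are *not* trimmed: the anchors are
located anywhere in the consensus, so a shifted read frame is harmless.

## The synthetic-data generator

The generator emulates the structure of a sequenced Cas9 amplicon library:
a ~480 nt amplicon (default `flank_len = 240` per side), 2 × 300 nt
paired-end reads, a random 0–8 nt phasing prefix per read, independent
per-base substitution errors (default rate 0.001, a typical Illumina
substitution rate), and Phred qualities drawn from 30–40. Scarred
amplicons are built by deleting `left_del + MH + right_del` bases across
the cut (keeping one MH copy) and splicing in any insertion, so every read
has an exact ground truth recorded in a manifest.

Two locus constructors support different test needs:

* `make_locus()` rejection-samples a random amplicon in which **every
  k-mer is unique**, so simulated junctions have a single correct
  decomposition;
* `make_mh_locus()` engineers a repeat pair (`motif`) around the cut so a
  deletion spanning both gap segments and one motif copy is a genuine
  MH-mediated junction. The generator additionally rejects references
  where the base flanking either motif copy matches across the junction,
  which would extend the effective microhomology past `motif_len` — the
  caller would (correctly) report the longer overlap, but the fixture's
  stated geometry would be wrong.

What the simulations do **not** model: sequencing indel errors (an
optional concern deliberately excluded so merge-stage ambiguity cannot
leak into junction-logic tests), PCR chimeras and jackpot duplicates,
instrument-specific quality/error coupling, and real-locus sequence
composition (repeats, homopolymers). Passing tests therefore demonstrate
the correctness of the decomposition and accounting logic under clean
Poisson-like noise, not performance on adversarial genomic contexts.

## Droplet digital PCR quantification

Molecules partition into ~20,000 droplets approximately Poisson, so the
mean copies per droplet is $\lambda = -\ln(1 - p)$ with $p$ the
positive-droplet fraction. A signature repair product's concentration is
normalized to 100 copies of a genomic reference amplicon:
$\text{percent repair} = 100\,\lambda_{sig} / \lambda_{ref}$.

Confidence intervals use the Wilson score interval on $p$ pushed through
the same transform — chosen because it stays well-behaved at zero or few
positive droplets, where the Wald interval collapses. The ratio interval
comes from the delta method on the log scale, treating the two channels as
independent. Saturated wells (`positives == total`) are rejected rather
than clipped: $\lambda$ is unbounded there and the assay must be diluted.
Replicate wells are pooled by summing counts before transformation.

```{r dpcr}
percent_repair(5000, 20000, 5000, 20000)   # equal channels: 100 by identity
```

## Numerical and design choices

* **Coordinates** are 0-based half-open throughout; `cut_index` counts
  bases 5′ of the blunt cut. This makes every deletion size a plain
  difference of indices.
* **Occurrence tie-breaks**: UF takes the rightmost occurrence (leaving at
  least one base after it so a DF start exists), DF the leftmost at or
  after $p_u - k + 2$. Both bias the anchors toward the junction,
  maximizing retained sequence — the same greedy, least-deletion semantics
  as the dictionary ordering. UF is located before DF; no global joint
  minimization is attempted.
* **Insertion left-alignment**: when an inserted base equals the first
  downstream reference base, the DF leftmost-occurrence rule left-aligns
  the call, the standard indel convention. Documented, not "corrected".
* **MH longer than k − 1** falls out of the anchor arithmetic (the DF
  anchor can sit fully inside the upstream match region); no post-hoc
  extension is performed, which would double-count.
* **Junction ambiguity is intrinsic, not a bug**: when the reference
  happens to carry a direct repeat at the junction, a pure deletion and an
  MH-mediated deletion of the same total size describe the same molecule.
  The caller resolves these deterministically by least deletion (the MH
  decomposition), and the test suite canonicalizes expected values through
  an independent brute-force oracle for exactly this reason.
* **Known limitation**: an insertion that happens to contain a dictionary
  k-mer (e.g. a templated insertion copied from near the cut) can capture
  a flank anchor, producing a smaller-deletion call whose reconstruction
  does not match the read. This is inherent to junction-anchored matching;
  on unique-k-mer simulated loci it requires a ≥ 10 nt templated match and
  is correspondingly rare in the property suites.
* **kmer_size < 6 is rejected**: with a 4-letter alphabet, windows shorter
  than ~6 nt match spuriously in almost any amplicon.

## Problem sizes used by the test suite

The property suites run at sizes chosen to exercise the guarantees while
keeping a full check fast on a laptop: flank-minimality versus the
brute-force oracle on 1,000 randomized junctions over references ≤ 290 nt;
pair-merge → junction round-trips on 1,000 error-free simulated reads;
frequency recovery within three binomial standard errors on a seeded
5,000-read, six-pattern mixture at error rate 0.001; and call invariance
under 500 rounds of triple distal substitutions. All randomness is seeded;
every run is reproducible.
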