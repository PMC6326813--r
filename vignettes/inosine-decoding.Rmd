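---
title: "Decoding and stalling at inosine: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decoding and stalling at inosine: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(inodecode)
```

## The problem

Adenosine-to-inosine (A-to-I) editing by ADAR enzymes is the most abundant
recoding modification in metazoan mRNA. Inosine lacks the C6 amino group of
adenosine and can form two-hydrogen-bond pairs with C, U or A, with pair
stability I:C > I:A > I:U. The textbook assumption is that the ribosome
reads inosine as guanosine (the I:C pair), but the pairing chemistry allows
decoding as A or U as well, and a poorly paired codon–anticodon complex may
also slow the ribosome down. `inodecode` implements the quantitative
machinery needed to ask both questions: *what* is incorporated at an
inosine-containing codon, and *does the ribosome stall there* — in a
reporter/mass-spectrometry setting and in ribosome-profiling data from
tissue.

## Codon-space model

A codon with $k$ inosines has $3^k$ decoding variants (each I read as G, A
or U). Variants are enumerated in a fixed order — the first inosine
position varying slowest, each inosine cycling G, A, U — which reflects
the base-pair stability ranking and makes every output deterministic.
There are $4^3 - 3^3 = 37$ codons over \{A, C, U, I\} with at least one
inosine: 27 with one, 9 with two, 1 with three (`III`).

Because the genetic code is degenerate, not every pair of decodings is
distinguishable at the protein level. `classify_resolvability()` partitions
the $3^k$ interpretations by their amino-acid product: `IAC` resolves fully
(D/N/Y), `CAI` is G/A-ambiguous (both Gln), and `CUI` is completely
unresolvable (all Leu). This is why wobble-position test codons are
mostly uninformative in an amino-acid readout and why the in-vitro panel
concentrates on codons with inosine in positions 1–2.

STOP is carried as the distinct symbol `*`, never as a residue. A
decoding class is *primary* when it contains the all-G interpretation;
read-through species exist only where that primary decoding is itself a
stop (`UAI`, `UIA`): a stop among the *alternative* decodings of a sense
codon (e.g. `IAA` read as UAA) is modelled as a premature-termination
event whose product is indistinguishable from the drop-off peptide.

## Reporter construct

The reporter ORF (start, FLAG tag, Leu-Ser-Lys, an 8-residue spacer, the
test codon, Ser-Asn-Ile-Ser-Lys, a C-terminal extension, stop) is encoded
by a template whose measured region uses only A, C and T. Transcription
with ITP instead of GTP places inosine at every template G, so the
*measured peptide window* — the residues strictly between the two lysines
flanking the test codon, the only MS-visible region — carries inosine
exclusively at the test codon. `validate_construct()` reports every other
G codon in the ORF and classifies the consequence of its I substitution
(`UCG` in the Leu-Ser-Lys linker is synonymous — the Ser family is
four-fold degenerate; the FLAG codons are not, which is why the FLAG
epitope's integrity under ITP transcription is a known caveat rather than
something the pipeline models). A G inside the measured window is a hard
failure because it would corrupt the readout.

One deliberate representation choice: the ITP transcript physically
contains no G at all — even the start codon is AUI. The ORF is therefore
represented at the *design* (template) level, with the test codon carried
as supplied; the transcript string itself is exposed separately and is
G-free. All species arithmetic happens in the design frame.

LysC digestion is implemented with full specificity (cleavage after every
K, no proline block) and configurable missed cleavages. The measured
peptide for the primary decoding of `IAC` is `SSFYSLTSDSNISK`; the
truncated drop-off product is `SSFYSLTS`, ending immediately upstream of
the test codon and carrying no C-terminal K. Monoisotopic masses use the
standard residue table plus water, with carbamidomethyl-Cys fixed
(+57.021464 Da) and Met oxidation variable (+15.994915 Da). Full-length
species with coinciding masses (Leu/Ile) are merged into a single flagged
quantification unit; the reporter design avoids informative L/I contrasts,
so the merge is a safety net rather than a limitation in practice.

## MS quantification

Per-peptide response factors come from two concatemer standards: fusion
proteins containing every candidate peptide once, in two different orders,
hence equimolar. The factor of a peptide is its intensity relative to a
reference peptide (the primary species by default), computed per standard
and combined as the arithmetic mean of the two standards. Corrected
intensity is raw intensity divided by the factor.

Decoding fractions are percentages of the summed full-length signal.
Choices that the data do not dictate, made once and documented here:

* **Replicates** are combined by computing fractions per replicate and
  averaging, with s.e.m. reported — not by pooling intensities. Pooling
  would weight replicates by their overall signal.
* **Detection threshold** (default 0.4% of the total full-length signal):
  classes at or below it are flagged undetected but *retained in the
  denominator* — the threshold is a detection call, not a censoring of
  mass. A fraction-of-primary variant of the threshold would change
  numbers only in the far tail and is not implemented.
* **Truncation** is `100 * truncated / (truncated + all full-length)`.
  The denominator includes all full-length species so percentages are
  bounded in [0, 100] and comparable across codons.
* **Standard injections**: the calibration consumes replicate injections
  of each standard (three by default in the generator) and averages them
  before forming ratios. With multiplicative noise of CV 0.1 this puts
  the response-factor error around 6% — small enough that a 2× response
  difference (the K- versus E-peptide case relevant to `IAA`/`IAI`) is
  recovered well inside 10%.

Group summaries of truncation (by inosine count, or by position of a
single inosine) are unweighted means with s.e.m., reported at two
decimals; comparisons against prose-level statements ("~5%", "about 30%")
round to the nearest multiple of 5. The bundled measured table
(`load_truncation_table()`) holds the per-codon truncation percentages of
the 31 sense test codons; running `group_truncation()` on it yields
5.24% (n = 21) for single-inosine codons, 28.44% (n = 9) for
double-inosine codons and 36% for `III` — i.e. 29.2% over all
multi-inosine codons.

## Amplicon QC

Faithful ITP incorporation is checked by sequencing cDNA of the reporter
transcript. Reads arrive pre-positioned (the generator emits true
offsets; mapping is out of scope), and `build_pileup()` counts bases per
reference position; the mismatch rate is `1 - ref_count/depth`. Inosine
reverse-transcribes like G, so I positions are compared as G — an
error-free inosine construct reads back at 100% fidelity, and
misincorporation claims are only informative at A/C/U positions. Codon
fidelity is the *minimum* per-position reference fraction over the three
positions: a conservative summary, slightly below the per-position
fidelity by construction (at per-position depth $10^4$ and a 0.2%
per-base error, the minimum of three binomial draws sits a fraction of a
standard error below 99.8%). Coordinates are 0-based half-open
throughout.

## Ribosome-profiling metagene

Editing rates are estimated per site from mRNA-seq base counts as
`g/(a+g)`. Sites with no informative reads are dropped; a configurable
minimum-depth guard (default 10 informative reads) is an extension added
for statistical sanity. A site is *edited* as soon as any edited read is
observed (rate > 0).

The metagene pipeline then:

1. excludes transcripts with two or more sites within ±5 nt of each other
   (a site at distance 6 is retained) so neighbouring sites cannot
   contaminate the aligned window;
2. resolves each site to one CDS — the longest, ties broken
   lexicographically by transcript id;
3. normalizes each site's coverage by the total signal within ±500 nt
   (±1000 nt for the codon-position-split analysis), masking positions
   beyond the transcript ends as missing rather than zero — zero-filling
   would fabricate a dip at transcript edges;
4. averages across sites, weighting each edited site by its editing rate.

The weighted mean divides by the sum of weights, not by the number of
sites, so a rate-0 site is a no-op; this matches the intent of giving
higher impact to more highly edited sites, and the unweighted mode (used
for the unedited control group) is the same code path with unit weights.
Display and normalization windows are independent parameters (a ±125 nt
display over a ±500 nt normalization is the default view). No P-site
offsetting or read-length selection is applied: the analysis aggregates
raw coverage.

The codon-position split assigns each in-CDS site
`1 + (pos - cds_start) mod 3` and recomputes the metagene per position
with the stated overrides (no neighbor filtering, ±1000 nt
normalization).

## Synthetic data: what it emulates, and what it does not

All generators are pure functions of their arguments and seed.

* **MS tables**: true decoding fractions and truncation are converted to
  species abundances; intensities are abundance × log-normal response
  factor (sdlog 0.3 around 1, the detectability bias the concatemers
  exist to correct) × mean-1 log-normal noise (CV 0.1 by default,
  typical for extracted-ion intensities). Standards are equimolar ×
  factor × noise.
* **Amplicon reads**: uniformly positioned, i.i.d. substitution errors at
  a uniform per-base rate, inosine emitted as G. No quality-score error
  model, no indels, no PCR duplicates.
* **Ribo-seq**: Poisson coverage (mean 5–8 per nt in the shipped
  analyses); at an edited site the Poisson mean over the site's codon ±1
  codon (9 nt) is scaled by `1 - rate·(1 - d)` — the fully edited
  molecules are covered at `d` times baseline, the unedited fraction is
  untouched, which is what makes editing-rate weighting the right
  estimator. Site editing rates are Beta-distributed (Beta(2, 2) by
  default) to exercise the weighting path. An optional exponential
  upstream queueing bump exists (disomes piling up behind a stall) but
  defaults off so the null stays clean.

These generators reproduce the statistical structure the analysis
*assumes*, not real data: no sequence-dependent MS detectability, no
ADAR neighbour-preference in site placement, no codon-specific elongation
rates, uniform coverage baseline. Passing recovery tests therefore
demonstrates correctness of the estimators under the stated model, not
robustness to everything real libraries do.

## Problem sizes and numerical choices

The shipped analyses use deliberately moderate simulation sizes — 5
repeated MS experiments of 3 replicates, amplicon depth $10^4$, 100–150
transcripts of 2000–2500 nt for the metagene — chosen so each recovery
quantity carries roughly 3-sigma margin against its tolerance while the
whole suite runs in seconds. Dip recovery is estimated as the profile
mean over relative positions |p| ≤ 3 (always inside the 9-nt stall
window whatever the codon frame) divided by the baseline mean over
|p| > 8; the ±500 nt normalization inflates this estimate by under 1%
for the dip depths used. Ties, degenerate inputs (empty read sets,
zero-signal windows, zero-depth sites) and error conditions are handled
explicitly and exercised in the test suite.

## Known limitations

* The amino-acid readout cannot resolve synonymous decodings; wobble
  codons are classified but yield no decoding measurement.
* Drop-off and premature termination give the same peptide; the
  truncation percentage aggregates both mechanisms.
* Amplicon fidelity cannot decompose sequencing error from transcription
  infidelity; the module reports rates only.
* The metagene operates on transcript-projected coverage; genome-to-
  transcript projection beyond a simple exon table, multimapper handling
  and mapping itself are out of scope.
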