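---
title: "Genome similarity codes: model, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Genome similarity codes: model, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(anicode)
```

## The problem

Below the species level there is no general, stable way to name organisms.
Sequence-typing schemes cover single species at a single resolution, and
phylogeny-derived names must be revised whenever new relatives are
sequenced. `anicode` implements an alternative: a hierarchical code assigned
to each genome from nothing but its measured similarity to previously coded
genomes. Because a genome's code depends only on the database state at its
registration, codes are permanent, and because each code position is tied to
a fixed similarity threshold, the depth of the shared prefix between two
codes is directly interpretable as a similarity statement.

## Fragment-based ANI

For an ordered pair (query, subject) the package computes the BLAST-style
fragment ANI ("ANIb"):

1. every query contig is cut into consecutive, non-overlapping fragments of
   `fragment_length` bp (default 1020 bp; the trailing window of a contig is
   kept and judged against its own length);
2. each fragment is aligned to the subject (both strands, every contig) and
   only its single best local alignment is considered;
3. a fragment passes when the alignment covers at least `coverage_min`
   (default 0.70) of the fragment length *and* its identity is at least
   `identity_min` percent (default 30) — both comparisons inclusive;
4. `ani_pct` is the arithmetic mean of the passed fragments' identities;
   `pct_aligned_fragments` is 100 × passed / total fragments.

Identity is defined as identical aligned bases over alignment columns
(matches + mismatches + gap columns), and an `N` never counts as a match,
not even against another `N`. When no fragment passes, the ANI is undefined
and reported as `NA`. The measure is intentionally one-directional — the
new genome is always the query — and no reciprocal averaging is done.

Note that ANI weights fragments, not sites: a short trailing fragment
contributes as much as a full one, so ANI can differ by a few hundredths of
a point from genome-wide identity. This is inherent to the fragment
recipe, not an artifact.

### Alignment backends

* `exact` (default): an exact Smith–Waterman local aligner (linear gap
  penalty; scores `match = 2`, `mismatch = -3`, `gap = 5`). Quadratic in
  subject length, intended for genomes up to a few tens of kb. Ties in
  score are broken deterministically: lower subject contig index, lower
  subject start, forward strand first.
* `seed`: exact k-mer seeds (default `seed_k = 13`) propose diagonals, each
  candidate diagonal is scored ungapped over the full fragment overlap, and
  the best diagonal wins. On substitution-only divergence this reproduces
  the true positional identity exactly and runs in roughly linear time,
  which is what makes hundred-kb all-against-all studies desk-scale. Its
  assumptions fail for indel-rich or very low-identity homology (an exact
  k-mer must survive; below ~60–65% identity seeds become rare), where it
  degrades to "no hit" rather than to a wrong alignment.
* `blast`: external `blastn` with the classical ANIb parameterization
  (reward 1, penalty −5, dust off, e-value 1e−15). Useful for parity runs
  against published ANIb values; identity then uses BLAST's own conventions.

The test suite checks the `exact` backend against an independent
local-alignment oracle built on `Biostrings::pairwiseAlignment` with the
same scoring, requiring agreement within 0.5 identity points on at least
95% of random fragments; exact agreement is not required because co-optimal
local alignments can differ in identity.

### The core-genome filter

Horizontally transferred regions depress ANI between closely related
genomes because their identity reflects the donor, not vertical descent.
With `core_filter = TRUE`, the passed fragment identities are restricted to
a window of ± `core_filter_halfwidth` (default 0.1) percentage points
around their median before averaging. The median of the passed identities
estimates the vertical bulk robustly as long as transferred fragments are a
minority; fragments from divergent donors fall far outside the window and
are discarded. `pct_aligned_fragments` is always computed before this
filter. Degenerate inputs are handled conservatively: the window always
retains the median-attaining values, and if (as possible for two-point
bimodal inputs) nothing lies within the window, the input is returned
unfiltered with a fallback flag rather than producing an empty set. The
published wording for the window ("a 0.1 interval of the median") is
ambiguous between half-width and total width; the package uses half-width
0.1 and exposes the knob, so total-width-0.1 is `core_filter_halfwidth =
0.05`.

## Code assignment

The default threshold table has 24 positions:

```{r}
default_threshold_table()
```

Intervals shrink to the right: the deep positions (V–X, up to 99.9999%)
resolve near-identical isolates, which is the regime where a naming system
is most needed. Position F (95%) approximates the classical species
boundary of 70% DNA–DNA hybridization.

Rules, in the package's formulation:

* **First genome**: all positions 0.
* **Anchor choice**: among registered subjects with
  `pct_aligned_fragments >= trust_min_pct_aligned` (default 20%), the
  highest-ANI subject; the ≥ 20% set takes precedence even when a
  low-coverage subject shows a higher ANI, because ANI computed from few
  fragments carries little signal. If no subject reaches 20%, the overall
  highest-ANI subject is recorded but *not trusted*.
* **Trusted walk**: copy the anchor's value at each position whose
  threshold the ANI *strictly* exceeds; at the first position not exceeded,
  assign the sibling-scoped next value and 0 to every later position. An
  ANI above all 24 thresholds copies the anchor's code entirely — code
  collisions between near-identical genomes are legitimate, and uniqueness
  is enforced on genomes (by content checksum), not on codes.
* **Untrusted**: fresh value at position A, 0 elsewhere (a new lineage).

"Next value" is scoped to *code siblings*: 1 + the maximum value at that
position among entries matching the new code at every position to the left,
or 0 when no such sibling exists. This scope reproduces sequential
numbering within each group (0, 1, 2, … per sibling group) without
collisions and without skipping values, which a "global maximum + 1" rule
would cause. Sub-choices the published rules leave open were fixed as
follows: a genome exactly at a threshold does **not** share that position
(strict `>`); ANI ties in anchor choice resolve to the earlier-registered
genome; an undefined ANI is treated as untrusted; duplicate submissions
(identical sequence content by checksum) are rejected with the existing
entry rather than assigned a second code.

The prefix/ANI coupling is exact by construction: immediately after a
trusted assignment, the last shared position between the new code and its
anchor equals the number of thresholds strictly exceeded by the measured
ANI. That invariant is asserted in the tests.

## The simulator

`simulate_clade()` generates the fixtures every other module is tested
against. Branch lengths of the supplied tree are per-site substitution
probabilities; each site mutates independently per branch and a mutated base
is drawn uniformly from the three alternatives. For two leaves connected by
branches with probabilities \(p_b\), the expected per-site identity is

\[ \Pr(\text{same}) \;=\; \tfrac14 + \tfrac34 \prod_b \left(1 - \tfrac{4 p_b}{3}\right), \]

which `expected_identity()` evaluates and the tests cross-check by
Monte-Carlo. Optional horizontal-transfer events replace a segment of a
recipient leaf with a divergent copy of the corresponding root segment;
optional short indels (1–10 bp) default off so that leaf coordinates remain
directly comparable. Every event is recorded in a ledger whose replay
reproduces each leaf exactly; `ledger_fragment_identity()` turns the ledger
into an aligner-free oracle for per-fragment identity.

What the simulator deliberately does *not* model: rate heterogeneity,
GC/compositional bias, repeats, rearrangement, gene content differences,
recombination beyond single-segment HGT, and sequencing error. Passing
tests on simulated clades therefore demonstrate that the classification
machinery is correct under its own model assumptions — clean substitution
divergence with known ground truth — not that ANI estimation is robust to
every property of real assemblies.

## Problem sizes and study conditions in the test suite

The clade-recovery and order-robustness checks use a 12-genome clade
(3 clades × 2 subclades × 2 leaves) on a 102000 bp root — an exact multiple
of the fragment length, so every fragment is full-width — with expected
identity tiers of about 92% between clades, 99.65% within clades and 99.95%
within subclades, i.e. tiers straddling the 95%, 99.5% and 99.9%
thresholds. Clade recovery is asserted as adjusted Rand index 1.0 between
prefix groups (positions F and M) and the simulated groups under 10 random
assignment orders; order robustness runs 100 random orders and summarizes,
per genome pair, deviation of the last shared position from its modal
value. Because the registration order only matters through which genome is
*first* of its neighbourhood, strongly tiered clades are expected to shift
by at most one position; the report flags any pair exceeding that rather
than silently failing. The core-filter check splices a 10200 bp segment at
30% donor divergence into one genome of a ~99.9%-identical pair and
requires the core-filtered ANI to sit within 0.05 points of the
ledger-derived vertical identity. All similarity computations in these
studies go through a content-addressed cache (query checksum, subject
checksum, configuration digest), so 100 orders cost no more alignment work
than one all-against-all pass.

## Known limitations

* ANI is meaningful only down to roughly the 60–70% identity floor of
  nucleotide alignment; genomes that cannot be aligned share no code
  positions by design, and protein-level similarity for deeper positions is
  out of scope.
* The `seed` backend assumes gap-free homology; use `exact` or `blast` for
  indel-rich comparisons.
* The `exact` backend is quadratic per fragment–subject pair; for full-size
  bacterial genomes use `seed` or `blast`.
* A registry is a sequential data structure: codes depend on registration
  order by design (that is what the permutation study quantifies), so two
  independently grown registries are not comparable — codes are only
  meaningful relative to one registry.
* Plasmid gain/loss, heavy recombination, or low assembly quality shift
  measured ANI and therefore codes; the core filter mitigates localized
  transfer but cannot rescue genome-wide recombination.
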