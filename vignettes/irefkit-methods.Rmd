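---
title: "Consolidated interaction data: redundancy, n-ary representation and degree distributions"
author: "irefkit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Consolidated interaction data: redundancy, n-ary representation and degree distributions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(irefkit)
```

## The problem this package addresses

Public protein–protein interaction databases overlap heavily and disagree in
how they represent the same experimental evidence.  Consolidated resources
distribute a single tab-delimited file (PSI-MI MITAB 2.6, in the iRefIndex
dialect) in which every interactor carries a sequence/taxon digest key — the
ROGID — and every record a key over its participants' ROGIDs — the RIGID —
so that records from different source databases describing the same
molecules can be recognized as redundant.  A second, *canonical* key pair
(cROGID/cRIGID) additionally merges related sequence variants (isoforms of
one gene) under one representative.

Three record shapes coexist in one file: binary records (`X`; A interacts
with B), n-ary records (`C`; three or more proteins observed together, e.g.
a co-purified complex, distributed as *bipartite* rows linking each member
to a group pseudo-node), and polymer records (`Y`; several copies of one
molecule).  None of the analyses usually run on such data — network
construction, degree statistics, power-law fitting — are well defined until
the analyst has decided (i) at which redundancy level proteins are
identified and (ii) how n-ary evidence is expanded into edges.  irefkit
makes those decisions explicit parameters of every conversion.

## N-ary expansion policies

For a complex with $m$ distinct members the three graphical expansions are:

* **spoke** — edges from one hub to each other member, $m-1$ edges.  The hub
  is the experimental bait when the group has exactly one bait-annotated
  member; otherwise the bytewise-smallest member key is used, a deterministic
  fallback chosen over any heuristic so that repeated runs (and reordered
  inputs) give identical graphs.
* **matrix** — all $\binom{m}{2} = m(m-1)/2$ pairwise edges.  Matrix edges
  carry no direction semantics; requesting a directed matrix expansion is an
  error rather than a silent guess.
* **bipartite** — $m$ edges from a pseudo-node named `complex:<RIGID>` to the
  members; collision-free and exactly invertible.

Edge weights count the distinct source records supporting a pair, with a
whole n-ary group counting as one record; weighting by distinct supporting
publications is available (`weight_by = "pmids"`) because either convention
is defensible and the choice visibly changes weights on consolidated data.
Undirected edges are stored with `node_a <= node_b` (bytewise) and self
loops are excluded by default; polymers only ever enter as opt-in self
loops.  In directed mode, records without bait/prey roles are dropped by
default — a directed graph should show direction that was actually observed
— or kept as flagged unoriented rows (`rolefree = "undirected"`).

## Spoke-represented ("regenerated") complexes

Some source databases curate co-purification experiments as stars of binary
bait–prey records.  `regenerate_complexes()` folds such stars back into
n-ary records using three criteria: the records share (1) source database
and publication, (2) a detection method known to produce n-ary data
(`default_nary_methods()`: affinity chromatography and its
coimmunoprecipitation / pull-down / tandem-affinity relatives), and (3) one
common protein, the hub.  With bait roles present, one complex is formed
per bait; without them, a greedy search repeatedly takes the most frequent
protein of a group as hub and consumes its records, so each record supports
at most one complex.  Records citing several publications are excluded from
grouping — a record reused across papers cannot be attributed to one
experiment without double counting.  Complexes below three members are
discarded (the defining size of n-ary evidence).  The conservative preset
restricts input to BioGRID records with MI:0004 (affinity chromatography),
the combination that dominates spoke-represented curation practice.

Small regenerated complexes can be false positives — genuinely independent
binary observations that happen to share a protein, paper and method; the
package deliberately attaches no confidence score and leaves confirmation
to inspection of the underlying publication.

## Bibliometric scores and throughput

For a distinct interaction (RIGID) with supporting publication set $P$ and
$\mathrm{reuse}(p)$ = number of distinct interactions publication $p$
supports anywhere in the table:

$$np = |P|, \qquad lpr = \min_{p \in P} \mathrm{reuse}(p), \qquad
hpr = \max_{p \in P} \mathrm{reuse}(p).$$

$lpr = 1$ means some supporting paper supports nothing else — a
low-throughput signature; large $lpr$ means every supporting paper is a
screen.  The conventional low/high cut (low: $lpr \le 21$) is a parameter
everywhere it appears, since it is a release-specific convention rather
than a property of the scores.  Scores are recomputed from the table in
hand by default: the values shipped in a release's `confidence` column
reflect reuse across the *whole* release, which is a different (equally
legitimate) view of a subset; `recompute = FALSE` trusts the file instead.
A regenerated complex is classed low-throughput when all of its scored
supporting records satisfy the cut, high otherwise, and unknown when none
is scored — the complex-level rule is not fixed by convention, so it is
documented here and parameterized.

Degree summaries report the population variance (divide by $n$): the node
set is the entire population of the graph under study, not a sample from a
larger one.  Directed graphs are summarized by total degree.

## Discrete power-law fitting

Degrees are integers, so the discrete model
$P(X = x) = x^{-\alpha} / \zeta(\alpha, x_{\min})$ is the default (the
continuous approximation is common in older scripts but biases $\alpha$ at
small $x_{\min}$).  The Hurwitz zeta is evaluated by Euler–Maclaurin
summation; no installed package provides it, and the implementation is
checked in the tests against direct summation and the Riemann special case.
For each candidate $x_{\min}$ among the observed values (with at least
`min_tail = 10` tail points) the exponent maximizes the tail log-likelihood
by golden-section search over $(1.01, 6)$ — the likelihood is smooth and
unimodal, and a bounded derivative-free search is deterministic.  The
reported fit minimizes the KS distance between empirical and model tail
CDFs; KS ties go to the smaller $x_{\min}$, keeping more data.

Goodness of fit uses a semiparametric bootstrap: each replicate draws from
the fitted tail model with probability $n_{\mathrm{tail}}/n$ and otherwise
uniformly from the observed sub-$x_{\min}$ values, is refitted from
scratch, and contributes its KS distance; $p$ is the fraction reaching the
observed distance, and $p < 0.1$ rejects the power law.  Defaults are
$B = 1000$ for reported values and $B = 100$ inside the test suite; seeds
are recorded in the fit object.  Tail sampling inverts the exact discrete
CDF through a lookup table covering all but $\sim 10^{-6}$ of the mass,
with integer bisection on the exact survival function for rarer draws.

Two behaviours of this estimator are worth knowing.  On true power-law
samples it is accurate and well calibrated: over twenty 5000-draw samples
with $\alpha = 2.5$, $x_{\min} = 5$, the suite observes mean
$|\hat\alpha - \alpha| \approx 0.02$ and bootstrap $p \ge 0.1$ throughout.
Against exponential-tailed alternatives its power is real but limited: the
KS-optimal $x_{\min}$ scan is free to crop a geometric sample to its
extreme tail, where an exponent at the upper search bound mimics the decay
over the short remaining range, and since the bootstrap is calibrated
against that same cropped model, a substantial minority of geometric
samples (roughly a third to a half at $n = 10^4$, across geometric
parameters) receives $p \ge 0.1$.  A cross-check of this implementation
against an independently written one reproduced the same fits and
p-values, so this is a property of the method, not of the code.  The
practical reading, which also applies to published applications of the
procedure: $p \ge 0.1$ supports only "a power law cannot be rejected",
never "the tail is a power law" — a caveat the fit object's `plausible`
verdict wording preserves.  Likelihood-ratio comparison against competing
tail models is deliberately out of scope.

## The synthetic generator

All tests run against `generate_mitab()`, which plants every structure the
analyses consume and writes an exact manifest: a pool of 40 main-organism
proteins (plus 4 foreign ones), 90 background binary records of which two
blocks of 25 come from single screen publications (their recomputed
$lpr = 25$ falls on the high-throughput side of the conventional cut) and
the remainder from single-use papers (with 10% given a second paper, so
$np = 2$ occurs), five reported complexes of sizes 3–8 distributed as
bipartite `C` rows, three polymers, three planted spoke-represented
complexes (sizes 4–6; two from BioGRID, one from MINT; affinity
chromatography; one fresh publication each), three isoform groups of sizes
3/2/2 sharing canonical keys, and 10% interspecies records.  Background
binary records use methods outside `default_nary_methods()`, so under the
default settings the planted spoke complexes are exactly the regenerable
structures — fixtures for confounded regeneration are built separately in
the tests.  All keys are computed with `compute_rogid()`/`compute_rigid()`
(SEGUID-style SHA-1 digests), so file-supplied and recomputed keys agree by
construction.

One integer seed drives everything through fixed per-phase substreams;
the same seed yields a byte-identical file and manifest, and enlarging one
record class does not shift another class's draws.  What the generator does
**not** emulate: the marginal distributions of any real release (organism
sizes, database shares, true degree distributions), annotation noise
(conflicting taxon assignments, malformed accessions beyond what the
lenient parser tests construct), or biologically structured overlap between
complexes.  Tests passing on these fixtures therefore certify the
*bookkeeping* — parsing, key handling, grouping, counting, expansion — and
the statistical machinery on known ground truth, not fidelity to any
particular release.

## Numerical and interface choices

* Parsing keeps every cell verbatim; "-" and the empty string both read as
  absent, and serialization always writes "-", so read/write round-trips
  are byte-stable.  Strict mode (library default) raises on malformed
  lines; lenient mode (CLI default) skips and counts them, matching how
  real dumps are consumed.
* The column dialect registry accepts any header containing the required
  iRefIndex columns and carries unknown extra columns through unchanged,
  because released headers have grown over versions.
* Selections never mutate records, preserve order, and treat `C` groups as
  units: a complex matches (or is excluded) whole, since a partial complex
  is meaningless downstream.
* All set orderings and tie-breaks use bytewise (`radix`) comparisons, so
  results are independent of the session locale.
* `compute_rogid()` appends the taxon id to the base64 SHA-1 digest of the
  uppercased sequence; keys are recomputed only for verification and for
  fixture construction — file-supplied keys always win on real data.

## Problem sizes in the test suite

The suite works at deliberately small scale: default fixtures of ~130
records, 100 random tables of at most 50 binary records for the
regeneration oracle, 50 tables for the score oracle, and, for the
power-law machinery, twenty 5000-draw power-law samples and twenty
10000-draw geometric samples with $B = 100$ bootstrap replicates.  These
sizes are where the exhaustive oracles remain exact and fast; all
statistical conclusions above were measured at exactly these conditions.
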