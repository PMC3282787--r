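# irefkit

Tools for consolidated protein–protein interaction data distributed in the
iRefIndex dialect of PSI-MI MITAB 2.6 — the tab-delimited format in which
interaction records from BIND, BioGRID, CORUM, DIP, HPRD, IntAct, MINT and
others are merged into one file with redundancy keys.

The package is for network biologists who build interactomes from such
files and need the two decisions that silently shape every downstream
statistic to be explicit and reproducible:

1. **Redundancy level.** Each interactor carries a ROGID (a SEGUID-style
   SHA-1 digest of its sequence plus taxon) and a canonical cROGID shared by
   isoforms of one gene; each record a RIGID/cRIGID over its participants.
   Counting proteins or interactions at the sequence-specific versus the
   canonical level gives different networks.
2. **N-ary representation.** Records listing *m* ≥ 3 co-purified proteins
   can be expanded as *spoke* (bait-to-member, *m* − 1 edges), *matrix*
   (all pairs, *m*(*m* − 1)/2 edges), *bipartite* (member-to-pseudo-node,
   *m* edges), or excluded — each choice changes degree distributions.

On top of the MITAB reader/writer and the pure selection operators (by
interaction type, source database, protein, publication, method, taxon and
bibliometric score range), irefkit provides:

* conversion among MITAB, complexList, edgeList and igraph representations,
  exactly invertible, with explicit expansion policy / id level /
  directionality / weighting;
* detection of **spoke-represented complexes** hidden in binary data:
  groups of binary records from one database, one publication and one
  n-ary-producing method that share a hub protein (the bait when known) are
  folded back into "regenerated" n-ary records, with a conservative
  BioGRID + MI:0004 preset;
* **bibliometric scores** per distinct interaction — np (supporting
  publications), lpr and hpr (least/most reuse of any supporting
  publication across interactions) — and the low/high-throughput partition
  at the conventional lpr ≤ 21 cut;
* **discrete power-law fitting** of degree distributions: maximum-likelihood
  exponent with Hurwitz-zeta normalization, KS-minimizing xmin, and a
  semiparametric bootstrap goodness-of-fit test (p < 0.1 rejects);
* a deterministic **synthetic-fixture generator** with a complete
  ground-truth manifest, so the whole pipeline is testable offline.

## Worked example

```r
library(irefkit)

fx  <- generate_mitab(seed = 42)   # synthetic table + ground-truth manifest
tab <- fx$table
tab
#> <mitab_table> 131 records (irefindex_8.0 dialect): 102 binary, 26 complex (5 groups), 3 polymer

summary_table(tab, taxid = 4932)$distinct_proteins
#> rogid cROGID counts: 43 39        # canonicalization merges isoform groups

rg <- regenerate_complexes(tab, default_nary_methods())
as.data.frame(rg)[, c("complex_id", "size", "source_db", "method", "throughput")]
#>   complex_id size source_db  method throughput
#> 1 regen_0001    4   biogrid MI:0004        low
#> 2 regen_0002    5   biogrid MI:0004        low
#> 3 regen_0003    6      mint MI:0004        low

e <- mitab_to_edgelist(tab, nary_policy = "spoke", id_level = "crogid")
e
#> <edge_list> 110 edges, 39 nodes (crogid, spoke n-ary policy, undirected)
unlist(summary_graph(edgelist_to_graph(e), mitab = tab))
#>    n      I      X    C   dav    dvar  dmax
#>   39    103     95    5  5.64   13.05    22

deg <- sample_discrete_powerlaw(alpha = 2.5, xmin = 5, n = 5000, seed = 42)
fit <- bootstrap_pvalue(deg, fit_discrete_powerlaw(deg), B = 100, seed = 43)
fit
#> Discrete power-law fit: alpha = 2.479, xmin = 5, ntail = 5000, KS D = 0.0054
#> Bootstrap GOF: p = 0.830 (B = 100, seed = 43) -> power law plausible
```

Reading the numbers: the 26 complex member rows group into 5 reported
complexes; the 3 planted spoke-represented complexes are recovered from the
binary records with their sizes, sources and low-throughput support intact;
expanding complexes as spokes at the canonical level yields a 39-node graph
whose mean degree (5.64) would rise under the matrix policy; and the
fitted exponent of a known power-law sample is recovered (2.48 vs 2.5) with
a bootstrap p-value far above the 0.1 rejection line.

For real data, `fetch_irefindex()` downloads a release file, `read_mitab()`
parses it (gzip/zip transparent, lenient mode for malformed lines), and
`scripts/reproduce.R` re-runs the release-scale analyses — organism
summaries, regenerated-complex statistics, throughput breakdown,
per-database power-law verdicts — against it.

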