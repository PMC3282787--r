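#!/usr/bin/env Rscript

# Regenerates the release-scale analyses (organism summary tables, complex
# regeneration statistics, throughput breakdown, per-database power-law
# fits) from a locally stored iRefIndex MITAB 2.6 release file.  Download
# one first, e.g.
#
#   Rscript -e 'irefkit::fetch_irefindex("8.0", 4932, "yeast.mitab.txt")'
#   Rscript scripts/reproduce.R yeast.mitab.txt 4932
#
# This script needs a real release file and is NOT part of the test suite;
# nothing in the package's tests or acceptance run depends on it.

suppressPackageStartupMessages(library(irefkit))

args <- commandArgs(trailingOnly = TRUE)
if (length(args) < 1)
  stop("usage: Rscript scripts/reproduce.R <release.mitab[.gz]> [taxid]")
path <- args[1]
taxid <- if (length(args) > 1) as.integer(args[2]) else NULL

t <- read_mitab(path, mode = "lenient")
cat(sprintf("parsed %d records (%d malformed lines skipped)\n",
            nrow(t), attr(t, "meta")$skipped))

## organism/table summary (distinct proteins and interactions at both
## redundancy levels; intra- vs inter-species scoping)
s <- summary_table(t, taxid = taxid)
str(s, max.level = 2)

## regenerated complexes, permissive and conservative
rg <- regenerate_complexes(t, default_nary_methods(), require_bait = FALSE)
cons <- conservative_preset(t)
cl <- mitab_to_complexlist(t, "rogid", "no")
cat(sprintf("reported complexes: %d, regenerated: %d, conservative: %d\n",
            nrow(cl), nrow(rg), nrow(cons)))
if (nrow(cl) && nrow(rg)) {
  ks <- compare_size_distributions(cl, rg)
  cat(sprintf("size-distribution KS: D = %.3f, p = %.3g\n", ks$D,
              ks$p_value))
}

## throughput breakdown of binary records
bi <- select_interaction_type(t, "binary")
parts <- classify_throughput(bi)
scored <- nrow(parts$low) + nrow(parts$high)
cat(sprintf("binary records: %.1f%% low-throughput (lpr <= 21) of %d scored\n",
            100 * nrow(parts$low) / scored, scored))

## network properties under the spoke representation
g <- edgelist_to_graph(mitab_to_edgelist(t, "spoke", "crogid"))
print(unlist(summary_graph(g, mitab = t)))

## per-database degree distributions and power-law verdicts
for (db in names(sort(table(mitab_source_labels(t)), decreasing = TRUE))) {
  sub <- suppressMessages(select_database(t, db))
  e <- mitab_to_edgelist(sub, "spoke", "crogid")
  if (!nrow(e)) next
  deg <- igraph::degree(edgelist_to_graph(e))
  f <- tryCatch({
    f0 <- fit_discrete_powerlaw(as.integer(deg))
    bootstrap_pvalue(as.integer(deg), f0, B = 1000, seed = 42)
  }, error = function(e) NULL)
  if (is.null(f)) next
  cat(sprintf("%-10s n=%6d dmax=%5d xmin=%4d alpha=%.2f ntail=%5d p=%.2f %s\n",
              db, length(deg), max(deg), f$xmin, f$alpha, f$ntail,
              f$p_value, f$verdict))
}
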