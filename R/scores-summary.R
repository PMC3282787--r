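# Bibliometric scores (np / lpr / hpr) and descriptive summaries.
#
# For a distinct interaction (RIGID) supported by the publication set P:
#   np  = |P|, the number of distinct supporting publications;
#   lpr = min over p in P of reuse(p), hpr = max over p in P of reuse(p),
# where reuse(p) is the number of distinct interactions publication p is
# used to support anywhere in the table.  lpr = 1 means some supporting
# paper supports nothing else (a low-throughput signature); a large lpr
# means every supporting paper is a screen.

#' Compute bibliometric scores for every interaction
#'
#' Scores are computed over the table as given: a subset's scores legitimately
#' differ from the release-wide values shipped in the `confidence` column
#' (those reflect reuse across the whole release).  Records without
#' publications contribute nothing and receive no row.
#'
#' @param t A `mitab_table`.
#' @return A `score_table` data frame with columns `rigid`, `np`, `lpr`,
#'   `hpr`, sorted by `rigid`.
#' @export
compute_bibliometric_scores <- function(t) {
  rid <- mitab_rigids(t)
  pms <- mitab_pmids(t)
  keep <- which(!is.na(rid) & lengths(pms) > 0)
  empty <- data.frame(rigid = character(0), np = integer(0),
                      lpr = integer(0), hpr = integer(0),
                      stringsAsFactors = FALSE)
  class(empty) <- c("score_table", "data.frame")
  if (!length(keep)) return(empty)
  pairs <- unique(data.frame(
    rigid = rep(rid[keep], lengths(pms[keep])),
    pmid = unlist(pms[keep]),
    stringsAsFactors = FALSE))
  reuse <- table(pairs$pmid)
  r <- as.integer(reuse[as.character(pairs$pmid)])
  out <- data.frame(
    rigid = sort(unique(pairs$rigid), method = "radix"),
    stringsAsFactors = FALSE)
  np <- tapply(pairs$pmid, pairs$rigid, length)
  lpr <- tapply(r, pairs$rigid, min)
  hpr <- tapply(r, pairs$rigid, max)
  out$np <- as.integer(np[out$rigid])
  out$lpr <- as.integer(lpr[out$rigid])
  out$hpr <- as.integer(hpr[out$rigid])
  class(out) <- c("score_table", "data.frame")
  out
}

#' Partition records into low- and high-throughput
#'
#' Low-throughput records have a (recomputed) lpr score of at most
#' `threshold`; the conventional release cut of lpr < 22 corresponds to the
#' default `threshold = 21`.  Records without publications cannot be scored
#' and are returned separately.
#'
#' @param t A `mitab_table`.
#' @param threshold Integer lpr boundary (inclusive on the low side).
#' @param recompute Recompute lpr from `t` (default) or use the
#'   file-supplied confidence column.
#' @return List of three `mitab_table`s: `low`, `high`, `unscored`.
#' @export
classify_throughput <- function(t, threshold = 21, recompute = TRUE) {
  lpr <- if (recompute) {
    st <- compute_bibliometric_scores(t)
    st$lpr[match(mitab_rigids(t), st$rigid)]
  } else mitab_confidence_scores(t, "lpr")
  list(low = .subset_rows(t, !is.na(lpr) & lpr <= threshold),
       high = .subset_rows(t, !is.na(lpr) & lpr > threshold),
       unscored = .subset_rows(t, is.na(lpr)))
}

#' Summary statistics for a MITAB table
#'
#' Record counts by interaction type and source database, distinct protein
#' and interaction counts at both redundancy levels, and (when a taxon is
#' given) the size of the at-least-one-interactor versus all-interactors
#' species scopes.
#'
#' @param t A `mitab_table`.
#' @param taxid Optional NCBI taxon id for the species breakdown.
#' @return Named list of counts.
#' @export
summary_table <- function(t, taxid = NULL) {
  cls <- classify_record(t)
  bydb <- table(mitab_source_labels(t))
  out <- list(
    n_records = nrow(t),
    records_by_type = c(binary = sum(cls == "binary"),
                        complex = sum(cls == "complex"),
                        polymer = sum(cls == "polymer")),
    records_by_db = stats::setNames(as.integer(bydb), names(bydb)),
    n_complex_groups = length(.complex_groups(t)),
    distinct_proteins = c(
      rogid = length(distinct_proteins(t, "rogid")),
      crogid = length(distinct_proteins(t, "crogid"))),
    distinct_interactions = c(
      rigid = length(distinct_interactions(t, "rigid")),
      crigid = length(distinct_interactions(t, "crigid"))),
    n_pmids = length(unique(unlist(mitab_pmids(t)))))
  if (!is.null(taxid)) {
    any_t <- select_taxon(t, taxid, "at_least_one")
    all_t <- select_taxon(t, taxid, "all_interactors")
    out$taxon <- list(
      taxid = taxid,
      at_least_one = c(records = nrow(any_t),
                       proteins_crogid = length(distinct_proteins(any_t, "crogid")),
                       interactions_crigid = length(distinct_interactions(any_t, "crigid"))),
      all_interactors = c(records = nrow(all_t),
                          proteins_crogid = length(distinct_proteins(all_t, "crogid")),
                          interactions_crigid = length(distinct_interactions(all_t, "crigid"))))
  }
  out
}

#' Summary statistics for one protein
#'
#' @param t A `mitab_table`.
#' @param id A ROGID or cROGID.
#' @param id_level "rogid" or "crogid".
#' @return Named list: record count, distinct binary partners, complexes
#'   containing the protein, supporting publications, source databases.
#' @export
summary_protein <- function(t, id, id_level = c("rogid", "crogid")) {
  id_level <- match.arg(id_level)
  sub <- select_protein(t, id, id_level)
  cls <- classify_record(sub)
  ka <- interactor_keys(sub, "a", id_level)
  kb <- interactor_keys(sub, "b", id_level)
  bin <- cls == "binary"
  partners <- c(kb[bin & !is.na(ka) & ka == id],
                ka[bin & !is.na(kb) & kb == id])
  partners <- setdiff(unique(partners[!is.na(partners)]), id)
  rlevel <- if (id_level == "rogid") "rigid" else "crigid"
  list(id = id,
       n_records = nrow(sub),
       n_partners = length(partners),
       partners = sort(partners, method = "radix"),
       n_complexes = length(unique(mitab_rigids(sub, rlevel)[cls == "complex"])),
       pmids = sort(unique(unlist(mitab_pmids(sub)))),
       source_dbs = sort(unique(stats::na.omit(mitab_source_labels(sub)))))
}

#' Degree summary of a graph
#'
#' Node count, mean/variance/maximum of the degree distribution (total
#' degree for directed graphs; the variance is the population variance), and
#' - when the originating MITAB table is supplied - the distinct interaction
#' (I), binary (X) and complex (C) counts behind the graph.
#'
#' @param g An `igraph` graph.
#' @param mitab Optional `mitab_table` the graph was derived from.
#' @return Named list `n`, `I`, `X`, `C`, `dav`, `dvar`, `dmax`.
#' @export
summary_graph <- function(g, mitab = NULL) {
  deg <- igraph::degree(g, mode = "total")
  n <- igraph::vcount(g)
  out <- list(n = n, I = NA_integer_, X = NA_integer_, C = NA_integer_,
              dav = if (n) mean(deg) else NA_real_,
              dvar = if (n) mean((deg - mean(deg))^2) else NA_real_,
              dmax = if (n) max(deg) else NA_real_)
  if (!is.null(mitab)) {
    lvl <- igraph::graph_attr(g, "id_level") %||% "rogid"
    rlevel <- if (lvl == "rogid") "rigid" else "crigid"
    cls <- classify_record(mitab)
    rid <- mitab_rigids(mitab, rlevel)
    out$I <- length(unique(stats::na.omit(rid)))
    out$X <- length(unique(stats::na.omit(rid[cls == "binary"])))
    out$C <- length(unique(stats::na.omit(rid[cls == "complex"])))
  }
  out
}
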