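# Pure filtering operators.  Every selector returns a sub-table of its input
# (records untouched, original order preserved) and is idempotent; complex
# (C) records are always kept or dropped as whole groups where membership
# criteria apply, since a partial complex is meaningless downstream.

.db_alias <- c(grid = "biogrid", "bio-grid" = "biogrid",
               "mips/mpact" = "mpact", "intact project" = "intact")

.norm_db_label <- function(x) {
  x <- tolower(trimws(x))
  hit <- x %in% names(.db_alias)
  x[hit] <- .db_alias[x[hit]]
  x
}

# expand a row-level match on C rows to their whole rigid group
.whole_complexes <- function(t, sel) {
  cls <- classify_record(t)
  hitC <- sel & cls == "complex"
  if (any(hitC)) {
    rid <- mitab_rigids(t)
    sel <- sel | (cls == "complex" & rid %in% rid[hitC])
  }
  sel
}

#' Select records by interaction type
#'
#' @param t A `mitab_table`.
#' @param kinds Nonempty subset of `c("binary", "complex", "polymer")`.
#' @return Sub-table with the matching records, original order.
#' @export
select_interaction_type <- function(t, kinds) {
  kinds <- match.arg(kinds, c("binary", "complex", "polymer"),
                     several.ok = TRUE)
  .subset_rows(t, classify_record(t) %in% kinds)
}

#' Select (or exclude) records by source database
#'
#' Databases may be named by MI code (e.g. "MI:0463") or by label
#' ("biogrid"); label matching is case-insensitive and tolerant of common
#' variants ("grid" for BioGRID).  A database absent from the table selects
#' nothing and is reported via `message()`.
#'
#' @param t A `mitab_table`.
#' @param dbs Nonempty character vector of database labels or MI codes.
#' @param exclude Invert the selection?
#' @return Sub-table, original order.
#' @export
select_database <- function(t, dbs, exclude = FALSE) {
  if (!length(dbs)) stop("dbs must be nonempty", call. = FALSE)
  codes <- mitab_source_codes(t)
  labels <- .norm_db_label(mitab_source_labels(t))
  sel <- rep(FALSE, nrow(t))
  for (q in dbs) {
    hit <- if (grepl("^MI:[0-9]{4}$", q)) !is.na(codes) & codes == q
           else !is.na(labels) & labels == .norm_db_label(q)
    if (!any(hit)) message("select_database: no records from '", q, "'")
    sel <- sel | hit
  }
  .subset_rows(t, if (exclude) !sel else sel)
}

#' Select records involving given proteins
#'
#' Matches interactor keys at the chosen redundancy level.  Complex rows
#' match through their member side, and a matching complex is returned whole
#' (every row of its group).
#'
#' @param t A `mitab_table`.
#' @param ids Nonempty vector of ROGIDs (or cROGIDs).
#' @param id_level "rogid" or "crogid".
#' @return Sub-table, original order.
#' @export
select_protein <- function(t, ids, id_level = c("rogid", "crogid")) {
  if (!length(ids)) stop("ids must be nonempty", call. = FALSE)
  id_level <- match.arg(id_level)
  cls <- classify_record(t)
  ka <- interactor_keys(t, "a", id_level)
  kb <- interactor_keys(t, "b", id_level)
  sel <- (!is.na(kb) & kb %in% ids) |
         (cls != "complex" & !is.na(ka) & ka %in% ids)
  .subset_rows(t, .whole_complexes(t, sel))
}

#' Select records by supporting publication
#'
#' @param t A `mitab_table`.
#' @param pmids Integer vector of PubMed ids; a record matches when its
#'   supporting publications intersect this set.
#' @return Sub-table, original order.
#' @export
select_publication <- function(t, pmids) {
  pm <- mitab_pmids(t)
  sel <- vapply(pm, function(p) any(p %in% pmids), logical(1))
  .subset_rows(t, sel)
}

#' Select records by experimental-method MI code
#'
#' Records with no recorded method never match.
#'
#' @param t A `mitab_table`.
#' @param mi_codes Character vector of MI codes, e.g. "MI:0004".
#' @return Sub-table, original order.
#' @export
select_method <- function(t, mi_codes) {
  mc <- mitab_method_codes(t)
  .subset_rows(t, !is.na(mc) & mc %in% mi_codes)
}

#' Select records by bibliometric score range
#'
#' Keeps records whose `np`, `lpr` or `hpr` score lies in `[lo, hi]`.  By
#' default scores are recomputed from the table itself with
#' [compute_bibliometric_scores()] (a subset's scores differ from the
#' release-wide values shipped in the file); set `recompute = FALSE` to trust
#' the file-supplied `confidence` column instead.
#'
#' @param t A `mitab_table`.
#' @param score "np", "lpr" or "hpr".
#' @param lo,hi Numeric bounds, `lo <= hi`.
#' @param recompute Recompute scores from `t` (default) or read them from the
#'   file's confidence column.
#' @return Sub-table of records with the score present and in range.
#' @export
select_confidence <- function(t, score = c("np", "lpr", "hpr"), lo, hi = Inf,
                              recompute = TRUE) {
  score <- match.arg(score)
  if (lo > hi) stop("lo must be <= hi", call. = FALSE)
  v <- if (recompute) {
    st <- compute_bibliometric_scores(t)
    st[[score]][match(mitab_rigids(t), st$rigid)]
  } else mitab_confidence_scores(t, score)
  .subset_rows(t, !is.na(v) & v >= lo & v <= hi)
}

#' Select records by taxon
#'
#' Two scopes, matching the two ways species-specific interactomes are cut:
#' `at_least_one` keeps records where either interactor is from the taxon
#' (the complex pseudo-node side, which carries no taxon, is ignored);
#' `all_interactors` keeps records where every interactor is from the taxon
#' - for complex groups, every member row, the group standing or falling as
#' a whole.
#'
#' @param t A `mitab_table`.
#' @param taxid NCBI taxon identifier.
#' @param mode "at_least_one" or "all_interactors".
#' @return Sub-table, original order.
#' @export
select_taxon <- function(t, taxid, mode = c("at_least_one", "all_interactors")) {
  mode <- match.arg(mode)
  cls <- classify_record(t)
  ta <- mitab_taxids(t, "a")
  tb <- mitab_taxids(t, "b")
  eq <- function(x) !is.na(x) & x == taxid
  if (mode == "at_least_one") {
    # C rows carry no taxon on the pseudo-node side, so the member side
    # decides; a matching complex is kept whole
    sel <- .whole_complexes(t, eq(ta) | eq(tb))
  } else {
    sel <- eq(ta) & eq(tb)
    isC <- cls == "complex"
    sel[isC] <- FALSE
    if (any(isC)) {
      grp <- .complex_groups(t)
      for (rows in grp)
        if (all(eq(tb)[rows])) sel[rows] <- TRUE
    }
  }
  .subset_rows(t, sel)
}
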