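# Column dialects for the iRefIndex flavour of PSI-MI MITAB 2.6.
#
# The format itself only fixes the first 15 MITAB columns; iRefIndex appends
# its own key columns (irogid/crogid/irigid/crigid, edgetype, numParticipants,
# ...).  A dialect maps abstract record fields to concrete column names so
# that added columns in future releases do not break parsing; columns that no
# field claims are carried along verbatim for lossless round-trips.

.irefkit_fields <- c(
  uid_a            = "uidA",
  uid_b            = "uidB",
  alt_a            = "altA",
  alt_b            = "altB",
  alias_a          = "aliasA",
  alias_b          = "aliasB",
  method           = "method",
  pmids            = "pmids",
  taxon_a          = "taxa",
  taxon_b          = "taxb",
  interaction_type = "interactionType",
  source_db        = "sourcedb",
  interaction_ids  = "interactionIdentifier",
  confidence       = "confidence",
  expansion        = "expansion",
  role_a           = "experimental_role_A",
  role_b           = "experimental_role_B",
  rogid_a          = "Checksum_A",
  rogid_b          = "Checksum_B",
  rigid            = "Checksum_Interaction",
  crogid_a         = "crogida",
  crogid_b         = "crogidb",
  crigid           = "crigid",
  edgetype         = "edgetype",
  num_participants = "numParticipants"
)

.irefindex_columns_8 <- c(
  "uidA", "uidB", "altA", "altB", "aliasA", "aliasB", "method", "author",
  "pmids", "taxa", "taxb", "interactionType", "sourcedb",
  "interactionIdentifier", "confidence", "expansion", "biological_role_A",
  "biological_role_B", "experimental_role_A", "experimental_role_B",
  "interactor_type_A", "interactor_type_B", "xrefs_A", "xrefs_B",
  "xrefs_Interaction", "Annotations_A", "Annotations_B",
  "Annotations_Interaction", "Host_organism_taxid", "parameters_Interaction",
  "Creation_date", "Update_date", "Checksum_A", "Checksum_B",
  "Checksum_Interaction", "Negative", "OriginalReferenceA",
  "OriginalReferenceB", "FinalReferenceA", "FinalReferenceB", "MappingScoreA",
  "MappingScoreB", "irogida", "irogidb", "irigid", "crogida", "crogidb",
  "crigid", "icrogida", "icrogidb", "icrigid", "imex_id", "edgetype",
  "numParticipants"
)

#' Registered MITAB column dialects
#'
#' Returns the registry of known iRefIndex column dialects.  Each entry
#' carries the full ordered column vector of the release header and the map
#' from abstract record fields (uid, taxon, checksum keys, edgetype, ...) to
#' column names.  `read_mitab()` accepts any header that contains all mapped
#' columns of some dialect; extra columns are preserved as opaque text.
#'
#' @return Named list of dialects, each a list with elements `columns` and
#'   `fields`.
#' @export
mitab_dialects <- function() {
  list(
    irefindex_8.0 = list(
      columns = .irefindex_columns_8,
      fields  = .irefkit_fields
    ),
    irefindex_7.0 = list(
      columns = setdiff(.irefindex_columns_8, "imex_id"),
      fields  = .irefkit_fields
    )
  )
}

.match_dialect <- function(cols) {
  reg <- mitab_dialects()
  # exact header match first, then required-field presence
  for (nm in names(reg))
    if (identical(cols, reg[[nm]]$columns))
      return(list(name = nm, fields = reg[[nm]]$fields))
  for (nm in names(reg))
    if (all(reg[[nm]]$fields %in% cols))
      return(list(name = paste0(nm, "+extra"), fields = reg[[nm]]$fields))
  stop("unrecognized MITAB header: required iRefIndex columns missing ",
       "(dialect error)", call. = FALSE)
}

new_mitab_table <- function(df, dialect, fields = .irefkit_fields,
                            meta = list()) {
  rownames(df) <- NULL
  structure(df,
            dialect = dialect,
            fields  = fields,
            meta    = meta,
            class   = c("mitab_table", "data.frame"))
}

#' @export
`[.mitab_table` <- function(x, i, j, ...) {
  out <- NextMethod()
  if (is.data.frame(out) && identical(names(out), names(x))) {
    attr(out, "dialect") <- attr(x, "dialect")
    attr(out, "fields")  <- attr(x, "fields")
    attr(out, "meta")    <- attr(x, "meta")
    class(out) <- c("mitab_table", "data.frame")
    rownames(out) <- NULL
  }
  out
}

#' @export
print.mitab_table <- function(x, ...) {
  cls <- classify_record(x)
  cat(sprintf("<mitab_table> %d records (%s dialect): %d binary, %d complex (%d groups), %d polymer\n",
              nrow(x), attr(x, "dialect") %||% "?",
              sum(cls == "binary"),
              sum(cls == "complex"),
              length(unique(mitab_rigids(x)[cls == "complex"])),
              sum(cls == "polymer")))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.subset_rows <- function(t, idx) t[idx, , drop = FALSE]

.mfield <- function(t, field) {
  col <- attr(t, "fields")[[field]]
  if (is.null(col) || !col %in% names(t)) rep("-", nrow(t)) else t[[col]]
}

.absent <- function(x) is.na(x) | x == "-" | x == ""
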