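# Parsed views over the raw character columns of a mitab_table.  The table
# keeps every cell as distributed text ("-" for absent, "|" between values,
# "key:value" tokens); these accessors are the only place that text is
# interpreted, so read/write round-trips stay lossless.

.uid_namespace <- function(x) {
  out <- sub("^([^:]+):.*$", "\\1", x)
  out[.absent(x) | !grepl(":", x, fixed = TRUE)] <- NA_character_
  out
}

.uid_accession <- function(x) {
  out <- sub("^[^:]+:", "", x)
  out[.absent(x)] <- NA_character_
  out
}

.strip_prefix <- function(x, prefix) {
  out <- sub(paste0("^", prefix, ":"), "", x)
  out[.absent(x)] <- NA_character_
  out
}

.mi_code <- function(x) {
  out <- rep(NA_character_, length(x))
  hit <- !.absent(x) & grepl("MI:[0-9]{4}", x)
  out[hit] <- regmatches(x[hit], regexpr("MI:[0-9]{4}", x[hit]))
  out
}

#' Interaction edge types of a MITAB table
#'
#' Returns the per-record edge type, using the `edgetype` column when present
#' (`X` binary, `C` complex/n-ary, `Y` polymer) and falling back, for dialects
#' lacking it, to: `uidA` in the "complex" namespace implies `C`; equal A/B
#' ROGIDs imply `Y`; otherwise `X`.
#'
#' @param t A `mitab_table`.
#' @return Character vector of "X", "C", "Y".
#' @export
mitab_edgetypes <- function(t) {
  et <- .mfield(t, "edgetype")
  miss <- .absent(et)
  if (any(miss)) {
    ns <- .uid_namespace(.mfield(t, "uid_a"))
    ra <- interactor_keys(t, "a", "rogid")
    rb <- interactor_keys(t, "b", "rogid")
    fb <- ifelse(!is.na(ns) & ns == "complex", "C",
          ifelse(!is.na(ra) & !is.na(rb) & ra == rb, "Y", "X"))
    et[miss] <- fb[miss]
  }
  et
}

#' Classify records as binary, complex or polymer
#'
#' Total function over any parsed table: `C` records are complexes, `Y`
#' polymers, `X` binary (with the same fallbacks as [mitab_edgetypes()]).
#'
#' @param t A `mitab_table`.
#' @return Character vector with values "binary", "complex", "polymer".
#' @export
classify_record <- function(t) {
  c(X = "binary", C = "complex", Y = "polymer")[mitab_edgetypes(t)]
}

#' Interactor keys at a redundancy level
#'
#' Extracts the ROGID (sequence+taxon key) or canonical ROGID of the A or B
#' interactor of every record.  For complex (`C`) rows the A side holds the
#' group pseudo-node key.
#'
#' @param t A `mitab_table`.
#' @param side "a" or "b".
#' @param level "rogid" or "crogid".
#' @return Character vector (NA where absent).
#' @export
interactor_keys <- function(t, side = c("a", "b"),
                            level = c("rogid", "crogid")) {
  side <- match.arg(side)
  level <- match.arg(level)
  if (level == "rogid")
    .strip_prefix(.mfield(t, paste0("rogid_", side)), "rogid")
  else {
    x <- .mfield(t, paste0("crogid_", side))
    x[.absent(x)] <- NA_character_
    x
  }
}

#' Interaction keys at a redundancy level
#'
#' @param t A `mitab_table`.
#' @param level "rigid" (sequence-specific) or "crigid" (canonical).
#' @return Character vector of interaction group keys.
#' @export
mitab_rigids <- function(t, level = c("rigid", "crigid")) {
  level <- match.arg(level)
  if (level == "rigid")
    .strip_prefix(.mfield(t, "rigid"), "rigid")
  else {
    x <- .mfield(t, "crigid")
    x[.absent(x)] <- NA_character_
    x
  }
}

#' NCBI taxon identifiers of the interactors
#'
#' Parses `taxid:NNNN(name)` cells down to the integer id; the organism name
#' is discarded.
#'
#' @param t A `mitab_table`.
#' @param side "a" or "b".
#' @return Integer vector (NA where absent).
#' @export
mitab_taxids <- function(t, side = c("a", "b")) {
  side <- match.arg(side)
  x <- .mfield(t, paste0("taxon_", side))
  out <- rep(NA_integer_, length(x))
  hit <- !.absent(x) & grepl("^taxid:-?[0-9]+", x)
  out[hit] <- as.integer(sub("^taxid:(-?[0-9]+).*$", "\\1", x[hit]))
  out
}

#' PubMed identifiers supporting each record
#'
#' @param t A `mitab_table`.
#' @return List of integer vectors, one per record (empty when unsupported).
#' @export
mitab_pmids <- function(t) {
  x <- .mfield(t, "pmids")
  lapply(seq_along(x), function(i) {
    if (.absent(x[i])) return(integer(0))
    toks <- strsplit(x[i], "|", fixed = TRUE)[[1]]
    ids <- suppressWarnings(as.integer(sub("^pubmed:", "", toks)))
    sort(unique(ids[!is.na(ids)]))
  })
}

#' Experimental-method MI codes
#'
#' @param t A `mitab_table`.
#' @return Character vector of `MI:nnnn` codes (NA where absent).
#' @export
mitab_method_codes <- function(t) .mi_code(.mfield(t, "method"))

#' Source-database MI codes and labels
#'
#' `sourcedb` cells look like `MI:0463(biogrid)`.
#'
#' @param t A `mitab_table`.
#' @return Character vector.
#' @export
mitab_source_codes <- function(t) .mi_code(.mfield(t, "source_db"))

#' @rdname mitab_source_codes
#' @export
mitab_source_labels <- function(t) {
  x <- .mfield(t, "source_db")
  out <- rep(NA_character_, length(x))
  hit <- !.absent(x)
  lab <- ifelse(grepl("\\(", x), sub("^.*\\(([^)]*)\\).*$", "\\1", x), x)
  out[hit] <- tolower(lab[hit])
  out
}

.role_codes <- function(t, side) .mi_code(.mfield(t, paste0("role_", side)))

#' File-supplied confidence/bibliometric scores
#'
#' Parses the `confidence` column (`np:2|lpr:1|hpr:34`) and returns the value
#' of one named score per record.
#'
#' @param t A `mitab_table`.
#' @param name Score name, e.g. "np", "lpr", "hpr".
#' @return Numeric vector (NA where the score is not listed).
#' @export
mitab_confidence_scores <- function(t, name) {
  x <- .mfield(t, "confidence")
  vapply(x, function(cell) {
    if (.absent(cell)) return(NA_real_)
    toks <- strsplit(cell, "|", fixed = TRUE)[[1]]
    kv <- strsplit(toks, ":", fixed = TRUE)
    for (p in kv)
      if (length(p) >= 2 && p[1] == name)
        return(suppressWarnings(as.numeric(p[2])))
    NA_real_
  }, numeric(1), USE.NAMES = FALSE)
}

.num_participants <- function(t) {
  x <- .mfield(t, "num_participants")
  out <- rep(NA_integer_, length(x))
  hit <- !.absent(x)
  out[hit] <- suppressWarnings(as.integer(x[hit]))
  out
}

# row indices of C records grouped by interaction key
.complex_groups <- function(t, level = "rigid") {
  cls <- classify_record(t)
  idx <- which(cls == "complex")
  if (!length(idx)) return(list())
  split(idx, mitab_rigids(t, level)[idx])
}

# distinct member keys (B side) of each complex group, sorted bytewise
.complex_member_keys <- function(t, groups, id_level = "rogid") {
  kb <- interactor_keys(t, "b", id_level)
  lapply(groups, function(rows) sort(unique(kb[rows]), method = "radix"))
}
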