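# Interactor/interaction key handling: accession lookup tables, namespace
# translation, distinct-entity counting at both redundancy levels, and
# recomputation of ROGID/RIGID digest keys for verification.

.AA_REGEX <- "^[ACDEFGHIKLMNPQRSTVWYBJOUXZ*]+$"

.sha1_b64 <- function(txt) {
  raw <- digest::digest(txt, algo = "sha1", serialize = FALSE, raw = TRUE)
  gsub("=+$", "", jsonlite::base64_enc(raw))
}

#' Recompute a ROGID key from sequence and taxon
#'
#' The ROGID groups identical protein interactors across source databases: a
#' SEGUID-style base64-encoded SHA-1 digest of the uppercased amino-acid
#' sequence, with the NCBI taxon identifier appended as text.  Intended for
#' verification of file-supplied keys (which remain authoritative), and used
#' by the synthetic-fixture generator so that all planted keys are
#' self-consistent.
#'
#' @param sequence Amino-acid string (standard plus ambiguity codes).
#' @param taxid NCBI taxon identifier (integer).
#' @return ROGID string.
#' @export
compute_rogid <- function(sequence, taxid) {
  stopifnot(length(sequence) == 1, length(taxid) == 1)
  sequence <- toupper(sequence)
  if (!nzchar(sequence) || !grepl(.AA_REGEX, sequence))
    stop("sequence contains non-amino-acid characters (validation error)",
         call. = FALSE)
  paste0(.sha1_b64(sequence), as.integer(taxid))
}

#' Recompute a RIGID key from participant ROGIDs
#'
#' The RIGID groups all source records sharing one set of interactors: the
#' base64-encoded SHA-1 digest of the participants' ROGIDs sorted bytewise
#' (so the key is invariant under input order) and concatenated.  The same
#' construction over canonical ROGIDs yields the canonical RIGID.
#'
#' @param rogids Character vector of participant ROGIDs (repeats allowed, as
#'   in polymers).
#' @return RIGID string.
#' @export
compute_rigid <- function(rogids) {
  if (!length(rogids) || any(is.na(rogids) | !nzchar(rogids)))
    stop("need a nonempty vector of ROGIDs", call. = FALSE)
  .sha1_b64(paste(sort(rogids, method = "radix"), collapse = ""))
}

#' Build an accession lookup table
#'
#' Harvests every `namespace:accession` token from the uid, alternative-id
#' and alias columns of both interactor slots (the complex pseudo-node side
#' of `C` rows is skipped) and pairs it with the slot's ROGID and canonical
#' ROGID.  Each ROGID and cROGID is also listed under its own namespace so
#' that translations can start or end at the key level.
#'
#' @param t A `mitab_table`.
#' @return An `id_mapping` data frame with columns `rogid`, `crogid`,
#'   `namespace`, `accession`; rows unique and sorted.  A ROGID mapped to two
#'   different cROGIDs is an integrity error.
#' @seealso [convert_protein_id()]
#' @export
build_id_table <- function(t) {
  cls <- classify_record(t)
  acc <- list()
  for (side in c("a", "b")) {
    keep <- if (side == "a") cls != "complex" else rep(TRUE, nrow(t))
    if (!any(keep)) next
    rog <- interactor_keys(t, side, "rogid")[keep]
    crog <- interactor_keys(t, side, "crogid")[keep]
    cells <- cbind(uid = .mfield(t, paste0("uid_", side))[keep],
                   alt = .mfield(t, paste0("alt_", side))[keep],
                   alias = .mfield(t, paste0("alias_", side))[keep])
    for (i in which(!is.na(rog))) {
      toks <- unlist(strsplit(cells[i, ], "|", fixed = TRUE), use.names = FALSE)
      toks <- toks[!.absent(toks) & grepl(":", toks, fixed = TRUE)]
      ns <- .uid_namespace(toks)
      ac <- .uid_accession(toks)
      ok <- !is.na(ns) & !is.na(ac) & nzchar(ac) &
        !ns %in% c("rogid", "crogid", "irogid", "icrogid", "complex")
      ns <- c(ns[ok], "rogid", if (!is.na(crog[i])) "crogid")
      ac <- c(ac[ok], rog[i], if (!is.na(crog[i])) crog[i])
      acc[[length(acc) + 1L]] <-
        data.frame(rogid = rog[i],
                   crogid = if (is.na(crog[i])) rog[i] else crog[i],
                   namespace = ns, accession = ac,
                   stringsAsFactors = FALSE)
    }
  }
  m <- if (length(acc)) unique(do.call(rbind, acc))
       else data.frame(rogid = character(0), crogid = character(0),
                       namespace = character(0), accession = character(0),
                       stringsAsFactors = FALSE)
  bad <- tapply(m$crogid, m$rogid, function(x) length(unique(x)) > 1)
  if (any(bad))
    stop("conflicting cROGID assignments for ROGID ",
         names(bad)[bad][1], " (integrity error)", call. = FALSE)
  m <- m[order(m$rogid, m$namespace, m$accession, method = "radix"), ]
  rownames(m) <- NULL
  class(m) <- c("id_mapping", "data.frame")
  m
}

#' Translate protein identifiers between namespaces
#'
#' Routes each query accession through the ROGID level: all ROGIDs carrying
#' the accession in `from_ns` are found and their accessions in `to_ns`
#' collected.  One-to-many translations return all targets; unmapped values
#' map to an empty vector.
#'
#' @param m An `id_mapping` from [build_id_table()].
#' @param values Character vector of accessions to translate.
#' @param from_ns,to_ns Namespace tokens known to `m` (e.g. "uniprotkb",
#'   "refseq", "entrezgene/locuslink", "rogid", "crogid"); "geneid" is
#'   accepted as an alias of "entrezgene/locuslink".
#' @return Named list mapping each input value to a sorted character vector
#'   of target accessions.
#' @export
convert_protein_id <- function(m, values, from_ns, to_ns) {
  alias <- c(geneid = "entrezgene/locuslink")
  if (from_ns %in% names(alias)) from_ns <- alias[[from_ns]]
  if (to_ns %in% names(alias)) to_ns <- alias[[to_ns]]
  vocab <- unique(m$namespace)
  for (ns in c(from_ns, to_ns))
    if (!ns %in% vocab)
      stop("unknown namespace '", ns, "' (known: ",
           paste(sort(vocab), collapse = ", "), ")", call. = FALSE)
  out <- lapply(as.character(values), function(v) {
    rogs <- m$rogid[m$namespace == from_ns & m$accession == v]
    if (!length(rogs)) return(character(0))
    sort(unique(m$accession[m$namespace == to_ns & m$rogid %in% rogs]),
         method = "radix")
  })
  names(out) <- as.character(values)
  out
}

#' Distinct interacting proteins
#'
#' The set of interactor keys, at the sequence-specific (ROGID) or canonical
#' (cROGID) level, over the table or its single-species core.  Complex
#' pseudo-nodes are never counted.
#'
#' @param t A `mitab_table`.
#' @param level "rogid" or "crogid".
#' @param taxid Optional NCBI taxon id: restrict to records whose interactors
#'   are all from this taxon (intra-species scope, see [select_taxon()])
#'   before counting.
#' @return Sorted character vector of keys.
#' @export
distinct_proteins <- function(t, level = c("rogid", "crogid"), taxid = NULL) {
  level <- match.arg(level)
  if (!is.null(taxid)) t <- select_taxon(t, taxid, "all_interactors")
  cls <- classify_record(t)
  ka <- interactor_keys(t, "a", level)
  kb <- interactor_keys(t, "b", level)
  keys <- c(ka[cls != "complex"], kb)
  sort(unique(keys[!is.na(keys)]), method = "radix")
}

#' Distinct interactions
#'
#' The set of interaction keys at the RIGID or canonical-RIGID level; a
#' complex counts once however many member rows represent it.
#'
#' @param t A `mitab_table`.
#' @param level "rigid" or "crigid".
#' @return Sorted character vector of keys.
#' @export
distinct_interactions <- function(t, level = c("rigid", "crigid")) {
  level <- match.arg(level)
  keys <- mitab_rigids(t, level)
  sort(unique(keys[!is.na(keys)]), method = "radix")
}
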