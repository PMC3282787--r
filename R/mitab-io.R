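# Reading, validating, writing and fetching iRefIndex MITAB 2.6 files.

.open_text <- function(source) {
  if (inherits(source, "connection")) return(source)
  if (!is.character(source) || length(source) != 1)
    stop("source must be a file path or a connection", call. = FALSE)
  if (grepl("\\.zip$", source)) {
    inner <- utils::unzip(source, list = TRUE)$Name[1]
    return(unz(source, inner))
  }
  # gzfile() reads both gzip-compressed and plain text transparently
  gzfile(source)
}

#' Read an iRefIndex MITAB table
#'
#' Parses a tab-delimited interaction file in the iRefIndex MITAB 2.6
#' dialect.  The header row (with or without a leading `#`) selects a column
#' dialect from [mitab_dialects()]; headers that contain all required columns
#' plus unknown extras are accepted, the extras travelling along unparsed so
#' that `write_mitab()` reproduces them.  gzip- and zip-compressed inputs are
#' decompressed transparently.
#'
#' @param source File path or text connection.
#' @param mode "strict" (default): a line with the wrong number of columns is
#'   an error and record-level invariants are checked after parsing;
#'   "lenient": malformed lines are skipped and counted in
#'   `attr(, "meta")$skipped`.
#' @return A `mitab_table`: a data frame of character columns (one per file
#'   column, cells kept verbatim) with dialect and provenance metadata.
#' @seealso [write_mitab()], [classify_record()], [validate_mitab()]
#' @examples
#' tab <- generate_mitab(seed = 1)$table
#' f <- tempfile(fileext = ".mitab")
#' write_mitab(tab, f)
#' identical(as.data.frame(read_mitab(f)), as.data.frame(tab))
#' @export
read_mitab <- function(source, mode = c("strict", "lenient")) {
  mode <- match.arg(mode)
  con <- .open_text(source)
  if (!isOpen(con)) { open(con, "rt"); on.exit(close(con)) }
  lines <- readLines(con, warn = FALSE)
  if (!length(lines))
    stop("empty input: no MITAB header line (dialect error)", call. = FALSE)
  cols <- strsplit(sub("^#", "", lines[[1]]), "\t", fixed = TRUE)[[1]]
  dial <- .match_dialect(cols)
  body <- lines[-1]
  body <- body[nzchar(body)]
  skipped <- 0L
  if (length(body)) {
    parts <- strsplit(body, "\t", fixed = TRUE)
    nc <- lengths(parts)
    bad <- nc != length(cols)
    if (any(bad)) {
      if (mode == "strict")
        stop(sprintf("line %d has %d columns, expected %d (parse error)",
                     which(bad)[1] + 1L, nc[bad][1], length(cols)),
             call. = FALSE)
      skipped <- sum(bad)
      parts <- parts[!bad]
    }
    m <- matrix(unlist(parts), ncol = length(cols), byrow = TRUE)
    df <- as.data.frame(m, stringsAsFactors = FALSE)
  } else {
    df <- as.data.frame(matrix(character(0), ncol = length(cols)),
                        stringsAsFactors = FALSE)
  }
  names(df) <- cols
  t <- new_mitab_table(df, dial$name, dial$fields,
                       meta = list(source = if (is.character(source)) source else "<connection>",
                                   skipped = skipped))
  if (mode == "strict") validate_mitab(t)
  t
}

#' Write a MITAB table
#'
#' Serializes a `mitab_table` back to tab-delimited text: header line (with a
#' leading `#`, as distributed) followed by one line per record.  Absent
#' values are emitted as `-`.  Rereading the output reproduces the table
#' field by field.
#'
#' @param t A `mitab_table`.
#' @param path Output file path (`.gz` suffix gzip-compresses) or writable
#'   text connection.
#' @return Invisibly, the number of data lines written.
#' @export
write_mitab <- function(t, path) {
  stopifnot(inherits(t, "mitab_table"))
  cells <- as.data.frame(t)
  for (j in seq_along(cells)) {
    x <- cells[[j]]
    x[is.na(x) | x == ""] <- "-"
    cells[[j]] <- x
  }
  lines <- c(paste0("#", paste(names(t), collapse = "\t")),
             if (nrow(cells)) do.call(paste, c(unname(as.list(cells)), sep = "\t")))
  if (inherits(path, "connection")) {
    writeLines(lines, path)
  } else {
    con <- if (grepl("\\.gz$", path)) gzfile(path, "wt") else file(path, "wt")
    on.exit(close(con))
    writeLines(lines, con)
  }
  invisible(nrow(cells))
}

#' Check record-level invariants of a MITAB table
#'
#' Verifies the structural rules of the dialect: `C` rows (and only those)
#' have a "complex" namespace A-interactor; polymer rows have equal A/B
#' ROGIDs; complex groups declare at least 3 participants and all rows of one
#' group agree on that count; and `lpr <= hpr`, `np >= 1` wherever all three
#' bibliometric scores are supplied.
#'
#' @param t A `mitab_table`.
#' @return Invisibly `TRUE`; stops with a descriptive error otherwise.
#' @export
validate_mitab <- function(t) {
  if (!nrow(t)) return(invisible(TRUE))
  et <- mitab_edgetypes(t)
  ns <- .uid_namespace(.mfield(t, "uid_a"))
  isc <- !is.na(ns) & ns == "complex"
  if (any((et == "C") != isc))
    stop("edgetype C and 'complex' uidA namespace must coincide (row ",
         which((et == "C") != isc)[1], ")", call. = FALSE)
  ra <- interactor_keys(t, "a", "rogid")
  rb <- interactor_keys(t, "b", "rogid")
  badY <- et == "Y" & (is.na(ra) | is.na(rb) | ra != rb)
  if (any(badY))
    stop("polymer (Y) row with differing A/B ROGIDs (row ",
         which(badY)[1], ")", call. = FALSE)
  np_ <- .num_participants(t)
  if (any(et == "C" & (is.na(np_) | np_ < 3)))
    stop("complex (C) row with numParticipants < 3", call. = FALSE)
  grp <- .complex_groups(t)
  for (g in grp)
    if (length(unique(np_[g])) > 1)
      stop("complex group with inconsistent numParticipants: rigid ",
           mitab_rigids(t)[g[1]], call. = FALSE)
  np <- mitab_confidence_scores(t, "np")
  lpr <- mitab_confidence_scores(t, "lpr")
  hpr <- mitab_confidence_scores(t, "hpr")
  all3 <- !is.na(np) & !is.na(lpr) & !is.na(hpr)
  if (any(all3 & (np < 1 | lpr > hpr)))
    stop("invalid bibliometric scores: need np >= 1 and lpr <= hpr",
         call. = FALSE)
  invisible(TRUE)
}

#' Download an iRefIndex release file
#'
#' Retrieves the compressed MITAB file for one taxon (or the all-organism
#' file) of a given release and decompresses it at `dest`.  Purely a
#' convenience for interactive use; nothing else in the package requires
#' network access, and the test suite never calls this.
#'
#' @param version Release tag, e.g. "8.0".
#' @param taxon NCBI taxon id (integer) or "all".
#' @param dest Destination path for the decompressed MITAB file.
#' @param url Optional explicit URL of the compressed file; when omitted a
#'   URL is composed from `base_url`, `version` and `taxon` (release archives
#'   are date-stamped, so the composed name may need overriding).
#' @param base_url Archive root.
#' @param overwrite Overwrite an existing `dest`?
#' @param retries Download attempts before giving up.
#' @return `dest`, invisibly.
#' @export
fetch_irefindex <- function(version, taxon = "all", dest,
                            url = NULL,
                            base_url = "ftp://ftp.no.embnet.org/irefindex/data/archive",
                            overwrite = FALSE, retries = 3) {
  if (!(identical(taxon, "all") ||
        (length(taxon) == 1 && grepl("^[0-9]+$", as.character(taxon)))))
    stop("unknown taxon '", taxon, "': need an NCBI taxid or \"all\" ",
         "(lookup error)", call. = FALSE)
  if (!grepl("^[0-9]+\\.[0-9]+$", version))
    stop("unknown release version '", version, "' (lookup error)",
         call. = FALSE)
  if (file.exists(dest) && !overwrite)
    stop("destination exists: ", dest, " (pass overwrite = TRUE)",
         call. = FALSE)
  if (is.null(url))
    url <- sprintf("%s/release_%s/psi_mitab/MITAB2.6/%s.mitab.txt.zip",
                   base_url, version, taxon)
  tmp <- tempfile(fileext = paste0(".", tools::file_ext(url)))
  on.exit(unlink(tmp))
  ok <- FALSE
  for (i in seq_len(max(1, retries))) {
    status <- tryCatch(utils::download.file(url, tmp, mode = "wb", quiet = TRUE),
                       error = function(e) -1L)
    if (identical(status, 0L)) { ok <- TRUE; break }
  }
  if (!ok)
    stop("transfer failed after ", retries, " attempts: ", url, call. = FALSE)
  con <- .open_text(tmp)
  open(con, "rt")
  on.exit(close(con), add = TRUE)
  out <- file(dest, "wt")
  on.exit(close(out), add = TRUE)
  repeat {
    chunk <- readLines(con, n = 100000L, warn = FALSE)
    if (!length(chunk)) break
    writeLines(chunk, out)
  }
  invisible(dest)
}
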