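# Detection of spoke-represented complexes hidden in binary records.  Some
# source databases curate co-purification experiments (inherently n-ary) as
# stars of binary bait-prey records; such a star can be folded back into one
# regenerated n-ary record when its records all come from the same database
# and paper, use a method known to produce n-ary data, and share one protein
# (the hub, normally the experimental bait).

#' MI codes of methods treated as n-ary-producing
#'
#' Pulldown-style detection methods whose "binary" records typically derive
#' from a co-purified group: affinity chromatography and its
#' coimmunoprecipitation / pull-down / tandem-affinity relatives.
#'
#' @return Character vector of MI codes.
#' @export
default_nary_methods <- function() {
  c("MI:0004",  # affinity chromatography technology
    "MI:0006",  # anti bait coimmunoprecipitation
    "MI:0007",  # anti tag coimmunoprecipitation
    "MI:0019",  # coimmunoprecipitation
    "MI:0096",  # pull down
    "MI:0676")  # tandem affinity purification
}

.empty_regenerated <- function() {
  out <- data.frame(complex_id = character(0), hub = character(0),
                    size = integer(0), source_db = character(0),
                    pmid = integer(0), method = character(0),
                    throughput = character(0), stringsAsFactors = FALSE)
  out$members <- list()
  out$support <- list()
  structure(out[c("complex_id", "hub", "members", "size", "source_db",
                  "pmid", "method", "support", "throughput")],
            class = c("regenerated_complexes", "data.frame"))
}

#' Regenerate candidate complexes from binary records
#'
#' Implements the three grouping criteria: (1) keep binary records whose
#' detection method is in `allowed_methods` and that are supported by exactly
#' one publication; (2) group them by (source database, publication, method);
#' (3) within a group, either form one complex per bait - members are the
#' bait plus its preys (`require_bait = TRUE`; records without a unique bait
#' role are ignored) - or greedily pick the protein occurring in the most
#' records as hub (ties broken bytewise), assign every record containing it,
#' remove those records and repeat.  Complexes with fewer than `min_members`
#' distinct members are discarded.
#'
#' Each record supports at most one complex (greedy assignment consumes it);
#' `allow_overlap = TRUE` switches to an overlap mode in which every protein
#' occurring in two or more records of a group seeds a candidate complex,
#' for comparing detection variants.
#'
#' @param t A `mitab_table`.
#' @param allowed_methods Nonempty character vector of MI codes.
#' @param require_bait Use bait roles (default) or greedy hub search.
#' @param min_members Minimum complex size (the n-ary definition: 3).
#' @param id_level "rogid" or "crogid" member identifiers.
#' @param allow_overlap Greedy mode only: let records support several hubs.
#' @param lpr_threshold Throughput boundary on the supporting records'
#'   recomputed lpr score (low when all scored supports have
#'   `lpr <= lpr_threshold`).
#' @return A `regenerated_complexes` data frame: `complex_id`, `hub`,
#'   `members` (list, sorted, hub included), `size`, `source_db`, `pmid`,
#'   `method`, `support` (list of row indices into `t`), `throughput`
#'   ("low"/"high"/"unknown").  Deterministic order regardless of input row
#'   order.
#' @export
regenerate_complexes <- function(t, allowed_methods, require_bait = TRUE,
                                 min_members = 3,
                                 id_level = c("rogid", "crogid"),
                                 allow_overlap = FALSE, lpr_threshold = 21) {
  if (!length(allowed_methods))
    stop("allowed_methods must be nonempty", call. = FALSE)
  id_level <- match.arg(id_level)
  cls <- classify_record(t)
  mcode <- mitab_method_codes(t)
  pms <- mitab_pmids(t)
  cand <- which(cls == "binary" & !is.na(mcode) &
                mcode %in% allowed_methods & lengths(pms) == 1)
  if (!length(cand)) return(.empty_regenerated())
  ka <- interactor_keys(t, "a", id_level)
  kb <- interactor_keys(t, "b", id_level)
  dbl <- .norm_db_label(mitab_source_labels(t))
  ra <- .role_codes(t, "a")
  rb <- .role_codes(t, "b")
  pmid1 <- vapply(pms, function(p) if (length(p)) p[1] else NA_integer_,
                  integer(1))
  gkey <- paste(dbl[cand], pmid1[cand], mcode[cand], sep = "\r")
  groups <- split(cand, gkey)
  res <- list()
  for (g in sort(names(groups), method = "radix")) {
    rows <- groups[[g]]
    if (require_bait) {
      bait <- ifelse(ra[rows] %in% "MI:0496" & !(rb[rows] %in% "MI:0496"),
                     ka[rows],
              ifelse(rb[rows] %in% "MI:0496" & !(ra[rows] %in% "MI:0496"),
                     kb[rows], NA_character_))
      ok <- !is.na(bait)
      if (!any(ok)) next
      for (h in sort(unique(bait[ok]), method = "radix")) {
        sup <- rows[ok & bait == h]
        mem <- sort(unique(c(h, ka[sup], kb[sup])), method = "radix")
        mem <- mem[!is.na(mem)]
        if (length(mem) >= min_members)
          res[[length(res) + 1L]] <- list(hub = h, members = mem,
                                          support = sup, row1 = rows[1])
      }
    } else if (allow_overlap) {
      keys <- sort(unique(c(ka[rows], kb[rows])), method = "radix")
      for (h in keys) {
        sup <- rows[ka[rows] == h | kb[rows] == h]
        if (length(sup) < 2) next
        mem <- sort(unique(c(ka[sup], kb[sup])), method = "radix")
        if (length(mem) >= min_members)
          res[[length(res) + 1L]] <- list(hub = h, members = mem,
                                          support = sup, row1 = rows[1])
      }
    } else {
      remaining <- rows
      while (length(remaining)) {
        keys <- c(ka[remaining], kb[remaining])
        tab <- table(keys)
        top <- max(tab)
        h <- sort(names(tab)[tab == top], method = "radix")[1]
        sup <- remaining[ka[remaining] == h | kb[remaining] == h]
        mem <- sort(unique(c(ka[sup], kb[sup])), method = "radix")
        if (length(mem) >= min_members)
          res[[length(res) + 1L]] <- list(hub = h, members = mem,
                                          support = sup, row1 = rows[1])
        remaining <- setdiff(remaining, sup)
      }
    }
  }
  if (!length(res)) return(.empty_regenerated())
  meta_row <- vapply(res, function(r) r$support[1], integer(1))
  out <- data.frame(
    complex_id = sprintf("regen_%04d", seq_along(res)),
    hub = vapply(res, `[[`, character(1), "hub"),
    size = vapply(res, function(r) length(r$members), integer(1)),
    source_db = dbl[meta_row],
    pmid = pmid1[meta_row],
    method = mcode[meta_row],
    stringsAsFactors = FALSE)
  out$members <- lapply(res, `[[`, "members")
  out$support <- lapply(res, function(r) sort(r$support))
  # throughput class from the supporting records' recomputed lpr
  st <- compute_bibliometric_scores(t)
  rid <- mitab_rigids(t)
  lpr <- st$lpr[match(rid, st$rigid)]
  out$throughput <- vapply(out$support, function(sup) {
    v <- lpr[sup]
    if (all(is.na(v))) "unknown"
    else if (max(v, na.rm = TRUE) <= lpr_threshold) "low"
    else "high"
  }, character(1))
  ord <- order(out$source_db, out$pmid, out$method, out$hub, method = "radix")
  out <- out[ord, c("complex_id", "hub", "members", "size", "source_db",
                    "pmid", "method", "support", "throughput")]
  out$complex_id <- sprintf("regen_%04d", seq_len(nrow(out)))
  rownames(out) <- NULL
  class(out) <- c("regenerated_complexes", "data.frame")
  out
}

#' Conservative complex regeneration
#'
#' The conservative preset: only binary BioGRID records with MI:0004
#' (affinity chromatography) as detection method are considered, with bait
#' roles used when the subset carries any.
#'
#' @param t A `mitab_table`.
#' @param min_members,id_level,lpr_threshold As [regenerate_complexes()].
#' @return A `regenerated_complexes` data frame (subset of the permissive
#'   result).
#' @export
conservative_preset <- function(t, min_members = 3,
                                id_level = c("rogid", "crogid"),
                                lpr_threshold = 21) {
  id_level <- match.arg(id_level)
  sub <- suppressMessages(select_database(t, "biogrid"))
  if (!nrow(sub)) return(.empty_regenerated())
  has_roles <- any(.role_codes(sub, "a") %in% "MI:0496" |
                   .role_codes(sub, "b") %in% "MI:0496")
  regenerate_complexes(sub, "MI:0004", require_bait = has_roles,
                       min_members = min_members, id_level = id_level,
                       lpr_threshold = lpr_threshold)
}

.complex_sizes <- function(x) {
  if (is.numeric(x)) return(as.integer(x))
  if (is.data.frame(x) && "members" %in% names(x))
    return(lengths(x$members))
  stop("cannot extract complex sizes from ", class(x)[1], call. = FALSE)
}

#' Size distribution of a set of complexes
#'
#' @param x A `complex_list`, `regenerated_complexes`, or an integer vector
#'   of sizes.
#' @return Data frame with columns `size` and `count`.
#' @export
size_distribution <- function(x) {
  s <- .complex_sizes(x)
  tab <- table(factor(s, levels = sort(unique(s))))
  data.frame(size = as.integer(names(tab)), count = as.integer(tab))
}

#' Compare two complex-size distributions
#'
#' Two-sample two-sided Kolmogorov-Smirnov test on the member counts
#' (asymptotic p-value, as sizes are tied integers).
#'
#' @param a,b Complex sets or integer size vectors (see
#'   [size_distribution()]).
#' @return List with elements `D` (statistic) and `p_value`.
#' @export
compare_size_distributions <- function(a, b) {
  sa <- .complex_sizes(a)
  sb <- .complex_sizes(b)
  kt <- suppressWarnings(stats::ks.test(sa, sb, exact = FALSE))
  list(D = unname(kt$statistic), p_value = kt$p.value)
}
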