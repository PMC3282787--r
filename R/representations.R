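# Interconversion among the four data representations: MITAB records,
# complexList (one row per n-ary group), edgeList (weighted node pairs) and
# igraph objects.  Every n-ary record is expanded under an explicit policy:
#   spoke     - hub to each other member, m-1 edges (hub = the unique bait
#               when exactly one member is a bait, else the bytewise-smallest
#               member id, logged);
#   matrix    - all pairwise edges, m(m-1)/2;
#   bipartite - each member to the group pseudo-node "complex:<rigid>", m
#               edges;
#   exclude   - n-ary records contribute nothing.

.pair_canonical <- function(a, b) {
  swap <- a > b
  data.frame(node_a = ifelse(swap, b, a), node_b = ifelse(swap, a, b),
             stringsAsFactors = FALSE)
}

new_edge_list <- function(df, id_level, nary_policy, directed) {
  rownames(df) <- NULL
  structure(df, id_level = id_level, nary_policy = nary_policy,
            directed = directed, class = c("edge_list", "data.frame"))
}

#' @export
print.edge_list <- function(x, ...) {
  cat(sprintf("<edge_list> %d edges, %d nodes (%s, %s n-ary policy, %s)\n",
              nrow(x), length(unique(c(x$node_a, x$node_b))),
              attr(x, "id_level"), attr(x, "nary_policy"),
              if (isTRUE(attr(x, "directed"))) "directed" else "undirected"))
  invisible(x)
}

# hub of one complex group: the unique bait member if there is exactly one,
# else the bytewise-smallest member key
.complex_hub <- function(t, rows, id_level) {
  kb <- interactor_keys(t, "b", id_level)[rows]
  baits <- unique(kb[.role_codes(t, "b")[rows] %in% "MI:0496"])
  members <- sort(unique(kb), method = "radix")
  if (length(baits) == 1) baits else members[1]
}

#' Convert MITAB records to a weighted edge list
#'
#' Binary records contribute one edge per distinct unordered interactor pair;
#' complex (n-ary) records are expanded under `nary_policy`; polymer records
#' are excluded unless `self_loops = TRUE`.  An edge's weight counts the
#' distinct source records supporting the pair (a complex group counting as
#' one record), or the distinct supporting publications with
#' `weight_by = "pmids"`.
#'
#' With `directed = TRUE`, binary edges are oriented bait to prey; records
#' without role information are dropped (`rolefree = "drop"`, the default) or
#' kept as unoriented rows flagged in a `has_direction` column.  Spoke edges
#' orient hub to member, bipartite edges pseudo-node to member; the matrix
#' policy has no direction semantics and is an error when `directed = TRUE`.
#'
#' @param t A `mitab_table`.
#' @param nary_policy "exclude", "spoke", "matrix" or "bipartite".
#' @param id_level "rogid" or "crogid" node identifiers.
#' @param directed Orient edges by experimental role?
#' @param weight_by "records" or "pmids".
#' @param rolefree Directed mode only: "drop" or "undirected".
#' @param self_loops Keep self-pairs (polymers, duplicated keys)?
#' @return An `edge_list` data frame (`node_a`, `node_b`, `weight`, plus
#'   `has_direction` when directed) with the policy recorded in attributes.
#'   Undirected rows are stored with `node_a <= node_b`; rows are unique and
#'   sorted.
#' @export
mitab_to_edgelist <- function(t,
                              nary_policy = c("exclude", "spoke", "matrix",
                                              "bipartite"),
                              id_level = c("rogid", "crogid"),
                              directed = FALSE,
                              weight_by = c("records", "pmids"),
                              rolefree = c("drop", "undirected"),
                              self_loops = FALSE) {
  nary_policy <- match.arg(nary_policy)
  id_level <- match.arg(id_level)
  weight_by <- match.arg(weight_by)
  rolefree <- match.arg(rolefree)
  if (directed && nary_policy == "matrix")
    stop("matrix expansion has no direction semantics; use directed = FALSE",
         call. = FALSE)
  cls <- classify_record(t)
  ka <- interactor_keys(t, "a", id_level)
  kb <- interactor_keys(t, "b", id_level)
  rlevel <- if (id_level == "rogid") "rigid" else "crigid"
  pm <- if (weight_by == "pmids") mitab_pmids(t)
  from <- character(0); to <- character(0)
  oriented <- logical(0); support <- character(0)

  add <- function(f, tt, o, s) {
    from <<- c(from, f); to <<- c(to, tt)
    oriented <<- c(oriented, rep(o, length(f)))
    support <<- c(support, s)
  }
  sup_of <- function(i, tag) {
    if (weight_by == "records") tag
    else if (length(pm[[i]])) paste0("pm", pm[[i]]) else paste0("nopm.", tag)
  }

  # binary records
  for (i in which(cls == "binary")) {
    a <- ka[i]; b <- kb[i]
    if (is.na(a) || is.na(b)) next
    if (a == b && !self_loops) next
    o <- FALSE
    if (directed) {
      ra <- .role_codes(t, "a")[i]; rb <- .role_codes(t, "b")[i]
      if (identical(ra, "MI:0496") && identical(rb, "MI:0498")) o <- TRUE
      else if (identical(rb, "MI:0496") && identical(ra, "MI:0498")) {
        tmp <- a; a <- b; b <- tmp; o <- TRUE
      } else if (rolefree == "drop") next
    }
    s <- sup_of(i, paste0("r", i))
    add(rep(a, length(s)), rep(b, length(s)), o, s)
  }

  # polymer records as self-loops, opt-in
  if (self_loops) {
    for (i in which(cls == "polymer")) {
      if (is.na(ka[i])) next
      s <- sup_of(i, paste0("r", i))
      add(rep(ka[i], length(s)), rep(ka[i], length(s)), FALSE, s)
    }
  }

  # n-ary records
  if (nary_policy != "exclude") {
    groups <- .complex_groups(t, rlevel)
    for (g in names(groups)) {
      rows <- groups[[g]]
      members <- sort(unique(kb[rows]), method = "radix")
      members <- members[!is.na(members)]
      if (length(members) < 2 && nary_policy != "bipartite") next
      i0 <- rows[1]
      s1 <- if (weight_by == "records") paste0("C", g) else {
        pms <- sort(unique(unlist(pm[rows])))
        if (length(pms)) paste0("pm", pms) else paste0("nopm.C", g)
      }
      emit <- function(f, tt, o) {
        for (s in s1) add(f, tt, o, rep(s, length(f)))
      }
      if (nary_policy == "spoke") {
        hub <- .complex_hub(t, rows, id_level)
        others <- setdiff(members, hub)
        emit(rep(hub, length(others)), others, directed)
      } else if (nary_policy == "matrix") {
        if (length(members) >= 2) {
          cmb <- utils::combn(members, 2)
          emit(cmb[1, ], cmb[2, ], FALSE)
        }
      } else { # bipartite
        pseudo <- paste0("complex:", g)
        emit(rep(pseudo, length(members)), members, directed)
      }
    }
  }

  if (!length(from)) {
    e <- data.frame(node_a = character(0), node_b = character(0),
                    weight = integer(0), stringsAsFactors = FALSE)
    if (directed) e$has_direction <- logical(0)
    return(new_edge_list(e, id_level, nary_policy, directed))
  }

  canon <- !oriented
  pa <- ifelse(canon & from > to, to, from)
  pb <- ifelse(canon & from > to, from, to)
  inc <- data.frame(node_a = pa, node_b = pb, oriented = oriented,
                    support = support, stringsAsFactors = FALSE)
  inc <- unique(inc)
  key <- paste(inc$node_a, inc$node_b, inc$oriented, sep = "\r")
  agg <- tapply(seq_len(nrow(inc)), key, function(ii) ii[1])
  w <- as.integer(table(key)[names(agg)])
  e <- data.frame(node_a = inc$node_a[agg], node_b = inc$node_b[agg],
                  weight = w, stringsAsFactors = FALSE)
  if (directed) e$has_direction <- inc$oriented[agg]
  e <- e[order(e$node_a, e$node_b, method = "radix"), , drop = FALSE]
  new_edge_list(e, id_level, nary_policy, directed)
}

#' Retrieve the MITAB records matching an edge list
#'
#' The inverse selection: returns the records of `t` whose interactor pair
#' (at the edge list's id level, order ignored) appears in `e`.  Complex
#' groups are retrieved whole when `include_complexes = TRUE` and any edge of
#' their expansion under the edge list's n-ary policy matches.
#'
#' @param e An `edge_list`.
#' @param t The `mitab_table` to subset.
#' @param include_complexes Allow complex groups to be retrieved?
#' @return Sub-table of `t`, original order.
#' @export
edgelist_to_mitab <- function(e, t, include_complexes = FALSE) {
  id_level <- attr(e, "id_level") %||% "rogid"
  pol <- attr(e, "nary_policy") %||% "exclude"
  pairs <- character(0)
  if (nrow(e)) {
    p <- .pair_canonical(e$node_a, e$node_b)
    pairs <- paste(p$node_a, p$node_b, sep = "\r")
  }
  cls <- classify_record(t)
  ka <- interactor_keys(t, "a", id_level)
  kb <- interactor_keys(t, "b", id_level)
  p <- .pair_canonical(ka, kb)
  rowkey <- paste(p$node_a, p$node_b, sep = "\r")
  sel <- cls != "complex" & !is.na(ka) & !is.na(kb) & rowkey %in% pairs
  if (include_complexes && pol != "exclude") {
    sub <- select_interaction_type(t, "complex")
    ec <- mitab_to_edgelist(sub, nary_policy = pol, id_level = id_level)
    if (nrow(ec)) {
      pc <- .pair_canonical(ec$node_a, ec$node_b)
      hit <- paste(pc$node_a, pc$node_b, sep = "\r") %in% pairs
      if (any(hit)) {
        # trace matching expansion edges back to their groups
        rlevel <- if (id_level == "rogid") "rigid" else "crigid"
        groups <- .complex_groups(t, rlevel)
        for (g in names(groups)) {
          eg <- mitab_to_edgelist(.subset_rows(t, groups[[g]]),
                                  nary_policy = pol, id_level = id_level)
          if (!nrow(eg)) next
          pg <- .pair_canonical(eg$node_a, eg$node_b)
          if (any(paste(pg$node_a, pg$node_b, sep = "\r") %in% pairs))
            sel[groups[[g]]] <- TRUE
        }
      }
    }
  }
  .subset_rows(t, sel)
}

new_complex_list <- function(df, id_level) {
  rownames(df) <- NULL
  structure(df, id_level = id_level,
            class = c("complex_list", "data.frame"))
}

#' @export
print.complex_list <- function(x, ...) {
  cat(sprintf("<complex_list> %d complexes (%d reported, %d regenerated), sizes %s\n",
              nrow(x), sum(x$origin == "reported"),
              sum(x$origin == "regenerated"),
              if (nrow(x)) paste(range(lengths(x$members)), collapse = "-")
              else "-"))
  invisible(x)
}

#' Convert MITAB records to a complex list
#'
#' Reported n-ary (`C`) records are grouped by interaction key into one row
#' per complex, with the sorted distinct member ids.  Optionally appends
#' complexes regenerated from binary records that plausibly encode
#' spoke-represented n-ary data: `include_regenerated = "yes"` uses
#' [regenerate_complexes()] over `allowed_methods`, `"conservative"` uses
#' [conservative_preset()] (BioGRID records with MI:0004 affinity
#' chromatography only).
#'
#' @param t A `mitab_table`.
#' @param id_level "rogid" or "crogid" member identifiers.
#' @param include_regenerated "no", "yes" or "conservative".
#' @param allowed_methods MI codes treated as n-ary-producing when
#'   regenerating; defaults to [default_nary_methods()].
#' @param require_bait,min_members Passed to [regenerate_complexes()].
#' @return A `complex_list` data frame: `complex_id`, `members`
#'   (list-column of sorted ids), `origin` ("reported"/"regenerated"),
#'   `num_participants`, plus `hub`, `source_db`, `pmid`, `method` for
#'   regenerated rows.
#' @export
mitab_to_complexlist <- function(t, id_level = c("rogid", "crogid"),
                                 include_regenerated = c("no", "yes",
                                                         "conservative"),
                                 allowed_methods = default_nary_methods(),
                                 require_bait = TRUE, min_members = 3) {
  id_level <- match.arg(id_level)
  include_regenerated <- match.arg(include_regenerated)
  rlevel <- if (id_level == "rogid") "rigid" else "crigid"
  groups <- .complex_groups(t, rlevel)
  members <- .complex_member_keys(t, groups, id_level)
  np <- .num_participants(t)
  rep_df <- data.frame(complex_id = names(groups),
                       origin = rep("reported", length(groups)),
                       num_participants = vapply(groups, function(r) np[r[1]],
                                                 integer(1)),
                       hub = NA_character_, source_db = NA_character_,
                       pmid = NA_integer_, method = NA_character_,
                       stringsAsFactors = FALSE)
  rep_df$members <- unname(members)
  rep_df <- rep_df[order(rep_df$complex_id, method = "radix"), , drop = FALSE]
  out <- rep_df
  if (include_regenerated != "no") {
    rg <- if (include_regenerated == "conservative")
      conservative_preset(t, min_members = min_members, id_level = id_level)
    else
      regenerate_complexes(t, allowed_methods, require_bait = require_bait,
                           min_members = min_members, id_level = id_level)
    if (nrow(rg)) {
      rg_df <- data.frame(complex_id = rg$complex_id,
                          origin = "regenerated",
                          num_participants = lengths(rg$members),
                          hub = rg$hub, source_db = rg$source_db,
                          pmid = rg$pmid, method = rg$method,
                          stringsAsFactors = FALSE)
      rg_df$members <- rg$members
      out <- rbind(rep_df, rg_df[names(rep_df)])
    }
  }
  new_complex_list(out[c("complex_id", "members", "origin",
                         "num_participants", "hub", "source_db", "pmid",
                         "method")], id_level)
}

#' Retrieve the MITAB records matching a complex list
#'
#' Reported rows pull back every `C` record of their interaction group.
#' Regenerated rows (only when `include_regenerated = TRUE`) pull back their
#' supporting binary records: same source database, publication and method,
#' pairing the hub with one of the members.
#'
#' @param cl A `complex_list`.
#' @param t The `mitab_table` to subset.
#' @param include_regenerated Also retrieve supporting records of
#'   regenerated complexes?
#' @return Sub-table of `t`, original order.
#' @export
complexlist_to_mitab <- function(cl, t, include_regenerated = FALSE) {
  id_level <- attr(cl, "id_level") %||% "rogid"
  rlevel <- if (id_level == "rogid") "rigid" else "crigid"
  cls <- classify_record(t)
  rid <- mitab_rigids(t, rlevel)
  rep_ids <- cl$complex_id[cl$origin == "reported"]
  sel <- cls == "complex" & !is.na(rid) & rid %in% rep_ids
  if (include_regenerated && any(cl$origin == "regenerated")) {
    ka <- interactor_keys(t, "a", id_level)
    kb <- interactor_keys(t, "b", id_level)
    mcode <- mitab_method_codes(t)
    dbl <- .norm_db_label(mitab_source_labels(t))
    pms <- mitab_pmids(t)
    for (i in which(cl$origin == "regenerated")) {
      hub <- cl$hub[i]; mem <- cl$members[[i]]
      cand <- which(cls == "binary" &
                    !is.na(mcode) & mcode == cl$method[i] &
                    !is.na(dbl) & dbl == .norm_db_label(cl$source_db[i]))
      for (j in cand) {
        if (!identical(pms[[j]], as.integer(cl$pmid[i]))) next
        pair <- c(ka[j], kb[j])
        if (hub %in% pair && all(pair %in% mem)) sel[j] <- TRUE
      }
    }
  }
  .subset_rows(t, sel)
}

#' Merge complex lists, removing duplicate complexes
#'
#' Duplicates are detected on the sorted member set; the first occurrence's
#' id and origin are kept, so the result is `a`'s rows followed by the novel
#' rows of `b`.
#'
#' @param a,b `complex_list` objects at the same id level.
#' @return A `complex_list`.
#' @export
merge_complex_lists <- function(a, b) {
  la <- attr(a, "id_level"); lb <- attr(b, "id_level")
  if (!is.null(la) && !is.null(lb) && !identical(la, lb))
    stop("cannot merge complex lists at different id levels", call. = FALSE)
  both <- rbind(as.data.frame(a), as.data.frame(b))
  key <- vapply(both$members, paste, character(1), collapse = ",")
  new_complex_list(both[!duplicated(key), , drop = FALSE],
                   la %||% lb %||% "rogid")
}

#' Convert an edge list to an igraph object
#'
#' Nodes are the ids appearing in the edges; weights and (for directed edge
#' lists) orientation are carried over.  Unoriented rows of a directed edge
#' list become reciprocal arc pairs.
#'
#' @param e An `edge_list`.
#' @return An `igraph` graph with the edge list's metadata stored as graph
#'   attributes.
#' @export
edgelist_to_graph <- function(e) {
  directed <- isTRUE(attr(e, "directed"))
  d <- data.frame(from = e$node_a, to = e$node_b, weight = e$weight,
                  stringsAsFactors = FALSE)
  if (directed && "has_direction" %in% names(e)) {
    d$has_direction <- e$has_direction
    undir <- !e$has_direction
    if (any(undir)) {
      back <- d[undir, ]
      names(back)[1:2] <- c("to", "from")
      d <- rbind(d, back[names(d)])
    }
  }
  g <- igraph::graph_from_data_frame(d, directed = directed)
  g <- igraph::set_graph_attr(g, "id_level", attr(e, "id_level") %||% "rogid")
  g <- igraph::set_graph_attr(g, "nary_policy",
                              attr(e, "nary_policy") %||% "exclude")
  g
}

#' Convert an igraph object back to an edge list
#'
#' Exact inverse of [edgelist_to_graph()]: reciprocal unoriented arc pairs
#' collapse back to one row, undirected edges are canonically ordered, rows
#' sorted.
#'
#' @param g An `igraph` graph.
#' @return An `edge_list`.
#' @export
graph_to_edgelist <- function(g) {
  directed <- igraph::is_directed(g)
  d <- igraph::as_data_frame(g, what = "edges")
  if (!nrow(d)) {
    e <- data.frame(node_a = character(0), node_b = character(0),
                    weight = integer(0), stringsAsFactors = FALSE)
    if (directed) e$has_direction <- logical(0)
    return(new_edge_list(e, igraph::graph_attr(g, "id_level") %||% "rogid",
                         igraph::graph_attr(g, "nary_policy") %||% "exclude",
                         directed))
  }
  if (is.null(d$weight)) d$weight <- 1L
  if (directed && !is.null(d$has_direction)) {
    undir <- !d$has_direction
    p <- .pair_canonical(d$from, d$to)
    d$from[undir] <- p$node_a[undir]
    d$to[undir] <- p$node_b[undir]
    d <- unique(d)
  } else if (!directed) {
    p <- .pair_canonical(d$from, d$to)
    d$from <- p$node_a
    d$to <- p$node_b
  }
  e <- data.frame(node_a = d$from, node_b = d$to,
                  weight = as.integer(d$weight), stringsAsFactors = FALSE)
  if (directed)
    e$has_direction <- if (is.null(d$has_direction)) rep(TRUE, nrow(d))
                       else d$has_direction
  e <- e[order(e$node_a, e$node_b, method = "radix"), , drop = FALSE]
  new_edge_list(e, igraph::graph_attr(g, "id_level") %||% "rogid",
                igraph::graph_attr(g, "nary_policy") %||% "exclude", directed)
}
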