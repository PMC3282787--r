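t <- tab_default
man <- man_default

test_that("expansion formulas hold for planted complexes of every size", {
  for (m in 3:12) {
    fx <- generate_mitab(fixture_config(n_binary = 0, n_polymer = 0,
                                        n_ht_screens = 0, ht_screen_size = 0,
                                        spoke_sizes = integer(0),
                                        isoform_groups = integer(0),
                                        complex_sizes = m),
                         seed = 300 + m)
    tt <- fx$table
    expect_equal(nrow(mitab_to_edgelist(tt, "spoke")), m - 1)
    expect_equal(nrow(mitab_to_edgelist(tt, "matrix")), m * (m - 1) / 2)
    expect_equal(nrow(mitab_to_edgelist(tt, "bipartite")), m)
    expect_equal(nrow(mitab_to_edgelist(tt, "exclude")), 0)
  }
})

test_that("spoke edges are a subset of matrix edges for every complex", {
  co <- select_interaction_type(t, "complex")
  es <- mitab_to_edgelist(co, "spoke")
  em <- mitab_to_edgelist(co, "matrix")
  key <- function(e) paste(e$node_a, e$node_b)
  expect_true(all(key(es) %in% key(em)))
})

test_that("binary edges equal brute-force pair enumeration with conserved weight", {
  for (policy in c("exclude", "spoke", "matrix", "bipartite")) {
    e <- mitab_to_edgelist(t, policy)
    inc <- oracle_pair_incidences(t, policy)
    # distinct (pair, support) incidences -> summed weight
    inckey <- unique(vapply(inc, paste, character(1), collapse = "\r"))
    expect_equal(sum(e$weight), length(inckey))
    pairs <- unique(vapply(inc, function(x)
      paste(x[1], x[2], sep = "\r"), character(1)))
    expect_setequal(paste(e$node_a, e$node_b, sep = "\r"), pairs)
    # canonical ordering and no duplicate rows
    expect_true(all(e$node_a <= e$node_b | startsWith(e$node_a, "complex:")))
    expect_false(any(duplicated(paste(e$node_a, e$node_b))))
  }
})

test_that("the spoke hub is the bait, with deterministic fallback", {
  # planted complexes mark their first member as bait
  co <- select_interaction_type(t, "complex")
  groups <- irefkit:::.complex_groups(co)
  kb <- interactor_keys(co, "b", "rogid")
  rb <- irefkit:::.role_codes(co, "b")
  es <- mitab_to_edgelist(co, "spoke", directed = TRUE)
  for (g in names(groups)) {
    bait <- unique(kb[groups[[g]]][rb[groups[[g]]] %in% "MI:0496"])
    if (length(bait) == 1)
      expect_true(all(es$node_a[es$node_a %in% kb[groups[[g]]] &
                                es$node_b %in% kb[groups[[g]]]] == bait))
  }
  # strip roles: hub falls back to the smallest member key
  co2 <- co
  co2[[attr(co, "fields")[["role_b"]]]] <- "-"
  e2 <- mitab_to_edgelist(co2, "spoke")
  members <- sort(unique(kb[groups[[1]]]), method = "radix")
  sub <- e2[e2$node_a %in% members | e2$node_b %in% members, ]
  expect_true(members[1] %in% c(sub$node_a))
})

test_that("directed edge lists orient bait to prey and drop role-less pairs", {
  bi <- select_interaction_type(t, "binary")
  ed <- mitab_to_edgelist(bi, "exclude", directed = TRUE)
  roles <- irefkit:::.role_codes(bi, "a")
  expect_lte(nrow(ed), nrow(mitab_to_edgelist(bi, "exclude")))
  expect_true(all(ed$has_direction))
  # with rolefree = "undirected" nothing is lost
  ek <- mitab_to_edgelist(bi, "exclude", directed = TRUE,
                          rolefree = "undirected")
  eu <- mitab_to_edgelist(bi, "exclude")
  expect_equal(sum(ek$weight), sum(eu$weight))
  expect_error(mitab_to_edgelist(t, "matrix", directed = TRUE), "matrix")
})

test_that("edgelist retrieval recovers exactly the binary subset", {
  e <- mitab_to_edgelist(t, "exclude")
  back <- edgelist_to_mitab(e, t)
  expect_same_records(back, select_interaction_type(t, "binary"))
  empty <- e[integer(0), ]
  expect_equal(nrow(edgelist_to_mitab(empty, t)), 0)
})

test_that("complexes are retrieved whole through matching expansion edges", {
  e <- mitab_to_edgelist(t, "spoke")
  back <- edgelist_to_mitab(e, t, include_complexes = TRUE)
  cls <- classify_record(back)
  expect_equal(sum(cls == "complex"), man$counts$complex_rows)
})

test_that("complex list round-trips recover the C rows", {
  cl <- mitab_to_complexlist(t, "rogid", "no")
  expect_equal(nrow(cl), man$counts$complexes)
  back <- complexlist_to_mitab(cl, t)
  expect_same_records(back, select_interaction_type(t, "complex"))
  # members equal the bipartite member rows
  rep_man <- man$reported_complexes
  for (i in seq_len(nrow(rep_man))) {
    j <- which(cl$complex_id == rep_man$rigid[i])
    expect_identical(cl$members[[j]], rep_man$members[[i]])
  }
  empty <- cl[integer(0), ]
  attr(empty, "id_level") <- "rogid"
  class(empty) <- class(cl)
  expect_equal(nrow(complexlist_to_mitab(empty, t)), 0)
})

test_that("regenerated complexes join the list and map back to their records", {
  cl <- mitab_to_complexlist(t, "rogid", "yes")
  expect_equal(sum(cl$origin == "regenerated"),
               nrow(man$spoke_complexes))
  expect_equal(sum(cl$origin == "reported"), man$counts$complexes)
  back <- complexlist_to_mitab(cl[cl$origin == "regenerated", ], t,
                               include_regenerated = TRUE)
  expect_equal(sort(as.integer(rownames(man$records)[!is.na(man$records$spoke_id)])),
               sort(man$records$row[!is.na(man$records$spoke_id)]))
  expect_equal(nrow(back), sum(!is.na(man$records$spoke_id)))
})

test_that("merging complex lists deduplicates on the member set", {
  cl <- mitab_to_complexlist(t, "rogid", "yes")
  expect_identical(mitab_cells(merge_complex_lists(cl, cl))$complex_id,
                   mitab_cells(cl)$complex_id)
  a <- cl[1:3, ]; b <- cl[3:5, ]
  for (x in c("a", "b")) {
    y <- get(x); attr(y, "id_level") <- "rogid"
    class(y) <- class(cl); assign(x, y)
  }
  m <- merge_complex_lists(a, b)
  expect_equal(nrow(m), 5)
  expect_identical(m$complex_id, cl$complex_id[1:5])
})

test_that("edgelist/graph conversion is an exact inverse", {
  for (args in list(list(policy = "spoke", directed = FALSE),
                    list(policy = "exclude", directed = TRUE),
                    list(policy = "matrix", directed = FALSE))) {
    e <- mitab_to_edgelist(t, args$policy, directed = args$directed)
    g <- edgelist_to_graph(e)
    expect_equal(igraph::vcount(g), length(unique(c(e$node_a, e$node_b))))
    e2 <- graph_to_edgelist(g)
    expect_identical(mitab_cells(e2), mitab_cells(e))
    expect_identical(attr(e2, "id_level"), attr(e, "id_level"))
    expect_identical(attr(e2, "nary_policy"), attr(e, "nary_policy"))
  }
  # single undirected edge
  e1 <- irefkit:::new_edge_list(
    data.frame(node_a = "a", node_b = "b", weight = 1L,
               stringsAsFactors = FALSE), "rogid", "exclude", FALSE)
  g1 <- edgelist_to_graph(e1)
  expect_equal(igraph::vcount(g1), 2)
  expect_equal(igraph::ecount(g1), 1)
})

test_that("canonical-level graphs never have more nodes or edges", {
  for (policy in c("exclude", "spoke", "matrix")) {
    er <- mitab_to_edgelist(t, policy, "rogid")
    ec <- mitab_to_edgelist(t, policy, "crogid")
    expect_lte(length(unique(c(ec$node_a, ec$node_b))),
               length(unique(c(er$node_a, er$node_b))))
    expect_lte(nrow(ec), nrow(er))
  }
})
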