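t <- tab_default
man <- man_default

test_that("bibliometric scores equal the brute-force double loop", {
  st <- compute_bibliometric_scores(t)
  expect_identical(mitab_cells(st), mitab_cells(oracle_scores(t)))
  expect_identical(mitab_cells(st), mitab_cells(man$scores))
  expect_true(all(st$lpr <= st$hpr))
  expect_true(all(st$np >= 1))
  expect_true(all(st$lpr[st$np == 1] == st$hpr[st$np == 1]))
  # across independently generated tables
  for (seed in c(21, 22)) {
    tt <- generate_mitab(seed = seed)$table
    expect_identical(mitab_cells(compute_bibliometric_scores(tt)),
                     mitab_cells(oracle_scores(tt)))
  }
})

test_that("single unique publication gives (np, lpr, hpr) = (1, 1, 1)", {
  rows <- data.frame(a = "p1", b = "p2", db = "dbx", pmid = 3L,
                     method = "MI:0018", bait = NA_character_,
                     stringsAsFactors = FALSE)
  st <- compute_bibliometric_scores(mini_mitab(rows))
  expect_equal(unname(unlist(st[1, c("np", "lpr", "hpr")])), c(1, 1, 1))
})

test_that("a fresh single-use publication pins lpr to 1", {
  # one interaction supported by a screen paper AND its own paper: lpr = 1
  rows <- data.frame(
    a = c(rep("hub", 25), "p1"), b = c(sprintf("m%02d", 1:25), "hub"),
    db = "dbx", pmid = c(rep(500L, 25), 501L), method = "MI:0018",
    bait = NA_character_, stringsAsFactors = FALSE)
  tt <- mini_mitab(rows)
  st <- compute_bibliometric_scores(tt)
  rid <- mitab_rigids(tt)[26]
  expect_equal(st$lpr[st$rigid == rid], 1L)
  expect_equal(st$hpr[st$rigid == rid], 1L)
  screen_rigids <- unique(mitab_rigids(tt)[1:25])
  expect_true(all(st$lpr[st$rigid %in% screen_rigids] ==
                    length(screen_rigids)))
})

test_that("throughput partition is exhaustive and threshold-sensitive", {
  parts <- classify_throughput(t)
  expect_equal(nrow(parts$low) + nrow(parts$high) + nrow(parts$unscored),
               nrow(t))
  st <- man$scores
  lpr <- st$lpr[match(man$records$rigid, st$rigid)]
  expect_equal(nrow(parts$low), sum(!is.na(lpr) & lpr <= 21))
  expect_equal(nrow(parts$high), sum(!is.na(lpr) & lpr > 21))
  everything <- classify_throughput(t, threshold = Inf)
  expect_equal(nrow(everything$high), 0)
  expect_equal(nrow(everything$low), nrow(t) - nrow(everything$unscored))
  # a planted screen (one pmid, many interactions) lands in `high`
  rows <- data.frame(
    a = rep("hub", 30), b = sprintf("m%02d", 1:30),
    db = "dbx", pmid = 5L, method = "MI:0018", bait = NA_character_,
    stringsAsFactors = FALSE)
  tt <- mini_mitab(rows)
  expect_equal(nrow(classify_throughput(tt)$high), 30)
})

test_that("table summaries count what the manifest planted", {
  s <- summary_table(t, taxid = man$config$taxid)
  expect_equal(s$n_records, man$counts$records)
  expect_equal(unname(s$records_by_type),
               c(man$counts$binary, man$counts$complex_rows,
                 man$counts$polymer))
  expect_equal(sum(s$records_by_db), s$n_records)
  expect_equal(unname(s$distinct_proteins),
               c(man$counts$distinct_rogid, man$counts$distinct_crogid))
  expect_equal(unname(s$distinct_interactions),
               c(man$counts$distinct_rigid, man$counts$distinct_crigid))
  expect_equal(s$n_complex_groups, man$counts$complexes)
  expect_equal(unname(s$taxon$at_least_one["records"]), nrow(t))
  empty <- summary_table(t[integer(0), ])
  expect_equal(empty$n_records, 0)
  expect_equal(sum(empty$records_by_type), 0)
})

test_that("protein summaries report partners, complexes and provenance", {
  hub <- man$spoke_complexes$hub[1]
  s <- summary_protein(t, hub, "rogid")
  expect_gte(s$n_partners, man$spoke_complexes$size[1] - 1)
  expect_true(man$spoke_complexes$pmid[1] %in% s$pmids)
  absent <- summary_protein(t, "nosuchkey", "rogid")
  expect_equal(absent$n_records, 0)
  expect_equal(absent$n_partners, 0)
  # partner count bounded by record count on binary-only input
  bi <- select_interaction_type(t, "binary")
  some <- interactor_keys(bi, "a", "rogid")[1]
  sb <- summary_protein(bi, some, "rogid")
  expect_lte(sb$n_partners, sb$n_records)
})

test_that("graph degree summaries match closed forms", {
  path3 <- irefkit:::new_edge_list(
    data.frame(node_a = c("a", "b"), node_b = c("b", "c"),
               weight = c(1L, 1L), stringsAsFactors = FALSE),
    "rogid", "exclude", FALSE)
  s <- summary_graph(edgelist_to_graph(path3))
  expect_equal(s$n, 3)
  expect_equal(s$dav, 4 / 3)
  expect_equal(s$dmax, 2)
  expect_equal(s$dvar, mean((c(1, 2, 1) - 4 / 3)^2))
  star4 <- irefkit:::new_edge_list(
    data.frame(node_a = rep("hub", 4), node_b = paste0("l", 1:4),
               weight = 1L, stringsAsFactors = FALSE),
    "rogid", "exclude", FALSE)
  s2 <- summary_graph(edgelist_to_graph(star4))
  expect_equal(s2$n, 5)
  expect_equal(s2$dav, 8 / 5)
  expect_equal(s2$dmax, 4)
})

test_that("graph summaries match independent recomputation on random graphs", {
  for (seed in 1:20) {
    set.seed(seed)
    n <- sample(5:25, 1)
    pairs <- unique(t(apply(matrix(sample(letters[1:12], 2 * n,
                                          replace = TRUE), ncol = 2),
                            1, sort)))
    pairs <- pairs[pairs[, 1] != pairs[, 2], , drop = FALSE]
    if (!nrow(pairs)) next
    e <- irefkit:::new_edge_list(
      data.frame(node_a = pairs[, 1], node_b = pairs[, 2], weight = 1L,
                 stringsAsFactors = FALSE), "rogid", "exclude", FALSE)
    s <- summary_graph(edgelist_to_graph(e))
    o <- oracle_degree_stats(e)
    expect_equal(s$n, o$n)
    expect_equal(s$dav, o$dav)
    expect_equal(s$dvar, o$dvar)
    expect_equal(s$dmax, o$dmax)
    expect_lte(s$dmax, s$n - 1)
  }
})

test_that("summary_graph fills I/X/C from the source table", {
  e <- mitab_to_edgelist(t, "spoke")
  s <- summary_graph(edgelist_to_graph(e), mitab = t)
  expect_equal(s$I, man$counts$distinct_rigid)
  expect_equal(s$C, man$counts$complexes)
  expect_equal(s$X, length(unique(man$records$rigid[man$records$class ==
                                                      "binary"])))
})

test_that("matrix expansion never lowers the average degree", {
  es <- summary_graph(edgelist_to_graph(mitab_to_edgelist(t, "spoke")))
  em <- summary_graph(edgelist_to_graph(mitab_to_edgelist(t, "matrix")))
  expect_lte(es$dav, em$dav)
})
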