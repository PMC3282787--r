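t <- tab_default
man <- man_default

test_that("interaction-type selection matches planted counts and partitions", {
  expect_same_records(select_interaction_type(t, c("binary", "complex",
                                                   "polymer")), t)
  expect_equal(nrow(select_interaction_type(t, "polymer")),
               man$counts$polymer)
  expect_equal(nrow(select_interaction_type(t, "complex")),
               man$counts$complex_rows)
  ns <- irefkit:::.uid_namespace(irefkit:::.mfield(
    select_interaction_type(t, "complex"), "uid_a"))
  expect_true(all(ns == "complex"))
  expect_error(select_interaction_type(t, character(0)))
})

test_that("database selection works by label, code and exclusion", {
  for (db in unique(man$records$db)) {
    sub <- select_database(t, db)
    expect_equal(nrow(sub), sum(man$records$db == db))
    code <- man$records$db_code[man$records$db == db][1]
    expect_same_records(select_database(t, code), sub)
    # selection and exclusion partition the table
    expect_equal(nrow(sub) + nrow(select_database(t, db, exclude = TRUE)),
                 nrow(t))
  }
  expect_message(empty <- select_database(t, "nosuchdb"), "no records")
  expect_equal(nrow(empty), 0)
})

test_that("protein selection matches the manifest and returns whole complexes", {
  rog <- man$records$rogid_b[1]
  sub <- select_protein(t, rog, "rogid")
  hit <- man$records$rogid_a %in% rog & man$records$class != "complex" |
         man$records$rogid_b %in% rog
  crig <- unique(man$records$rigid[hit & man$records$class == "complex"])
  hit <- hit | (man$records$class == "complex" & man$records$rigid %in% crig)
  expect_equal(nrow(sub), sum(hit))
  # complexes always whole
  cls <- classify_record(sub)
  for (rows in irefkit:::.complex_groups(sub))
    expect_equal(length(rows),
                 sum(man$records$rigid == mitab_rigids(sub)[rows[1]] &
                       man$records$class == "complex"))
  expect_equal(nrow(select_protein(t, "nosuchkey")), 0)
})

test_that("crogid-level protein selection is a superset of rogid-level", {
  iso <- man$isoform_map
  grouped <- iso$rogid[iso$rogid != iso$crogid][1]
  crog <- iso$crogid[iso$rogid == grouped]
  a <- select_protein(t, grouped, "rogid")
  b <- select_protein(t, crog, "crogid")
  keys_a <- paste(mitab_rigids(a), seq_len(nrow(a)))
  expect_true(all(mitab_rigids(a) %in% mitab_rigids(b)))
  expect_gte(nrow(b), nrow(a))
})

test_that("publication selection matches per-pmid manifest counts", {
  all_pm <- unique(unlist(man$records$pmids))
  for (pm in all_pm[1:5]) {
    expect_equal(nrow(select_publication(t, pm)),
                 sum(vapply(man$records$pmids, function(p) pm %in% p,
                            logical(1))))
  }
  expect_equal(nrow(select_publication(t, 1L)), 0)
  expect_equal(nrow(select_publication(t, all_pm)),
               sum(lengths(man$records$pmids) > 0))
})

test_that("method selection matches the manifest; absent methods never match", {
  for (mc in unique(man$records$method))
    expect_equal(nrow(select_method(t, mc)),
                 sum(man$records$method == mc))
  expect_equal(nrow(select_method(t, "MI:9999")), 0)
  t2 <- t
  t2[[attr(t, "fields")[["method"]]]] <- "-"
  expect_equal(nrow(select_method(t2, unique(man$records$method))), 0)
})

test_that("confidence selection recovers the planted low-throughput subset", {
  st <- man$scores
  lo <- select_confidence(t, "lpr", 1, 21)
  lpr <- st$lpr[match(man$records$rigid, st$rigid)]
  expect_equal(nrow(lo), sum(!is.na(lpr) & lpr >= 1 & lpr <= 21))
  expect_equal(nrow(select_confidence(t, "np", 1, Inf)),
               sum(!is.na(lpr)))
  expect_equal(nrow(select_confidence(t, "hpr", 0, 0)), 0)
  expect_error(select_confidence(t, "np", 5, 1), "lo")
  # file-trusting mode agrees here because the generator embeds recomputed
  # scores
  expect_same_records(select_confidence(t, "lpr", 1, 21, recompute = FALSE),
                      lo)
})

test_that("taxon selection distinguishes its two scopes", {
  taxid <- man$config$taxid
  any_t <- select_taxon(t, taxid, "at_least_one")
  all_t <- select_taxon(t, taxid, "all_interactors")
  expect_true(all(mitab_rigids(all_t) %in% mitab_rigids(any_t)))
  expect_lte(nrow(all_t), nrow(any_t))
  inter <- man$records$kind == "interspecies"
  expect_true(any(inter))
  expect_equal(nrow(any_t), nrow(t))  # every record touches the main taxon
  expect_equal(nrow(all_t), nrow(t) - sum(inter))
  expect_equal(nrow(select_taxon(t, 999999, "at_least_one")), 0)
  # interspecies records involve the foreign taxon only under at_least_one
  vir <- select_taxon(t, man$config$foreign_taxid, "at_least_one")
  expect_equal(nrow(vir), sum(inter))
  expect_equal(nrow(select_taxon(t, man$config$foreign_taxid,
                                 "all_interactors")), 0)
})

test_that("selectors are idempotent and commute pairwise", {
  sels <- list(
    type = function(x) select_interaction_type(x, "binary"),
    db = function(x) suppressMessages(select_database(x, "biogrid")),
    tax = function(x) select_taxon(x, man$config$taxid, "all_interactors"),
    meth = function(x) select_method(x, "MI:0004"),
    pub = function(x) select_publication(x, unlist(man$records$pmids)[1:40])
  )
  for (f in sels) expect_same_records(f(f(t)), f(t))
  for (i in seq_along(sels))
    for (j in seq_along(sels))
      if (i < j)
        expect_same_records(sels[[i]](sels[[j]](t)),
                            sels[[j]](sels[[i]](t)))
})
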