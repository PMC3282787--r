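t <- tab_default
man <- man_default

test_that("planted spoke complexes are recovered exactly, nothing else", {
  rg <- regenerate_complexes(t, default_nary_methods())
  expect_equal(nrow(rg), nrow(man$spoke_complexes))
  got <- rg$members[order(vapply(rg$members, paste, character(1),
                                 collapse = ","))]
  want <- man$spoke_complexes$members[
    order(vapply(man$spoke_complexes$members, paste, character(1),
                 collapse = ","))]
  expect_identical(got, want)
  expect_setequal(rg$hub, man$spoke_complexes$hub)
  expect_setequal(rg$pmid, man$spoke_complexes$pmid)
  # every complex is a star around its hub
  ka <- interactor_keys(t, "a", "rogid")
  kb <- interactor_keys(t, "b", "rogid")
  for (i in seq_len(nrow(rg)))
    expect_true(all(rg$hub[i] == ka[rg$support[[i]]] |
                    rg$hub[i] == kb[rg$support[[i]]]))
  expect_error(regenerate_complexes(t, character(0)), "nonempty")
})

test_that("independent binary records sharing nothing regenerate nothing", {
  rows <- data.frame(a = c("p1", "p3", "p5"), b = c("p2", "p4", "p6"),
                     db = "dbx", pmid = 7L, method = "MI:0004", bait = "a",
                     stringsAsFactors = FALSE)
  tt <- mini_mitab(rows)
  expect_equal(nrow(regenerate_complexes(tt, "MI:0004")), 0)
  # greedy mode likewise: max star size is 2 < 3
  expect_equal(nrow(regenerate_complexes(tt, "MI:0004",
                                         require_bait = FALSE)), 0)
})

test_that("bait mode equals the exhaustive oracle on random tables", {
  for (seed in 1:25) {
    tt <- random_star_table(seed)
    rg <- regenerate_complexes(tt, "MI:0004")
    got <- rg$members[order(vapply(rg$members, paste, character(1),
                                   collapse = ","))]
    want <- oracle_regenerate_bait(tt, "MI:0004")
    expect_identical(unname(got), unname(want))
  }
})

test_that("multi-publication records never join a regenerated complex", {
  man2 <- generate_mitab(seed = 11)$manifest
  t2 <- generate_mitab(seed = 11)$table
  multi <- lengths(man2$records$pmids) > 1
  rg <- regenerate_complexes(t2, default_nary_methods())
  sup <- unlist(rg$support)
  expect_false(any(multi[sup]))
})

test_that("greedy mode consumes records once and is permutation-invariant", {
  rows <- data.frame(
    a = c("hub", "hub", "hub", "aux", "aux"),
    b = c("m1", "m2", "aux", "m3", "m4"),
    db = "dbx", pmid = 9L, method = "MI:0004", bait = NA_character_,
    stringsAsFactors = FALSE)
  tt <- mini_mitab(rows)
  rg <- regenerate_complexes(tt, "MI:0004", require_bait = FALSE)
  # hub appears in 3 records -> first complex {hub,m1,m2,aux}; remaining two
  # aux records form {aux,m3,m4}
  expect_equal(nrow(rg), 2)
  sizes <- sort(lengths(rg$members))
  expect_equal(sizes, c(3, 4))
  expect_equal(sort(unlist(lapply(rg$support, length))), c(2, 3))
  # permuting input rows leaves member sets unchanged
  for (perm_seed in 1:5) {
    set.seed(perm_seed)
    tp <- tt[sample(nrow(tt)), ]
    rgp <- regenerate_complexes(tp, "MI:0004", require_bait = FALSE)
    expect_identical(
      rgp$members[order(vapply(rgp$members, paste, character(1),
                               collapse = ","))],
      rg$members[order(vapply(rg$members, paste, character(1),
                              collapse = ","))])
  }
})

test_that("the conservative preset is a BioGrid/MI:0004 restriction", {
  rg_all <- regenerate_complexes(t, default_nary_methods())
  rg_cons <- conservative_preset(t)
  key <- function(x) vapply(x$members, paste, character(1), collapse = ",")
  expect_true(all(key(rg_cons) %in% key(rg_all)))
  expect_true(all(rg_cons$source_db == "biogrid"))
  expect_true(all(rg_cons$method == "MI:0004"))
  want <- man$spoke_complexes[man$spoke_complexes$db == "biogrid", ]
  expect_equal(nrow(rg_cons), nrow(want))
  # BioGrid-free table -> nothing
  nob <- suppressMessages(select_database(t, "biogrid", exclude = TRUE))
  expect_equal(nrow(conservative_preset(nob)), 0)
})

test_that("size distributions and their KS comparison behave", {
  cl <- mitab_to_complexlist(t, "rogid", "no")
  sd <- size_distribution(cl)
  expect_equal(sum(sd$count), nrow(cl))
  expect_identical(sort(rep(sd$size, sd$count)),
                   sort(lengths(cl$members)))
  same <- compare_size_distributions(cl, cl)
  expect_equal(same$D, 0)
  rg <- regenerate_complexes(t, default_nary_methods())
  ks <- compare_size_distributions(cl, rg)
  expect_gte(ks$D, 0); expect_lte(ks$D, 1)
  # cross-check against the direct ECDF + Kolmogorov-series oracle
  or <- oracle_ks2(lengths(cl$members), lengths(rg$members))
  expect_equal(ks$D, or$D, tolerance = 1e-12)
  expect_equal(ks$p_value, or$p_value, tolerance = 1e-6)
  set.seed(99)
  a <- sample(3:12, 40, replace = TRUE)
  b <- sample(3:30, 60, replace = TRUE)
  ks2 <- compare_size_distributions(a, b)
  or2 <- oracle_ks2(a, b)
  expect_equal(ks2$D, or2$D, tolerance = 1e-12)
  expect_equal(ks2$p_value, or2$p_value, tolerance = 1e-6)
})

test_that("throughput class reflects the supporting records' lpr", {
  # a hub star from one screen paper supporting many interactions is high
  rows <- data.frame(
    a = rep("hub", 30), b = sprintf("m%02d", 1:30),
    db = "dbx", pmid = 5L, method = "MI:0004", bait = "a",
    stringsAsFactors = FALSE)
  tt <- mini_mitab(rows)
  rg <- regenerate_complexes(tt, "MI:0004")
  expect_equal(rg$throughput, "high")  # lpr = 30 > 21
  rg2 <- regenerate_complexes(t, default_nary_methods())
  expect_true(all(rg2$throughput == "low"))  # planted spokes cite small papers
})
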