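# Shared fixtures, built in code at load time.

fx_default <- generate_mitab(seed = 101)
tab_default <- fx_default$table
man_default <- fx_default$manifest

# identity canonical map: no isoform groups
fx_flat <- generate_mitab(fixture_config(isoform_groups = integer(0)),
                          seed = 102)

# strip provenance attributes so two tables can be compared cell-by-cell
mitab_cells <- function(t) {
  df <- as.data.frame(t)
  attributes(df) <- attributes(df)[c("names", "row.names", "class")]
  class(df) <- "data.frame"
  df
}

expect_same_records <- function(a, b) {
  expect_identical(mitab_cells(a), mitab_cells(b))
}

# a minimal hand-built table: nb binary rows given as a data.frame with
# columns a, b (protein labels), db, pmid, method, bait ("a", "b" or NA)
mini_mitab <- function(rows, taxid = 4932) {
  cfg <- fixture_config()
  labs <- sort(unique(c(rows$a, rows$b)))
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  seqs <- vapply(seq_along(labs), function(i) paste0(
    strrep(aa[((i - 1) %% 20) + 1], 15),
    strrep(aa[(((i - 1) %/% 20) %% 20) + 1], 15)), character(1))
  rog <- vapply(seqs, irefkit::compute_rogid, character(1), taxid = taxid)
  names(rog) <- labs
  n <- nrow(rows)
  blank <- rep("-", n)
  cells <- data.frame(
    uidA = paste0("uniprotkb:", rows$a), uidB = paste0("uniprotkb:", rows$b),
    altA = blank, altB = blank, aliasA = blank, aliasB = blank,
    method = vapply(rows$method, function(m)
      if (is.na(m)) "-" else paste0(m, "(method)"), character(1)),
    author = blank,
    pmids = ifelse(is.na(rows$pmid), "-", paste0("pubmed:", rows$pmid)),
    taxa = sprintf("taxid:%d(x)", taxid), taxb = sprintf("taxid:%d(x)", taxid),
    interactionType = blank,
    sourcedb = paste0("MI:0000(", rows$db, ")"),
    interactionIdentifier = blank, confidence = blank, expansion = "none",
    biological_role_A = blank, biological_role_B = blank,
    experimental_role_A = ifelse(!is.na(rows$bait) & rows$bait == "a",
                                 "MI:0496(bait)",
                          ifelse(!is.na(rows$bait) & rows$bait == "b",
                                 "MI:0498(prey)", "-")),
    experimental_role_B = ifelse(!is.na(rows$bait) & rows$bait == "b",
                                 "MI:0496(bait)",
                          ifelse(!is.na(rows$bait) & rows$bait == "a",
                                 "MI:0498(prey)", "-")),
    interactor_type_A = blank, interactor_type_B = blank,
    xrefs_A = blank, xrefs_B = blank, xrefs_Interaction = blank,
    Annotations_A = blank, Annotations_B = blank,
    Annotations_Interaction = blank, Host_organism_taxid = blank,
    parameters_Interaction = blank, Creation_date = blank,
    Update_date = blank,
    Checksum_A = paste0("rogid:", rog[rows$a]),
    Checksum_B = paste0("rogid:", rog[rows$b]),
    Checksum_Interaction = paste0("rigid:", vapply(seq_len(n), function(i)
      irefkit::compute_rigid(c(rog[rows$a[i]], rog[rows$b[i]])),
      character(1))),
    Negative = blank, OriginalReferenceA = blank, OriginalReferenceB = blank,
    FinalReferenceA = blank, FinalReferenceB = blank, MappingScoreA = blank,
    MappingScoreB = blank, irogida = blank, irogidb = blank, irigid = blank,
    crogida = rog[rows$a], crogidb = rog[rows$b],
    crigid = vapply(seq_len(n), function(i)
      irefkit::compute_rigid(c(rog[rows$a[i]], rog[rows$b[i]])),
      character(1)),
    icrogida = blank, icrogidb = blank, icrigid = blank, imex_id = blank,
    edgetype = ifelse(rows$a == rows$b, "Y", "X"),
    numParticipants = "2",
    stringsAsFactors = FALSE)
  f <- tempfile(fileext = ".mitab")
  on.exit(unlink(f))
  writeLines(c(paste0("#", paste(names(cells), collapse = "\t")),
               do.call(paste, c(unname(as.list(cells)), sep = "\t"))), f)
  read_mitab(f)
}

# random small binary-only tables for oracle-equivalence runs: a handful of
# proteins, records grouped into few (db, pmid, method) cells, every record
# carrying a bait so the bait path is exercised
random_star_table <- function(seed, n_max = 50) {
  set.seed(seed)
  n <- sample(5:n_max, 1)
  prot <- sprintf("AA%02d", 1:12)
  rows <- data.frame(
    a = sample(prot, n, replace = TRUE),
    b = sample(prot, n, replace = TRUE),
    db = sample(c("dbx", "dby"), n, replace = TRUE),
    pmid = sample(100:104, n, replace = TRUE),
    method = sample(c("MI:0004", "MI:0018"), n, replace = TRUE),
    bait = "a",
    stringsAsFactors = FALSE)
  rows <- rows[rows$a != rows$b, , drop = FALSE]
  mini_mitab(rows)
}
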