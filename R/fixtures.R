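# Synthetic MITAB fixtures with a complete ground-truth manifest.
#
# The generator emulates the structures the package's analyses assume:
# mixtures of binary / n-ary (bipartite-represented) / polymer records,
# bait-prey roles, publication-reuse structure (a few screen publications
# supporting many interactions next to single-use papers), isoform groups
# driving canonical-versus-sequence-specific count ratios, a fraction of
# interspecies records, and planted spoke-represented complexes.  Every
# stochastic choice derives from one integer seed through fixed per-phase
# substreams, so the same seed always yields a byte-identical table and
# manifest, and adding records of one class does not shift the draws of
# another.

.TAXON_NAMES <- c("4932" = "Saccharomyces cerevisiae",
                  "9606" = "Homo sapiens",
                  "11676" = "Human immunodeficiency virus 1",
                  "562" = "Escherichia coli")

.METHOD_LABELS <- c("MI:0004" = "affinity chromatography technology",
                    "MI:0006" = "anti bait coimmunoprecipitation",
                    "MI:0007" = "anti tag coimmunoprecipitation",
                    "MI:0018" = "two hybrid",
                    "MI:0019" = "coimmunoprecipitation",
                    "MI:0096" = "pull down",
                    "MI:0114" = "x-ray crystallography",
                    "MI:0401" = "biochemical",
                    "MI:0676" = "tandem affinity purification")

.DB_CODES <- c(biogrid = "MI:0463", intact = "MI:0469", mint = "MI:0471",
               dip = "MI:0465", bind = "MI:0462")

.taxon_cell <- function(taxid) {
  if (is.na(taxid)) return("-")
  nm <- .TAXON_NAMES[as.character(taxid)]
  sprintf("taxid:%d(%s)", taxid,
          if (is.na(nm)) paste0("taxon ", taxid) else nm)
}

.method_cell <- function(code) {
  if (is.na(code) || code == "-") return("-")
  lab <- .METHOD_LABELS[code]
  sprintf("%s(%s)", code, if (is.na(lab)) "unknown" else lab)
}

.role_cell <- function(code) {
  switch(code,
         "MI:0496" = "MI:0496(bait)",
         "MI:0498" = "MI:0498(prey)",
         "-")
}

#' Configuration for the synthetic MITAB generator
#'
#' Defaults describe a small yeast-like interactome slice: a pool of 40
#' yeast proteins (plus a few viral ones for interspecies records), 90
#' binary records of which two blocks of 25 come from screen publications
#' (so their recomputed lpr exceeds the conventional low-throughput cut of
#' 21) and the rest from single-use papers, five reported complexes, three
#' polymers, three planted spoke-represented complexes (two from BioGRID,
#' one from MINT, all affinity chromatography, one publication each), and
#' three isoform groups sharing a canonical key.  Background binary records
#' use methods outside [default_nary_methods()] so that planted spoke
#' complexes are the only regenerable structures under the defaults.
#'
#' @param taxid Main organism NCBI taxon id.
#' @param foreign_taxid Second organism for interspecies records.
#' @param n_proteins,n_foreign_proteins Protein pool sizes.
#' @param seq_length Amino-acid sequence length for generated proteins.
#' @param n_binary Background binary record count.
#' @param interspecies_fraction Fraction of background binary records with
#'   one foreign interactor.
#' @param bait_fraction Fraction of background binary records carrying
#'   bait/prey roles.
#' @param multi_pmid_fraction Fraction of single-paper records given a
#'   second supporting publication (np = 2).
#' @param n_ht_screens,ht_screen_size Number and size of screen
#'   publications; each screen is one PubMed id supporting
#'   `ht_screen_size` records.
#' @param n_polymer Polymer (Y) record count.
#' @param complex_sizes Integer sizes (>= 3) of reported n-ary records.
#' @param spoke_sizes Integer sizes (>= 3, hub included) of planted
#'   spoke-represented complexes.
#' @param spoke_dbs Source database per planted spoke complex (recycled).
#' @param spoke_method Detection method of planted spoke records.
#' @param isoform_groups Sizes of canonical groups (>= 2 members each).
#' @param databases Named character vector label -> MI code.
#' @param binary_methods MI codes for background binary records.
#' @param nary_methods MI codes for reported n-ary records.
#' @param embed_scores Write recomputed np/lpr/hpr into the confidence
#'   column?
#' @return A `fixture_config` list.
#' @export
fixture_config <- function(taxid = 4932,
                           foreign_taxid = 11676,
                           n_proteins = 40,
                           n_foreign_proteins = 4,
                           seq_length = 60,
                           n_binary = 90,
                           interspecies_fraction = 0.1,
                           bait_fraction = 0.5,
                           multi_pmid_fraction = 0.1,
                           n_ht_screens = 2,
                           ht_screen_size = 25,
                           n_polymer = 3,
                           complex_sizes = c(3, 4, 5, 6, 8),
                           spoke_sizes = c(4, 5, 6),
                           spoke_dbs = c("biogrid", "biogrid", "mint"),
                           spoke_method = "MI:0004",
                           isoform_groups = c(3, 2, 2),
                           databases = .DB_CODES,
                           binary_methods = c("MI:0018", "MI:0114",
                                              "MI:0401"),
                           nary_methods = c("MI:0004", "MI:0676"),
                           embed_scores = TRUE) {
  cfg <- as.list(environment())
  for (f in c("taxid", "foreign_taxid", "n_proteins", "n_foreign_proteins",
              "seq_length", "n_binary", "n_ht_screens", "ht_screen_size",
              "n_polymer", "complex_sizes", "spoke_sizes", "isoform_groups"))
    cfg[[f]] <- as.integer(cfg[[f]])
  if (any(cfg$complex_sizes < 3))
    stop("complex sizes must be >= 3 (validation error)", call. = FALSE)
  if (any(cfg$spoke_sizes < 3))
    stop("spoke complex sizes must be >= 3 (validation error)", call. = FALSE)
  if (length(cfg$isoform_groups) && any(cfg$isoform_groups < 2))
    stop("isoform groups need >= 2 members (validation error)", call. = FALSE)
  if (sum(cfg$isoform_groups) > cfg$n_proteins)
    stop("isoform groups exceed the protein pool (validation error)",
         call. = FALSE)
  if (cfg$interspecies_fraction < 0 || cfg$interspecies_fraction > 1 ||
      cfg$bait_fraction < 0 || cfg$bait_fraction > 1)
    stop("fractions must lie in [0, 1] (validation error)", call. = FALSE)
  if (cfg$n_ht_screens * cfg$ht_screen_size > cfg$n_binary)
    stop("screen records exceed n_binary (validation error)", call. = FALSE)
  if (cfg$n_proteins < max(3, cfg$complex_sizes, cfg$spoke_sizes))
    stop("protein pool too small for the requested complexes",
         call. = FALSE)
  class(cfg) <- "fixture_config"
  cfg
}

.phase_seed <- function(seed, phase) {
  as.integer((as.numeric(seed) * 131L + phase * 7919) %% 2147483647)
}

#' Generate a synthetic MITAB table with ground truth
#'
#' Deterministically builds a valid `mitab_table` (passing
#' [validate_mitab()]) together with a manifest recording every planted
#' structure, so that any derived quantity the package computes can be
#' checked against the generator's own bookkeeping.
#'
#' @param config A [fixture_config()] (or a list of overrides for it).
#' @param seed Integer seed; the same (config, seed) pair always produces a
#'   byte-identical table and manifest.
#' @return List with elements `table` (the `mitab_table`) and `manifest`, a
#'   list holding: `proteins` (pool with sequences, accessions, keys),
#'   `records` (per-record ground truth: class, database, method,
#'   publications, roles, taxa, keys, planted-complex membership),
#'   `reported_complexes`, `spoke_complexes`, `isoform_map`, `id_table`
#'   (expected accession lookup rows), `scores` (np/lpr/hpr recomputed by an
#'   independent double loop), and `counts` (expected distinct-entity
#'   tallies).
#' @export
generate_mitab <- function(config = fixture_config(), seed = 1) {
  if (!inherits(config, "fixture_config"))
    config <- do.call(fixture_config, config)
  cfg <- config

  ## phase 1: protein pool ---------------------------------------------
  set.seed(.phase_seed(seed, 1))
  n_all <- cfg$n_proteins + cfg$n_foreign_proteins
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  prot <- data.frame(
    id = sprintf("P%03d", seq_len(n_all)),
    taxid = c(rep(cfg$taxid, cfg$n_proteins),
              rep(cfg$foreign_taxid, cfg$n_foreign_proteins)),
    uniprot = sprintf("Q%05d", 10000 + seq_len(n_all)),
    geneid = as.character(850000 + seq_len(n_all)),
    refseq = sprintf("NP_%06d", 100000 + seq_len(n_all)),
    stringsAsFactors = FALSE)
  prot$sequence <- vapply(seq_len(n_all), function(i)
    paste(sample(aa, cfg$seq_length, replace = TRUE), collapse = ""),
    character(1))
  prot$rogid <- vapply(seq_len(n_all), function(i)
    compute_rogid(prot$sequence[i], prot$taxid[i]), character(1))
  prot$crogid <- prot$rogid
  g0 <- 0L
  for (k in cfg$isoform_groups) {
    members <- (g0 + 1L):(g0 + k)
    prot$crogid[members] <- prot$rogid[members[1]]
    g0 <- g0 + k
  }
  main_idx <- which(prot$taxid == cfg$taxid)
  foreign_idx <- which(prot$taxid == cfg$foreign_taxid)

  pmid_counter <- 20000000L
  next_pmid <- function() {
    pmid_counter <<- pmid_counter + 1L
    pmid_counter
  }

  rec <- list()  # internal ledger, one entry per output row
  add_rec <- function(...) rec[[length(rec) + 1L]] <<- list(...)

  ## phase 2: background binary records --------------------------------
  set.seed(.phase_seed(seed, 2))
  ht_pmids <- vapply(seq_len(cfg$n_ht_screens), function(i) next_pmid(),
                     integer(1))
  n_inter <- round(cfg$n_binary * cfg$interspecies_fraction)
  n_ht <- cfg$n_ht_screens * cfg$ht_screen_size
  for (i in seq_len(cfg$n_binary)) {
    inter <- i > cfg$n_binary - n_inter
    if (inter && length(foreign_idx)) {
      a <- sample(main_idx, 1)
      b <- sample(foreign_idx, 1)
    } else {
      ab <- sample(main_idx, 2)
      a <- ab[1]; b <- ab[2]
    }
    db <- sample(names(cfg$databases), 1)
    method <- sample(cfg$binary_methods, 1)
    withroles <- stats::runif(1) < cfg$bait_fraction
    pm <- if (i <= n_ht) ht_pmids[ceiling(i / cfg$ht_screen_size)]
          else {
            p <- next_pmid()
            if (stats::runif(1) < cfg$multi_pmid_fraction) c(p, next_pmid())
            else p
          }
    add_rec(class = "binary", kind = if (inter) "interspecies" else "background",
            a = a, b = b, db = db, method = method,
            role_a = if (withroles) "MI:0496" else "-",
            role_b = if (withroles) "MI:0498" else "-",
            pmids = sort(pm), spoke_id = NA_integer_,
            complex_rigid = NA_character_)
  }

  ## phase 3: polymer records ------------------------------------------
  set.seed(.phase_seed(seed, 3))
  for (i in seq_len(cfg$n_polymer)) {
    a <- sample(main_idx, 1)
    add_rec(class = "polymer", kind = "polymer", a = a, b = a,
            db = sample(names(cfg$databases), 1),
            method = sample(cfg$binary_methods, 1),
            role_a = "-", role_b = "-", pmids = next_pmid(),
            spoke_id = NA_integer_, complex_rigid = NA_character_)
  }

  ## phase 4: reported n-ary records (bipartite C rows) ----------------
  set.seed(.phase_seed(seed, 4))
  reported <- list()
  for (ci in seq_along(cfg$complex_sizes)) {
    m <- cfg$complex_sizes[ci]
    members <- sort(sample(main_idx, m))
    rigid <- compute_rigid(prot$rogid[members])
    crigid <- compute_rigid(unique(prot$crogid[members]))
    db <- sample(c("intact", "dip", "mint"), 1)
    method <- sample(cfg$nary_methods, 1)
    pm <- next_pmid()
    reported[[ci]] <- list(rigid = rigid, crigid = crigid,
                           members = members, size = m, db = db,
                           method = method, pmid = pm)
    for (j in seq_along(members)) {
      add_rec(class = "complex", kind = "complex_member",
              a = NA_integer_, b = members[j], db = db, method = method,
              role_a = "-",
              role_b = if (j == 1) "MI:0496" else "MI:0498",
              pmids = pm, spoke_id = NA_integer_, complex_rigid = rigid,
              complex_crigid = crigid, num_participants = m)
    }
  }

  ## phase 5: planted spoke-represented complexes ----------------------
  set.seed(.phase_seed(seed, 5))
  spoke_dbs <- rep_len(cfg$spoke_dbs, length(cfg$spoke_sizes))
  spokes <- list()
  for (si in seq_along(cfg$spoke_sizes)) {
    m <- cfg$spoke_sizes[si]
    mem <- sample(main_idx, m)
    hub <- mem[1]; preys <- sort(mem[-1])
    pm <- next_pmid()
    spokes[[si]] <- list(hub = hub, preys = preys, size = m,
                         db = spoke_dbs[si], method = cfg$spoke_method,
                         pmid = pm)
    for (p in preys)
      add_rec(class = "binary", kind = "spoke", a = hub, b = p,
              db = spoke_dbs[si], method = cfg$spoke_method,
              role_a = "MI:0496", role_b = "MI:0498", pmids = pm,
              spoke_id = si, complex_rigid = NA_character_)
  }

  ## assemble ----------------------------------------------------------
  nrec <- length(rec)
  get <- function(fld, default = NA) {
    vapply(rec, function(r) {
      v <- r[[fld]]
      if (is.null(v)) default else v
    }, default)
  }
  cls <- get("class", NA_character_)
  ia <- get("a", NA_integer_)
  ib <- get("b", NA_integer_)
  rogid_a <- ifelse(is.na(ia), NA_character_, prot$rogid[ia])
  rogid_b <- prot$rogid[ib]
  crogid_a <- ifelse(is.na(ia), NA_character_, prot$crogid[ia])
  crogid_b <- prot$crogid[ib]
  rigid <- character(nrec)
  crigid <- character(nrec)
  for (i in seq_len(nrec)) {
    if (cls[i] == "complex") {
      rigid[i] <- rec[[i]]$complex_rigid
      crigid[i] <- rec[[i]]$complex_crigid
    } else if (cls[i] == "polymer") {
      rigid[i] <- compute_rigid(rogid_a[i])
      crigid[i] <- compute_rigid(crogid_a[i])
    } else {
      rigid[i] <- compute_rigid(c(rogid_a[i], rogid_b[i]))
      crigid[i] <- compute_rigid(unique(c(crogid_a[i], crogid_b[i])))
    }
  }
  pmid_list <- lapply(rec, function(r) as.integer(r$pmids))

  # independent double-loop recomputation of np / lpr / hpr
  scores <- .manifest_scores(rigid, pmid_list)

  irog <- function(x) {
    u <- sort(unique(stats::na.omit(x)), method = "radix")
    as.integer(match(x, u))
  }
  irogida <- irog(rogid_a); irogidb <- irog(rogid_b)
  icrogida <- irog(crogid_a); icrogidb <- irog(crogid_b)
  irigid <- irog(rigid); icrigid <- irog(crigid)

  conf <- rep("-", nrec)
  if (cfg$embed_scores) {
    hit <- match(rigid, scores$rigid)
    ok <- !is.na(hit)
    conf[ok] <- sprintf("np:%d|lpr:%d|hpr:%d", scores$np[hit[ok]],
                        scores$lpr[hit[ok]], scores$hpr[hit[ok]])
  }

  np_col <- vapply(seq_len(nrec), function(i) {
    if (cls[i] == "complex") as.integer(rec[[i]]$num_participants) else 2L
  }, integer(1))

  uid_a <- ifelse(cls == "complex", paste0("complex:", rigid),
                  paste0("uniprotkb:", prot$uniprot[ia]))
  alt_a <- ifelse(cls == "complex", "-",
                  paste0("entrezgene/locuslink:", prot$geneid[ia],
                         "|refseq:", prot$refseq[ia]))
  cells <- data.frame(
    uidA = uid_a,
    uidB = paste0("uniprotkb:", prot$uniprot[ib]),
    altA = alt_a,
    altB = paste0("entrezgene/locuslink:", prot$geneid[ib],
                  "|refseq:", prot$refseq[ib]),
    aliasA = "-",
    aliasB = "-",
    method = vapply(get("method", NA_character_), .method_cell, character(1)),
    author = "-",
    pmids = vapply(pmid_list, function(p)
      paste(paste0("pubmed:", p), collapse = "|"), character(1)),
    taxa = ifelse(cls == "complex", "-",
                  vapply(prot$taxid[ifelse(is.na(ia), 1L, ia)],
                         .taxon_cell, character(1))),
    taxb = vapply(prot$taxid[ib], .taxon_cell, character(1)),
    interactionType = "MI:0915(physical association)",
    sourcedb = sprintf("%s(%s)", cfg$databases[get("db", NA_character_)],
                       get("db", NA_character_)),
    interactionIdentifier = sprintf("rigid:%s|irigid:%d|crigid:%s|icrigid:%d",
                                    rigid, irigid, crigid, icrigid),
    confidence = conf,
    expansion = ifelse(cls == "complex", "bipartite", "none"),
    biological_role_A = "MI:0499(unspecified role)",
    biological_role_B = "MI:0499(unspecified role)",
    experimental_role_A = vapply(get("role_a", "-"), .role_cell, character(1)),
    experimental_role_B = vapply(get("role_b", "-"), .role_cell, character(1)),
    interactor_type_A = ifelse(cls == "complex", "MI:0315(protein complex)",
                               "MI:0326(protein)"),
    interactor_type_B = "MI:0326(protein)",
    xrefs_A = "-", xrefs_B = "-", xrefs_Interaction = "-",
    Annotations_A = "-", Annotations_B = "-", Annotations_Interaction = "-",
    Host_organism_taxid = "-", parameters_Interaction = "-",
    Creation_date = "2026-01-01", Update_date = "2026-01-01",
    Checksum_A = paste0("rogid:", ifelse(cls == "complex", rigid, rogid_a)),
    Checksum_B = paste0("rogid:", rogid_b),
    Checksum_Interaction = paste0("rigid:", rigid),
    Negative = "false",
    OriginalReferenceA = "-", OriginalReferenceB = "-",
    FinalReferenceA = "-", FinalReferenceB = "-",
    MappingScoreA = "-", MappingScoreB = "-",
    irogida = as.character(ifelse(cls == "complex", irigid, irogida)),
    irogidb = as.character(irogidb),
    irigid = as.character(irigid),
    crogida = ifelse(cls == "complex", crigid, crogid_a),
    crogidb = crogid_b,
    crigid = crigid,
    icrogida = as.character(ifelse(cls == "complex", icrigid, icrogida)),
    icrogidb = as.character(icrogidb),
    icrigid = as.character(icrigid),
    imex_id = "-",
    edgetype = c(binary = "X", complex = "C", polymer = "Y")[cls],
    numParticipants = as.character(np_col),
    stringsAsFactors = FALSE)
  stopifnot(identical(names(cells), .irefindex_columns_8))
  tab <- new_mitab_table(cells, "irefindex_8.0",
                         meta = list(source = "irefkit generator",
                                     seed = seed, skipped = 0L))

  ## manifest ----------------------------------------------------------
  records <- data.frame(
    row = seq_len(nrec), class = cls, kind = get("kind", NA_character_),
    db = get("db", NA_character_),
    db_code = unname(cfg$databases[get("db", NA_character_)]),
    method = get("method", NA_character_),
    role_a = get("role_a", "-"), role_b = get("role_b", "-"),
    taxon_a = ifelse(is.na(ia), NA_integer_, prot$taxid[ia]),
    taxon_b = prot$taxid[ib],
    rogid_a = rogid_a, rogid_b = rogid_b,
    crogid_a = crogid_a, crogid_b = crogid_b,
    rigid = rigid, crigid = crigid,
    spoke_id = get("spoke_id", NA_integer_),
    stringsAsFactors = FALSE)
  records$pmids <- pmid_list

  used <- sort(unique(c(ia[!is.na(ia)], ib)))
  id_rows <- do.call(rbind, lapply(used, function(i) {
    data.frame(rogid = prot$rogid[i], crogid = prot$crogid[i],
               namespace = c("uniprotkb", "entrezgene/locuslink", "refseq",
                             "rogid", "crogid"),
               accession = c(prot$uniprot[i], prot$geneid[i], prot$refseq[i],
                             prot$rogid[i], prot$crogid[i]),
               stringsAsFactors = FALSE)
  }))
  id_rows <- id_rows[order(id_rows$rogid, id_rows$namespace,
                           id_rows$accession, method = "radix"), ]
  rownames(id_rows) <- NULL

  reported_df <- data.frame(
    rigid = vapply(reported, `[[`, character(1), "rigid"),
    crigid = vapply(reported, `[[`, character(1), "crigid"),
    size = vapply(reported, `[[`, integer(1), "size"),
    db = vapply(reported, `[[`, character(1), "db"),
    method = vapply(reported, `[[`, character(1), "method"),
    pmid = vapply(reported, `[[`, integer(1), "pmid"),
    stringsAsFactors = FALSE)
  reported_df$members <- lapply(reported, function(r)
    sort(prot$rogid[r$members], method = "radix"))

  spoke_df <- data.frame(
    spoke_id = seq_along(spokes),
    hub = vapply(spokes, function(s) prot$rogid[s$hub], character(1)),
    size = vapply(spokes, `[[`, integer(1), "size"),
    db = vapply(spokes, `[[`, character(1), "db"),
    method = vapply(spokes, `[[`, character(1), "method"),
    pmid = vapply(spokes, `[[`, integer(1), "pmid"),
    stringsAsFactors = FALSE)
  spoke_df$members <- lapply(spokes, function(s)
    sort(prot$rogid[c(s$hub, s$preys)], method = "radix"))

  notC <- cls != "complex"
  counts <- list(
    records = nrec,
    binary = sum(cls == "binary"),
    complex_rows = sum(cls == "complex"),
    complexes = length(reported),
    polymer = sum(cls == "polymer"),
    spoke_records = sum(!is.na(records$spoke_id)),
    distinct_rogid = length(unique(c(rogid_a[notC], rogid_b))),
    distinct_crogid = length(unique(c(crogid_a[notC], crogid_b))),
    distinct_rigid = length(unique(rigid)),
    distinct_crigid = length(unique(crigid)))

  manifest <- list(seed = seed, config = cfg, proteins = prot,
                   records = records, reported_complexes = reported_df,
                   spoke_complexes = spoke_df,
                   isoform_map = data.frame(rogid = prot$rogid,
                                            crogid = prot$crogid,
                                            stringsAsFactors = FALSE),
                   id_table = id_rows, scores = scores, counts = counts)
  list(table = tab, manifest = manifest)
}

# brute-force double loop over interactions and publications; kept separate
# from compute_bibliometric_scores() on purpose (manifest ground truth)
.manifest_scores <- function(rigids, pmid_list) {
  has <- lengths(pmid_list) > 0
  urig <- sort(unique(rigids[has]), method = "radix")
  pm_of <- lapply(urig, function(rg)
    sort(unique(unlist(pmid_list[has & rigids == rg]))))
  all_pm <- sort(unique(unlist(pm_of)))
  reuse <- vapply(all_pm, function(p)
    sum(vapply(pm_of, function(ps) p %in% ps, logical(1))), integer(1))
  np <- lengths(pm_of)
  lpr <- vapply(pm_of, function(ps) min(reuse[match(ps, all_pm)]), integer(1))
  hpr <- vapply(pm_of, function(ps) max(reuse[match(ps, all_pm)]), integer(1))
  out <- data.frame(rigid = urig, np = np, lpr = lpr, hpr = hpr,
                    stringsAsFactors = FALSE)
  class(out) <- c("score_table", "data.frame")
  out
}

#' Generate a deterministic degree sample
#'
#' Test inputs for the power-law machinery: discrete power-law, shifted
#' geometric (`rgeom + 1`) or shifted Poisson (`rpois + 1`) samples.
#'
#' @param dist "powerlaw", "geometric" or "poisson".
#' @param params Named list: `alpha`/`xmin` for powerlaw, `prob` for
#'   geometric, `lambda` for poisson.
#' @param n Sample size.
#' @param seed Integer seed.
#' @return Integer vector of length `n`, all values `>= 1`.
#' @export
generate_degree_sample <- function(dist = c("powerlaw", "geometric",
                                            "poisson"),
                                   params = list(), n, seed = 1) {
  dist <- match.arg(dist)
  set.seed(seed)
  switch(dist,
         powerlaw = sample_discrete_powerlaw(params$alpha %||% 2.5,
                                             params$xmin %||% 1, n),
         geometric = stats::rgeom(n, params$prob %||% 0.1) + 1L,
         poisson = stats::rpois(n, params$lambda %||% 5) + 1L)
}
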