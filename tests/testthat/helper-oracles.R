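# Independent brute-force oracles.  Each recomputes a quantity from first
# principles, sharing no code path with the implementation it checks.

# np / lpr / hpr by explicit double loop over interactions and publications
oracle_scores <- function(t) {
  rid <- mitab_rigids(t)
  pms <- mitab_pmids(t)
  keep <- !is.na(rid) & lengths(pms) > 0
  urig <- sort(unique(rid[keep]), method = "radix")
  sup <- lapply(urig, function(rg) sort(unique(unlist(pms[keep & rid == rg]))))
  res <- data.frame(rigid = urig, np = NA_integer_, lpr = NA_integer_,
                    hpr = NA_integer_, stringsAsFactors = FALSE)
  for (i in seq_along(urig)) {
    reuse <- vapply(sup[[i]], function(p)
      sum(vapply(sup, function(ps) p %in% ps, logical(1))), integer(1))
    res$np[i] <- length(sup[[i]])
    res$lpr[i] <- min(reuse)
    res$hpr[i] <- max(reuse)
  }
  res
}

# exhaustive bait-mode complex regeneration: enumerate every
# (db, pmid, method, bait) cell over eligible records and collect members
oracle_regenerate_bait <- function(t, allowed_methods, min_members = 3) {
  cls <- classify_record(t)
  mcode <- mitab_method_codes(t)
  pms <- mitab_pmids(t)
  dbl <- mitab_source_labels(t)
  ka <- interactor_keys(t, "a", "rogid")
  kb <- interactor_keys(t, "b", "rogid")
  ra <- irefkit:::.role_codes(t, "a")
  rb <- irefkit:::.role_codes(t, "b")
  out <- list()
  elig <- which(cls == "binary" & mcode %in% allowed_methods &
                lengths(pms) == 1)
  if (!length(elig)) return(out)
  bait <- ifelse(ra[elig] %in% "MI:0496" & !(rb[elig] %in% "MI:0496"),
                 ka[elig],
          ifelse(rb[elig] %in% "MI:0496" & !(ra[elig] %in% "MI:0496"),
                 kb[elig], NA))
  key <- paste(dbl[elig], vapply(pms[elig], `[`, integer(1), 1),
               mcode[elig], bait)
  for (cell in unique(key[!is.na(bait)])) {
    rows <- elig[key == cell & !is.na(bait)]
    mem <- sort(unique(c(ka[rows], kb[rows])), method = "radix")
    if (length(mem) >= min_members) out[[length(out) + 1L]] <- mem
  }
  # canonical order for set comparison
  out[order(vapply(out, paste, character(1), collapse = ","))]
}

# all record-pair incidences at rogid level (binary + expanded complexes)
oracle_pair_incidences <- function(t, policy) {
  cls <- classify_record(t)
  ka <- interactor_keys(t, "a", "rogid")
  kb <- interactor_keys(t, "b", "rogid")
  rid <- mitab_rigids(t)
  inc <- list()
  for (i in which(cls == "binary")) {
    if (is.na(ka[i]) || is.na(kb[i]) || ka[i] == kb[i]) next
    p <- sort(c(ka[i], kb[i]))
    inc[[length(inc) + 1L]] <- c(p, paste0("r", i))
  }
  if (policy != "exclude") {
    for (g in unique(rid[cls == "complex"])) {
      rows <- which(cls == "complex" & rid == g)
      mem <- sort(unique(kb[rows]))
      pairs <- if (policy == "matrix") {
        if (length(mem) >= 2) combn(mem, 2, simplify = FALSE) else list()
      } else if (policy == "spoke") {
        baits <- unique(kb[rows][irefkit:::.role_codes(t, "b")[rows] %in% "MI:0496"])
        hub <- if (length(baits) == 1) baits else mem[1]
        lapply(setdiff(mem, hub), function(o) sort(c(hub, o)))
      } else { # bipartite
        lapply(mem, function(o) sort(c(paste0("complex:", g), o)))
      }
      for (p in pairs)
        inc[[length(inc) + 1L]] <- c(p, paste0("C", g))
    }
  }
  inc
}

# degree statistics recomputed directly from an edge data frame
oracle_degree_stats <- function(edges) {
  nodes <- unique(c(edges$node_a, edges$node_b))
  deg <- vapply(nodes, function(v)
    sum(edges$node_a == v) + sum(edges$node_b == v), integer(1))
  list(n = length(nodes), dav = mean(deg),
       dvar = mean((deg - mean(deg))^2), dmax = max(deg))
}

# two-sample KS: D by direct ECDF enumeration, p by the Kolmogorov series
oracle_ks2 <- function(a, b) {
  grid <- sort(unique(c(a, b)))
  Fa <- vapply(grid, function(g) mean(a <= g), numeric(1))
  Fb <- vapply(grid, function(g) mean(b <= g), numeric(1))
  D <- max(abs(Fa - Fb))
  lambda <- sqrt(length(a) * length(b) / (length(a) + length(b))) * D
  k <- 1:100
  p <- 2 * sum((-1)^(k - 1) * exp(-2 * k^2 * lambda^2))
  list(D = D, p_value = max(0, min(1, p)))
}

# Hurwitz zeta by direct summation plus a midpoint-rule integral tail
# (deliberately a different correction than the implementation uses)
oracle_hurwitz <- function(s, a, upper = 1e5) {
  k <- 0:(upper - 1)
  sum((a + k)^(-s)) + (a + upper - 0.5)^(1 - s) / (s - 1)
}

# discrete power-law fit with Brent optimization of the direct-sum
# likelihood (independent zeta and independent optimizer)
oracle_plfit <- function(x, min_tail = 10, alpha_range = c(1.01, 6)) {
  best <- NULL
  for (m in sort(unique(x))) {
    tail <- x[x >= m]
    n <- length(tail)
    if (n < min_tail) next
    S <- sum(log(tail))
    opt <- stats::optimize(function(a)
      -n * log(oracle_hurwitz(a, m)) - a * S,
      interval = alpha_range, maximum = TRUE, tol = 1e-6)
    alpha <- opt$maximum
    grid <- m:max(tail)
    cdf <- cumsum(grid^(-alpha)) / oracle_hurwitz(alpha, m)
    uq <- sort(unique(tail))
    ec <- cumsum(tabulate(match(sort(tail), uq))) / n
    D <- max(abs(ec - cdf[uq - m + 1]))
    if (is.null(best) || D < best$D - 1e-12)
      best <- list(alpha = alpha, xmin = m, ntail = n, D = D)
  }
  best
}
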