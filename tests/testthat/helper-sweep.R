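# Seeded synthetic sweep shared by the acceptance tests: 200 datasets over
# the three graph models, n in 50..2000, blank ratios {0, .25, .5, 1}, each
# split (in memory) for m in {1, 2, 5, 10}. Results are computed once per
# test run and cached; the triple sets themselves are not retained.

.sweep_cache <- new.env(parent = emptyenv())

# TRUE iff each distinct value of `a` pairs with exactly one value of `b`
one_to_one_of <- function(a, b) {
  if (!length(a)) return(TRUE)
  length(unique(paste0(a, "\r", b))) == length(unique(a))
}

sweep_specs <- function() {
  if (!is.null(.sweep_cache$specs)) return(.sweep_cache$specs)
  ratios <- c(0, 0.25, 0.5, 1)
  models <- c("random", "watts_strogatz", "barabasi_albert")
  specs <- list()
  add <- function(model, n, ratio, seed, p = NULL) {
    specs[[length(specs) + 1L]] <<- list(model = model, n = n, ratio = ratio,
                                         seed = seed, p = p)
  }
  s <- 74000L
  # grid A: all models, n up to 2000
  for (model in models) for (r in ratios) for (n in c(50, 100, 200, 500, 1000, 2000)) {
    s <- s + 1L
    # ER at the reference probability is near-empty below n ~ 2000; use a
    # mean-degree-2 probability for half the ER cells to exercise structure
    p <- if (model == "random" && n <= 500) 2 / n else NULL
    add(model, n, r, s, p)
  }
  # grid B: all models, small n, two further replicates
  for (rep in 1:2) for (model in models) for (r in ratios) for (n in c(50, 150, 300)) {
    s <- s + 1L
    add(model, n, r, s, if (model == "random") 2 / n else NULL)
  }
  # grid C: the two cheap models, intermediate n
  for (model in c("random", "watts_strogatz")) for (r in ratios) {
    for (n in c(60, 120, 240, 480, 960, 1920)) {
      s <- s + 1L
      add(model, n, r, s, if (model == "random") 0.0005 else NULL)
    }
  }
  # grid D: large preferential-attachment graphs
  for (r in ratios) for (n in c(1500, 2000)) {
    s <- s + 1L
    add("barabasi_albert", n, r, s)
  }
  stopifnot(length(specs) == 200L)
  .sweep_cache$specs <- specs
  specs
}

sweep_make_ts <- function(sp) {
  spec <- synthetic_graph_spec(sp$model, n = sp$n, p = sp$p,
                               blank_ratio = sp$ratio, seed = sp$seed)
  edges <- generate_graph(spec)
  label_graph(edges, sp$ratio)          # continues the seeded RNG stream
}

# route triples to bins without touching the filesystem, mirroring the
# pass-2 logic: blank groups by assignment, plain triples by per-bin quota
bins_for <- function(part, asg) {
  k <- part$n_blank_groups
  bins <- integer(length(part$group))
  blank <- part$group <= k & k > 0L
  if (any(blank)) bins[blank] <- asg$bin_of_group[part$group[blank]]
  plainq <- asg$plain_added
  if (is.null(plainq)) plainq <- rep(0L, asg$m)
  bins[!blank] <- rep.int(seq_along(plainq), plainq)
  bins
}

# exhaustive bipartition check of one group: every two-way split of its
# triples must share a blank label across the cut
bipartitions_share_blank <- function(lab_sets) {
  s <- length(lab_sets)
  if (s < 2L) return(TRUE)
  for (mask in 0:(2L^(s - 1L) - 2L)) {
    inA <- c(TRUE, bitwAnd(mask, bitwShiftL(1L, 0:(s - 2L))) > 0L)
    a <- unique(unlist(lab_sets[inA], use.names = FALSE))
    b <- unique(unlist(lab_sets[!inA], use.names = FALSE))
    if (!length(intersect(a, b))) return(FALSE)
  }
  TRUE
}

# igraph-based connectivity oracle: components of the triple/label incidence
# graph must coincide with the blank groups of the partition
groups_match_incidence_components <- function(ts, part) {
  bl <- which(part$classes != "plain")
  if (!length(bl)) return(TRUE)
  sb <- ts$subj_kind[bl] == "blank"
  ob <- ts$obj_kind[bl] == "blank"
  e1 <- if (any(sb)) cbind(sprintf("t%d", bl[sb]), paste0("L", ts$subject[bl][sb]))
  e2 <- if (any(ob)) cbind(sprintf("t%d", bl[ob]), paste0("L", ts$object[bl][ob]))
  edges <- rbind(e1, e2)
  g <- igraph::graph_from_edgelist(edges, directed = FALSE)
  memb <- igraph::components(g)$membership
  cm <- memb[sprintf("t%d", bl)]
  identical(canon_partition(cm), canon_partition(part$group[bl]))
}

sweep_results <- function() {
  if (!is.null(.sweep_cache$res)) return(.sweep_cache$res)
  specs <- sweep_specs()
  ms <- c(1L, 2L, 5L, 10L)
  ds_rows <- vector("list", length(specs))
  m_rows <- list()
  for (si in seq_along(specs)) {
    sp <- specs[[si]]
    ts <- sweep_make_ts(sp)
    part <- build_partition(ts)
    k <- part$n_blank_groups
    n_plain <- sum(part$classes == "plain")

    # Proposition 1, from the triples themselves: each blank label's
    # occurrences all fall in a single group
    occ_lab <- c(ts$subject[ts$subj_kind == "blank"], ts$object[ts$obj_kind == "blank"])
    occ_grp <- c(part$group[ts$subj_kind == "blank"], part$group[ts$obj_kind == "blank"])
    prop1_ok <- one_to_one_of(occ_lab, occ_grp)
    disjoint_ok <- sum(lengths(part$group_blanks)) ==
      length(unique(unlist(part$group_blanks, use.names = FALSE)))

    prop2_conn <- groups_match_incidence_components(ts, part)

    # exhaustive bipartition check on small groups (every 5th dataset)
    prop2_bipart <- NA
    if (si %% 5L == 1L && k > 0L) {
      prop2_bipart <- TRUE
      small <- which(tabulate(part$group, k) >= 2L & tabulate(part$group, k) <= 12L)
      for (g in head(small, 25L)) {
        idx <- which(part$group == g)
        lab_sets <- lapply(idx, function(i) {
          c(if (ts$subj_kind[i] == "blank") ts$subject[i],
            if (ts$obj_kind[i] == "blank") ts$object[i])
        })
        if (!bipartitions_share_blank(lab_sets)) { prop2_bipart <- FALSE; break }
      }
    }

    n_blanks <- length(unique(occ_lab))
    prof_orig <- blank_profile(ts)
    iso_ok <- NA
    for (m in ms) {
      asg <- if (k > 0L) suppressWarnings(lpt_assign(part$group_sizes[seq_len(k)], m))
             else bnsplit:::empty_bin_assignment(m)
      asg <- distribute_plain_fast(asg, n_plain)
      bins <- bins_for(part, asg)
      cover_ok <- length(bins) == nrow(ts) && all(bins >= 1L & bins <= m) &&
        identical(tabulate(bins, m), as.integer(round(asg$bin_sizes)))
      # no blank label in two output files
      occ_bin <- c(bins[ts$subj_kind == "blank"], bins[ts$obj_kind == "blank"])
      label_one_file <- one_to_one_of(occ_lab, occ_bin)
      spl <- lapply(seq_len(m), function(j) ts[bins == j, , drop = FALSE])
      cons_ok <- identical(sort(ts$raw_line),
                           sort(unlist(lapply(spl, `[[`, "raw_line"), use.names = FALSE)))
      prof_ok <- profiles_match(prof_orig, blank_profile(spl))
      lb_ok <- asg$makespan >= ceiling(nrow(ts) / m) - 1e-9 &&
        (k == 0L || asg$makespan >= max(part$group_sizes[seq_len(k)]))
      if (m == 2L && n_blanks <= 20L && nrow(ts) > 0L) {
        iso_ok <- isTRUE(check_isomorphic(ts, spl))
      }
      m_rows[[length(m_rows) + 1L]] <- data.frame(
        dataset = si, m = m, cover_ok = cover_ok, label_one_file = label_one_file,
        cons_ok = cons_ok, prof_ok = prof_ok, lb_ok = lb_ok)
    }
    ds_rows[[si]] <- data.frame(
      dataset = si, model = sp$model, n = sp$n, ratio = sp$ratio,
      triples = nrow(ts), n_blanks = n_blanks,
      prop1_ok = prop1_ok, disjoint_ok = disjoint_ok,
      prop2_conn = prop2_conn, prop2_bipart = prop2_bipart, iso_ok = iso_ok)
  }
  res <- list(datasets = do.call(rbind, ds_rows), runs = do.call(rbind, m_rows))
  .sweep_cache$res <- res
  res
}
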