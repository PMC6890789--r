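ta_fix <- make_toy_atlas(seed = 5)
ont_fix <- ta_fix$ontology
tab_fix <- ta_fix$connectivity

test_that("connectivity tables validate schema and consistency on load", {
  f <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(tab_fix, f, row.names = FALSE)
  tab <- read_connectivity_table(f)
  expect_equal(nrow(tab), nrow(tab_fix))
  expect_equal(tab$normalized_projection_volume,
               tab_fix$normalized_projection_volume)
  bad <- tab_fix
  bad$normalized_projection_volume[1] <-
    bad$normalized_projection_volume[1] * 3
  utils::write.csv(bad, f, row.names = FALSE)
  expect_error(read_connectivity_table(f), "inconsistent")
  dup <- rbind(tab_fix, tab_fix[1, ])
  utils::write.csv(dup, f, row.names = FALSE)
  expect_error(read_connectivity_table(f), "duplicate")
  other <- tab_fix
  other$strain <- "BALB/c"
  utils::write.csv(other, f, row.names = FALSE)
  expect_equal(nrow(read_connectivity_table(f)), 0L)  # strain filter
})

test_that("experiment lookup falls back to the nearest ancestor", {
  # direct hit
  inj <- tab_fix$injection_structure_id[1]
  hit <- find_injection_experiment(inj, tab_fix, ont_fix)
  expect_equal(hit$matched_structure_id, inj)
  # experiments exist only at injection_depth; deeper labels resolve to the
  # unique ancestor at that depth (exhaustive ancestor-scan oracle)
  deep <- ont_fix$nodes$id[ont_fix$nodes$depth >= 4]
  for (id in deep) {
    hit <- find_injection_experiment(id, tab_fix, ont_fix)
    chain <- c(id, ancestors(ont_fix, id)$id)
    oracle <- chain[chain %in% tab_fix$injection_structure_id][1]
    expect_equal(hit$matched_structure_id, oracle)
    expect_true(hit$experiment_id %in%
                  tab_fix$experiment_id[tab_fix$injection_structure_id ==
                                          oracle])
  }
  # no experiment anywhere up the chain
  none <- find_injection_experiment(ont_fix$root,
                                    tab_fix[0, ], ont_fix)
  expect_true(is.na(none$experiment_id))
})

test_that("ranked targets apply filters and ordering like a brute-force oracle", {
  simple <- tibble::tibble(
    experiment_id = 1L, injection_structure_id = 8L,
    target_structure_id = c(101L, 102L, 103L),
    hemisphere = "ipsi",
    normalized_projection_volume = c(0.5, 0.9, 0.1))
  ont_flat <- ontology(data.frame(
    id = c(1L, 8L, 101L, 102L, 103L),
    parent_id = c(NA, 1L, 8L, 1L, 1L),
    depth = c(0L, 1L, 5L, 6L, 7L), order = c(0L, 5L, 6L, 7L, 8L)))
  rt <- ranked_targets(1L, simple, ont_flat, min_depth = 5, min_order = 6)
  # 101 is a child of the injection structure: excluded; rest sorted desc
  expect_equal(rt$target_structure_id, c(102L, 103L))
  expect_equal(rt$normalized_projection_volume, c(0.9, 0.1))
  expect_error(ranked_targets(99L, simple, ont_flat), "unknown experiment")
})

test_that("ranked targets equal the oracle on 50 random synthetic tables", {
  set.seed(71)
  all_ids <- ont_fix$nodes$id
  for (rep in 1:50) {
    inj <- sample(ont_fix$nodes$id[ont_fix$nodes$depth == 3], 1)
    tgt <- sample(setdiff(all_ids, inj), 12)
    tab <- tibble::tibble(experiment_id = 7L, injection_structure_id = inj,
                          target_structure_id = tgt, hemisphere = "ipsi",
                          normalized_projection_volume =
                            round(runif(12), 4))
    excl <- if (rep %% 3 == 0) sample(tgt, 2) else NULL
    rt <- ranked_targets(7L, tab, ont_fix, min_depth = 5, min_order = 6,
                         exclude_ids = excl)
    # independent brute-force filter-and-sort
    nd <- ont_fix$nodes[match(tab$target_structure_id, ont_fix$nodes$id), ]
    desc <- clarityatlas:::descendant_ids(ont_fix, inj)
    keep <- nd$depth >= 5 & nd$order >= 6 &
      !(tab$target_structure_id %in% c(inj, desc)) &
      !(tab$target_structure_id %in% excl)
    oracle <- tab[keep, ]
    oracle <- oracle[order(-oracle$normalized_projection_volume,
                           oracle$target_structure_id), ]
    expect_equal(rt$target_structure_id, oracle$target_structure_id)
    expect_equal(rt$normalized_projection_volume,
                 oracle$normalized_projection_volume)
    # filtering never reorders: output is a subsequence of unfiltered sort
    full <- tab[order(-tab$normalized_projection_volume,
                      tab$target_structure_id), ]
    expect_false(is.unsorted(match(rt$target_structure_id,
                                   full$target_structure_id)))
  }
})

test_that("projection matrices assemble per-row ranked targets", {
  inj_ids <- ont_fix$nodes$id[ont_fix$nodes$depth == 5][1:5]
  pm <- projection_matrix(inj_ids, tab_fix, ont_fix, top_k = 5,
                          min_depth = 3, min_order = 0)
  for (lid in inj_ids) {
    hit <- find_injection_experiment(lid, tab_fix, ont_fix)
    rt <- utils::head(ranked_targets(hit$experiment_id, tab_fix, ont_fix,
                                     injection_structure =
                                       hit$matched_structure_id,
                                     min_depth = 3, min_order = 0), 5)
    rows <- pm[pm$injection_id == lid, ]
    expect_equal(rows$target_structure_id, rt$target_structure_id)
    expect_equal(rows$normalized_projection_volume,
                 rt$normalized_projection_volume)
  }
  wide <- projection_matrix_wide(pm)
  expect_equal(nrow(wide), 5L)
  # unresolvable injection becomes an NA row
  pm2 <- projection_matrix(ont_fix$root, tab_fix[0, ], ont_fix)
  expect_true(is.na(pm2$experiment_id))
})

test_that("common targets rank by frequency with strength tie-breaks", {
  ont_flat <- ontology(data.frame(
    id = 1:8, parent_id = c(NA, rep(1L, 7)),
    depth = c(0, rep(1, 7)), order = 0:7))
  tab <- tibble::tibble(
    experiment_id = rep(1:3, each = 2),
    injection_structure_id = rep(2:4, each = 2),
    target_structure_id = c(5L, 6L, 5L, 7L, 5L, 8L),
    hemisphere = "ipsi",
    normalized_projection_volume = c(0.1, 0.9, 0.2, 0.8, 0.3, 0.8))
  ct <- common_targets(2:4, tab, ont_flat, n = 10,
                       min_depth = 0, min_order = 0)
  expect_equal(ct$target_structure_id[1], 5L)   # present in all three
  expect_equal(ct$n_injections[1], 3L)
  # ties (6, 7, 8 each once) broken by mean strength desc then id asc
  expect_equal(ct$target_structure_id[-1], c(6L, 7L, 8L))
  expect_true(all(ct$n_injections <= 3))
  # brute-force tally on the fixture table
  ct2 <- common_targets(unique(tab_fix$injection_structure_id), tab_fix,
                        ont_fix, n = 50, min_depth = 3, min_order = 0)
  pm <- projection_matrix(unique(tab_fix$injection_structure_id), tab_fix,
                          ont_fix, top_k = Inf, min_depth = 3,
                          min_order = 0)
  tally <- table(pm$target_structure_id)
  for (k in seq_len(nrow(ct2)))
    expect_equal(ct2$n_injections[k],
                 unname(tally[[as.character(ct2$target_structure_id[k])]]))
})

test_that("degeneration reports join the 2-SD flags onto targets", {
  inj <- unique(tab_fix$injection_structure_id)[1:2]
  pm <- projection_matrix(inj, tab_fix, ont_fix, top_k = Inf,
                          hemisphere = "ipsi", min_depth = 3, min_order = 0)
  ids <- unique(pm$target_structure_id)
  dens <- tibble::tibble(id = ids,
                         normalized_density = rep(1, length(ids)),
                         degeneration = 1, flagged = FALSE)
  rep1 <- degeneration_report(inj, tab_fix, ont_fix, dens,
                              min_depth = 3, min_order = 0)
  expect_true(all(!rep1$flagged[!is.na(rep1$flagged)]))
  # one collapsed region at 0.4 among values near 1 is the only flag
  set.seed(81)
  vals <- c(1 + rnorm(length(ids) - 1, sd = 0.02), 0.4)
  dens2 <- normalize_and_flag(
    tibble::tibble(id = ids, density = vals),
    tibble::tibble(id = ids, density = rep(1, length(ids))))
  rep2 <- degeneration_report(inj, tab_fix, ont_fix, dens2,
                              min_depth = 3, min_order = 0)
  flagged_ids <- unique(rep2$target_structure_id[which(rep2$flagged)])
  expect_equal(flagged_ids, ids[length(ids)])
  # absent target: NA marker
  dens3 <- dens[-1, ]
  rep3 <- degeneration_report(inj, tab_fix, ont_fix, dens3,
                              min_depth = 3, min_order = 0)
  expect_true(any(is.na(rep3$normalized_density)))
})

test_that("graph export drops sub-threshold links and counts nodes", {
  pm <- tibble::tibble(injection_id = c(1L, 1L, 2L, 2L),
                       target_structure_id = c(10L, 11L, 10L, 12L),
                       normalized_projection_volume = c(0.9, 0.05, 0.5,
                                                        0.2))
  g <- export_graph(pm, threshold = 0.1)
  expect_length(g$links, 3L)
  expect_length(g$nodes, 4L)  # node 11's only link is sub-threshold
  g2 <- export_graph(pm, threshold = 1)
  expect_length(g2$links, 0L)
  # link count equals supra-threshold entries; JSON written when asked
  f <- withr::local_tempfile(fileext = ".json")
  export_graph(pm, threshold = 0.1, path = f)
  doc <- jsonlite::fromJSON(f, simplifyDataFrame = FALSE)
  expect_length(doc$links, sum(pm$normalized_projection_volume > 0.1))
})
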