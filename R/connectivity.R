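#' Read a projection-connectivity table
#'
#' One row per (experiment, target) pair, in the schema of viral-tracing
#' connectivity exports: `experiment_id`, `injection_structure_id`,
#' `injection_volume_mm3`, `target_structure_id`, `hemisphere`
#' (`ipsi`/`contra`), `strain`, `projection_volume`,
#' `normalized_projection_volume` (projection volume divided by tracer
#' volume in the injection structure; recomputed consistency is checked on
#' load). The wild-type strain restriction (`C57BL/6J`) is applied by
#' default, mirroring the atlas query the analysis is built on.
#'
#' @param path CSV file path.
#' @param strain strain filter; `NULL` disables it.
#' @param tol relative tolerance for the normalized-volume consistency
#'   check.
#' @return A tibble of connectivity records.
#' @export
read_connectivity_table <- function(path, strain = "C57BL/6J", tol = 1e-6) {
  tab <- tibble::as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
  required <- c("experiment_id", "injection_structure_id",
                "target_structure_id", "normalized_projection_volume")
  missing <- setdiff(required, names(tab))
  if (length(missing))
    stop("connectivity table lacks column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  if (!is.null(strain) && "strain" %in% names(tab))
    tab <- tab[tab$strain == strain, ]
  if (all(c("projection_volume", "injection_volume_mm3") %in% names(tab))) {
    ok <- is.na(tab$projection_volume) | is.na(tab$injection_volume_mm3) |
      abs(tab$normalized_projection_volume -
            tab$projection_volume / tab$injection_volume_mm3) <=
      tol * pmax(1, abs(tab$normalized_projection_volume))
    if (!all(ok))
      stop("normalized_projection_volume inconsistent with ",
           "projection_volume / injection_volume in ", sum(!ok), " row(s)",
           call. = FALSE)
  }
  if (anyDuplicated(tab[, c("experiment_id", "target_structure_id")]))
    stop("duplicate (experiment, target) pair(s) in connectivity table",
         call. = FALSE)
  if (!"hemisphere" %in% names(tab)) {
    warning("no hemisphere column; treating all records as ipsilateral")
    tab$hemisphere <- "ipsi"
  }
  tab
}

#' Find the injection experiment for a label, with parent fallback
#'
#' Returns the experiment whose injection structure is the label itself;
#' if none exists, the label's ancestors are searched nearest-first until
#' an experiment-bearing structure is found. When a structure hosts
#' several experiments the one with the largest injection volume (ties:
#' smallest experiment id) is chosen.
#'
#' @param label_id structure id to resolve.
#' @param table connectivity tibble from [read_connectivity_table()].
#' @param ont an [ontology()].
#' @return List with `experiment_id` and `matched_structure_id`, or both
#'   `NA` when no ancestor up to the root has an experiment.
#' @export
find_injection_experiment <- function(label_id, table, ont) {
  chain <- c(label_id, ancestors(ont, label_id)$id)
  for (sid in chain) {
    hits <- table[table$injection_structure_id == sid, , drop = FALSE]
    if (nrow(hits)) {
      if ("injection_volume_mm3" %in% names(hits))
        hits <- hits[order(-hits$injection_volume_mm3,
                           hits$experiment_id), ]
      return(list(experiment_id = hits$experiment_id[1],
                  matched_structure_id = as.integer(sid)))
    }
  }
  list(experiment_id = NA_integer_, matched_structure_id = NA_integer_)
}

descendant_ids <- function(ont, id) {
  out <- integer(0)
  frontier <- id
  kids <- split(ont$nodes$id, factor(ont$nodes$parent_id,
                                     levels = ont$nodes$id))
  while (length(frontier)) {
    ch <- unlist(kids[as.character(frontier)], use.names = FALSE)
    ch <- ch[!is.na(ch)]
    out <- c(out, ch)
    frontier <- ch
  }
  out
}

#' Ranked projection targets of an injection experiment
#'
#' Targets are sorted by decreasing normalized projection volume after
#' removing (a) major structures with ontology graph depth < `min_depth`
#' or graph order < `min_order` (keeping mid-ontology detail structures),
#' (b) descendants of the injection structure (targets inside the
#' injection site itself), and (c) optionally, structures named in
#' `exclude_ids` (e.g. regions overlapping any lesion mask). Ties are
#' broken by ascending structure id.
#'
#' @param experiment_id experiment to rank.
#' @param table connectivity tibble.
#' @param ont an [ontology()].
#' @param injection_structure id of the experiment's injection structure;
#'   defaults to the table's record.
#' @param min_depth,min_order ontology filters (defaults 5 and 6).
#' @param exclude_ids optional structure ids to drop.
#' @param hemisphere optional filter (`"ipsi"`/`"contra"`).
#' @return Tibble of targets with `target_structure_id`,
#'   `normalized_projection_volume`, `rank`.
#' @export
ranked_targets <- function(experiment_id, table, ont,
                           injection_structure = NULL,
                           min_depth = 5, min_order = 6,
                           exclude_ids = NULL, hemisphere = NULL) {
  rec <- table[table$experiment_id == experiment_id, , drop = FALSE]
  if (nrow(rec) == 0) stop("unknown experiment: ", experiment_id,
                           call. = FALSE)
  if (is.null(injection_structure))
    injection_structure <- rec$injection_structure_id[1]
  if (!is.null(hemisphere)) rec <- rec[rec$hemisphere == hemisphere, ]
  nodes <- ontology_node(ont, rec$target_structure_id)
  keep <- nodes$depth >= min_depth & nodes$order >= min_order
  desc <- descendant_ids(ont, injection_structure)
  keep <- keep & !(rec$target_structure_id %in% c(injection_structure, desc))
  if (!is.null(exclude_ids))
    keep <- keep & !(rec$target_structure_id %in% exclude_ids)
  rec <- rec[keep, , drop = FALSE]
  rec <- rec[order(-rec$normalized_projection_volume,
                   rec$target_structure_id), ]
  tibble::tibble(target_structure_id = rec$target_structure_id,
                 normalized_projection_volume =
                   rec$normalized_projection_volume,
                 rank = seq_len(nrow(rec)))
}

#' Projection matrix for a set of injection labels
#'
#' Each row is an injection label (resolved to an experiment via
#' [find_injection_experiment()]); columns hold its `top_k` ranked targets
#' as `<target_id>:<weight>` entries in a long tibble. Unresolvable labels
#' yield `NA` rows.
#'
#' @param injection_label_ids structure ids of the injections.
#' @param table connectivity tibble.
#' @param ont an [ontology()].
#' @param top_k targets kept per injection.
#' @param ... passed to [ranked_targets()].
#' @return Long tibble with `injection_id`, `experiment_id`,
#'   `matched_structure_id`, `rank`, `target_structure_id`,
#'   `normalized_projection_volume`.
#' @export
projection_matrix <- function(injection_label_ids, table, ont, top_k = 5,
                              ...) {
  rows <- lapply(injection_label_ids, function(lid) {
    hit <- find_injection_experiment(lid, table, ont)
    if (is.na(hit$experiment_id))
      return(tibble::tibble(injection_id = lid,
                            experiment_id = NA_integer_,
                            matched_structure_id = NA_integer_,
                            rank = NA_integer_,
                            target_structure_id = NA_integer_,
                            normalized_projection_volume = NA_real_))
    rt <- ranked_targets(hit$experiment_id, table, ont,
                         injection_structure = hit$matched_structure_id,
                         ...)
    rt <- utils::head(rt, top_k)
    tibble::tibble(injection_id = lid, experiment_id = hit$experiment_id,
                   matched_structure_id = hit$matched_structure_id,
                   rank = rt$rank,
                   target_structure_id = rt$target_structure_id,
                   normalized_projection_volume =
                     rt$normalized_projection_volume)
  })
  do.call(rbind, rows)
}

#' Spread a long projection matrix into wide form
#'
#' @param pm long tibble from [projection_matrix()].
#' @return Numeric matrix, rows = injections, columns = rank slots.
#' @export
projection_matrix_wide <- function(pm) {
  inj <- unique(pm$injection_id)
  kmax <- max(pm$rank, na.rm = TRUE)
  m <- matrix(NA_real_, length(inj), kmax,
              dimnames = list(inj, paste0("rank", seq_len(kmax))))
  ok <- !is.na(pm$rank)
  m[cbind(match(pm$injection_id[ok], inj), pm$rank[ok])] <-
    pm$normalized_projection_volume[ok]
  m
}

#' Most common targets across injection labels
#'
#' Targets ranked by how many injections list them (after the usual
#' depth/order and child filters), with ties broken by mean normalized
#' projection volume (descending) and then ascending id.
#'
#' @param injection_label_ids structure ids of the injections.
#' @param table connectivity tibble.
#' @param ont an [ontology()].
#' @param n maximum number of targets returned.
#' @param ... passed to [ranked_targets()].
#' @return Tibble with `target_structure_id`, `n_injections`,
#'   `mean_normalized_projection_volume`.
#' @export
common_targets <- function(injection_label_ids, table, ont, n = 50, ...) {
  pm <- projection_matrix(injection_label_ids, table, ont, top_k = Inf, ...)
  pm <- pm[!is.na(pm$target_structure_id), , drop = FALSE]
  if (nrow(pm) == 0)
    return(tibble::tibble(target_structure_id = integer(0),
                          n_injections = integer(0),
                          mean_normalized_projection_volume = numeric(0)))
  agg <- stats::aggregate(
    normalized_projection_volume ~ target_structure_id,
    data = pm, FUN = mean)
  freq <- stats::aggregate(injection_id ~ target_structure_id, data = pm,
                           FUN = function(x) length(unique(x)))
  out <- tibble::tibble(
    target_structure_id = agg$target_structure_id,
    n_injections = freq$injection_id[match(agg$target_structure_id,
                                           freq$target_structure_id)],
    mean_normalized_projection_volume = agg$normalized_projection_volume)
  out <- out[order(-out$n_injections,
                   -out$mean_normalized_projection_volume,
                   out$target_structure_id), ]
  utils::head(out, n)
}

#' Cellular degeneration along the connectivity tree
#'
#' For each injection label, its (ipsilateral) projection targets are
#' annotated with the control-normalized cell density and the two-standard-
#' deviation degeneration flag from [normalize_and_flag()]; targets absent
#' from the density table are listed with `NA`.
#'
#' @param injection_label_ids structure ids of the injections.
#' @param table connectivity tibble.
#' @param ont an [ontology()].
#' @param density_table tibble from [normalize_and_flag()].
#' @param ... passed to [ranked_targets()] (e.g. `exclude_ids`).
#' @return Tibble with `injection_id`, `target_structure_id`, `rank`,
#'   `normalized_density`, `flagged` (`NA` when the target is absent).
#' @export
degeneration_report <- function(injection_label_ids, table, ont,
                                density_table, ...) {
  pm <- projection_matrix(injection_label_ids, table, ont, top_k = Inf,
                          hemisphere = "ipsi", ...)
  i <- match(pm$target_structure_id, density_table$id)
  tibble::tibble(injection_id = pm$injection_id,
                 target_structure_id = pm$target_structure_id,
                 rank = pm$rank,
                 normalized_density = density_table$normalized_density[i],
                 flagged = density_table$flagged[i])
}

#' Export a connectivity weight table as a node-link graph document
#'
#' Produces the JSON consumed by static network-graph viewers: nodes carry
#' the structure id, acronym and group (injection vs target); links carry
#' the weight, with links at or below `threshold` dropped.
#'
#' @param pm long tibble from [projection_matrix()] (or any tibble with
#'   `injection_id`, `target_structure_id`, and a weight column).
#' @param threshold minimum (exclusive) link weight.
#' @param ont optional [ontology()] for acronyms.
#' @param path optional output path; when given the JSON is written there.
#' @param weight_col name of the weight column.
#' @return The graph as a list (`nodes`, `links`); written as JSON when
#'   `path` is given.
#' @export
export_graph <- function(pm, threshold = 0, ont = NULL, path = NULL,
                         weight_col = "normalized_projection_volume") {
  pm <- pm[!is.na(pm$target_structure_id) &
             pm[[weight_col]] > threshold, , drop = FALSE]
  ids <- unique(c(pm$injection_id, pm$target_structure_id))
  acro <- if (!is.null(ont)) ontology_node(ont, ids)$acronym
  else paste0("S", ids)
  nodes <- lapply(seq_along(ids), function(i) {
    list(id = ids[i], acronym = acro[i],
         group = if (ids[i] %in% pm$injection_id) "injection" else "target")
  })
  links <- lapply(seq_len(nrow(pm)), function(r) {
    list(source = pm$injection_id[r], target = pm$target_structure_id[r],
         weight = pm[[weight_col]][r])
  })
  graph <- list(nodes = nodes, links = links)
  if (!is.null(path))
    jsonlite::write_json(graph, path, auto_unbox = TRUE, digits = NA)
  graph
}
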