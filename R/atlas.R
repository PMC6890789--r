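#' Atlas ontology trees and label volumes
#'
#' An `ontology` is a hierarchical structure graph in the Allen style: every
#' node has an integer id, an acronym, a parent (except the single root), a
#' graph depth (root = 0) and a graph order (index in a depth-first
#' traversal). A `label_volume` is an integer [voxel_grid()] whose nonzero
#' values are ontology ids (optionally through an `id_map`).
#'
#' @name atlas
NULL

default_field_aliases <- list(
  id = c("id"),
  acronym = c("acronym", "abbrev"),
  name = c("name", "safe_name"),
  parent_id = c("parent_id", "parent_structure_id"),
  depth = c("graph_depth", "depth", "st_level"),
  order = c("graph_order", "order", "graph_order_index")
)

pick_field <- function(rec, aliases) {
  hit <- intersect(aliases, names(rec))
  if (length(hit) == 0) return(NULL)
  rec[[hit[1]]]
}

#' Load an ontology from flat-record JSON
#'
#' Accepts the flat list-of-records dialect of Allen structure-graph
#' exports; field names are resolved through an alias table so both
#' `graph_depth`/`parent_id` and `st_level`/`parent_structure_id` spellings
#' load without changes.
#'
#' @param path JSON file: an array of records with id, parent, depth, order.
#' @param aliases named list of accepted field names per canonical field;
#'   see `clarityatlas:::default_field_aliases`.
#' @return An `ontology` object.
#' @export
load_ontology <- function(path, aliases = default_field_aliases) {
  recs <- jsonlite::fromJSON(path, simplifyDataFrame = TRUE)
  nodes <- tibble::tibble(
    id = as.integer(pick_field(recs, aliases$id)),
    acronym = as.character(pick_field(recs, aliases$acronym) %||%
                             paste0("S", pick_field(recs, aliases$id))),
    name = as.character(pick_field(recs, aliases$name) %||%
                          paste0("structure ", pick_field(recs, aliases$id))),
    parent_id = as.integer(pick_field(recs, aliases$parent_id)),
    depth = as.integer(pick_field(recs, aliases$depth)),
    order = as.integer(pick_field(recs, aliases$order))
  )
  ontology(nodes)
}

#' Build an ontology from a node table
#'
#' @param nodes data frame with columns `id`, `parent_id` (`NA` for the
#'   root), and optionally `acronym`, `name`, `depth`, `order`.
#' @return An `ontology` object with O(1) id lookup.
#' @export
ontology <- function(nodes) {
  nodes <- tibble::as_tibble(nodes)
  if (anyDuplicated(nodes$id))
    stop("duplicate ontology id(s): ",
         paste(unique(nodes$id[duplicated(nodes$id)]), collapse = ", "),
         call. = FALSE)
  root <- nodes$id[is.na(nodes$parent_id)]
  if (length(root) != 1L)
    stop("ontology must have exactly one root (parent_id = NA), found ",
         length(root), call. = FALSE)
  known <- nodes$parent_id %in% nodes$id | is.na(nodes$parent_id)
  if (!all(known))
    stop("orphan parent reference(s): parent id(s) ",
         paste(unique(nodes$parent_id[!known]), collapse = ", "),
         " absent from ontology", call. = FALSE)
  parent <- stats::setNames(nodes$parent_id, nodes$id)
  # depth by parent-chain walk; doubles as cycle detection
  depth <- stats::setNames(rep(NA_integer_, nrow(nodes)), nodes$id)
  n <- nrow(nodes)
  for (id in nodes$id) {
    d <- 0L
    cur <- id
    while (!is.na(parent[[as.character(cur)]])) {
      cur <- parent[[as.character(cur)]]
      d <- d + 1L
      if (d > n) stop("cycle detected in ontology parent links", call. = FALSE)
    }
    depth[[as.character(id)]] <- d
  }
  if (!"depth" %in% names(nodes) || all(is.na(nodes[["depth"]])))
    nodes$depth <- unname(depth[as.character(nodes$id)])
  if (!"order" %in% names(nodes) || all(is.na(nodes[["order"]])))
    nodes$order <- dfs_order(nodes, root)
  if (!"acronym" %in% names(nodes)) nodes$acronym <- paste0("S", nodes$id)
  if (!"name" %in% names(nodes)) nodes$name <- paste0("structure ", nodes$id)
  structure(list(nodes = nodes, parent = parent, root = root,
                 row = stats::setNames(seq_len(nrow(nodes)), nodes$id)),
            class = "ontology")
}

dfs_order <- function(nodes, root) {
  kids <- split(nodes$id, factor(nodes$parent_id, levels = nodes$id))
  ord <- stats::setNames(rep(NA_integer_, nrow(nodes)), nodes$id)
  counter <- 0L
  stack <- root
  while (length(stack)) {
    cur <- stack[[1]]
    stack <- stack[-1]
    ord[[as.character(cur)]] <- counter
    counter <- counter + 1L
    ch <- sort(kids[[as.character(cur)]])
    if (length(ch)) stack <- c(ch, stack)
  }
  unname(ord[as.character(nodes$id)])
}

#' @export
print.ontology <- function(x, ...) {
  cat(sprintf("<ontology> %d structures, max depth %d, root id %d\n",
              nrow(x$nodes), max(x$nodes$depth), x$root))
  invisible(x)
}

ontology_node <- function(ont, id) {
  r <- ont$row[as.character(id)]
  if (any(is.na(r))) stop("unknown ontology id: ",
                          paste(id[is.na(r)], collapse = ", "), call. = FALSE)
  ont$nodes[r, ]
}

#' Ancestors of an ontology node
#'
#' Walks the parent chain from the node's parent up to the root; used for
#' parent-fallback searches where a label without its own injection
#' experiment inherits the nearest ancestor's.
#'
#' @param ont an [ontology()].
#' @param node_id structure id present in the ontology.
#' @return Tibble of ancestor nodes, nearest (the parent) first; zero rows
#'   for the root.
#' @export
ancestors <- function(ont, node_id) {
  ontology_node(ont, node_id)  # validates
  ids <- integer(0)
  cur <- node_id
  repeat {
    p <- ont$parent[[as.character(cur)]]
    if (is.na(p)) break
    ids <- c(ids, p)
    cur <- p
  }
  ontology_node(ont, ids)[seq_along(ids), , drop = FALSE]
}

#' Create a label volume
#'
#' @param grid integer [voxel_grid()] (or array) of region labels, 0 =
#'   unlabelled.
#' @param spacing_um,origin_um,axes geometry, when `grid` is a bare array.
#' @param id_map named integer vector mapping voxel values to ontology ids;
#'   defaults to the identity over the values present.
#' @return A `label_volume` (a [voxel_grid()] subclass).
#' @export
label_volume <- function(grid, spacing_um = c(1, 1, 1),
                         origin_um = c(0, 0, 0), axes = "RAS",
                         id_map = NULL) {
  if (!is_voxel_grid(grid))
    grid <- voxel_grid(grid, spacing_um, origin_um, axes)
  vals <- sort(unique(as.vector(grid$data)))
  vals <- vals[vals != 0]
  if (is.null(id_map)) id_map <- stats::setNames(as.integer(vals), vals)
  missing <- setdiff(as.character(vals), names(id_map))
  if (length(missing))
    stop("label value(s) absent from id_map: ",
         paste(missing, collapse = ", "), call. = FALSE)
  grid$id_map <- id_map
  class(grid) <- c("label_volume", class(grid))
  grid
}

#' Collapse a label volume to a target ontology depth
#'
#' Each voxel's label is replaced by its unique ancestor at `target_depth`
#' (labels already at or above that depth pass through unchanged) —
#' the "grand-parent" grouping of fine labels into coarser parents,
#' generalised to any depth.
#'
#' @param labels a [label_volume()].
#' @param ont an [ontology()].
#' @param target_depth non-negative integer depth to collapse to.
#' @return A [label_volume()] on the same grid.
#' @export
collapse_to_depth <- function(labels, ont, target_depth) {
  stopifnot(inherits(labels, "label_volume"), target_depth >= 0)
  vals <- sort(unique(as.vector(labels$data)))
  vals <- vals[vals != 0]
  new_id <- vapply(vals, function(v) {
    id <- unname(labels$id_map[[as.character(v)]])
    ancestor_at_depth(ont, id, target_depth)
  }, integer(1))
  lut <- integer(max(c(vals, 1L)) + 1L)  # value + 1 -> new id, 0 stays 0
  lut[vals + 1L] <- new_id
  data <- array(lut[labels$data + 1L], dim(labels$data))
  label_volume(vg_like(labels, data))
}

ancestor_at_depth <- function(ont, id, target_depth) {
  node <- ontology_node(ont, id)
  if (node$depth <= target_depth) return(as.integer(id))
  cur <- id
  repeat {
    cur <- ont$parent[[as.character(cur)]]
    if (ontology_node(ont, cur)$depth <= target_depth)
      return(as.integer(cur))
  }
}

#' Collapse a label volume upwards by k levels
#'
#' Convenience mode: each label moves to its ancestor `k` levels up (its
#' grand-parent for `k = 2`), clamped at the root.
#'
#' @inheritParams collapse_to_depth
#' @param k number of levels to move up.
#' @return A [label_volume()].
#' @export
collapse_up_levels <- function(labels, ont, k) {
  stopifnot(inherits(labels, "label_volume"), k >= 0)
  vals <- sort(unique(as.vector(labels$data)))
  vals <- vals[vals != 0]
  new_id <- vapply(vals, function(v) {
    id <- unname(labels$id_map[[as.character(v)]])
    d <- ontology_node(ont, id)$depth
    ancestor_at_depth(ont, id, max(0L, d - as.integer(k)))
  }, integer(1))
  lut <- integer(max(c(vals, 1L)) + 1L)
  lut[vals + 1L] <- new_id
  label_volume(vg_like(labels, array(lut[labels$data + 1L],
                                     dim(labels$data))))
}

#' Labels present in a mask, largest first
#'
#' Counts in-mask voxels per label; used e.g. to pick the largest regions
#' inside a lesion mask. Ties in voxel count are broken by ascending id.
#'
#' @param labels a [label_volume()].
#' @param mask logical/binary [voxel_grid()] on the same grid.
#' @param top_n maximum number of labels to return.
#' @return Tibble with `id` and `n_voxels`, sorted by count descending.
#' @export
labels_in_mask <- function(labels, mask, top_n = Inf) {
  stopifnot(inherits(labels, "label_volume"))
  stopifnot_aligned(labels, mask, "labels and mask")
  vals <- labels$data[mask$data > 0]
  vals <- vals[vals != 0]
  if (length(vals) == 0)
    return(tibble::tibble(id = integer(0), n_voxels = integer(0)))
  tab <- table(vals)
  out <- tibble::tibble(
    id = unname(labels$id_map[names(tab)]),
    n_voxels = as.integer(tab)
  )
  out <- out[order(-out$n_voxels, out$id), ]
  utils::head(out, top_n)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
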