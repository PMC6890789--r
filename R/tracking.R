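#' Streamline sets
#'
#' An ordered collection of 3D polylines in world micrometres, as produced
#' by [fact_track()] or read from TCK files.
#'
#' @param points list of n_i x 3 numeric matrices (world um), each with at
#'   least 2 rows.
#' @param seed_index integer seed identifier per streamline.
#' @return A `streamline_set`.
#' @export
streamline_set <- function(points, seed_index = seq_along(points)) {
  stopifnot(is.list(points), length(seed_index) == length(points))
  for (p in points)
    if (!is.matrix(p) || ncol(p) != 3 || nrow(p) < 2)
      stop("each streamline must be an n x 3 matrix with n >= 2",
           call. = FALSE)
  structure(list(points = points, seed_index = as.integer(seed_index)),
            class = "streamline_set")
}

#' @export
length.streamline_set <- function(x) length(x$points)

#' @export
print.streamline_set <- function(x, ...) {
  npt <- vapply(x$points, nrow, integer(1))
  cat(sprintf("<streamline_set> %d streamlines, %d-%d points each\n",
              length(x$points), if (length(npt)) min(npt) else 0,
              if (length(npt)) max(npt) else 0))
  invisible(x)
}

#' Deterministic FACT streamline tracking
#'
#' Streamlines are seeded at the voxel centres of `seed_mask` (lexicographic
#' voxel order, truncated at `max_streamlines`) and propagated
#' bidirectionally in fixed steps of `step_um` along the orientation of the
#' containing voxel. Orientations are axial, so at each step the vector is
#' sign-flipped to best align with the previous direction before the angle
#' test. A streamline terminates when (a) the turn between consecutive
#' steps exceeds `alpha_thresh_deg`, (b) it leaves `brain_mask`, (c) it
#' enters a voxel with no valid orientation, or (d) it exceeds
#' `max_length_um`. In unstained/noisy regions the orientation decorrelates
#' between voxels, so the angular threshold alone terminates tracks there.
#'
#' @param field an [orientation_field()].
#' @param seed_mask binary [voxel_grid()] of seed voxels.
#' @param brain_mask binary [voxel_grid()]; tracking is confined to it
#'   (`NULL` = whole volume).
#' @param params an [sta_params()].
#' @param seed_density keep every k-th seed voxel (1 = all), a
#'   deterministic subsampling of the lexicographic seed order.
#' @return A [streamline_set()] (streamlines that never left their seed
#'   voxel's centre are dropped).
#' @export
fact_track <- function(field, seed_mask, brain_mask = NULL,
                       params = sta_params(), seed_density = 1L) {
  stopifnot(inherits(field, "orientation_field"))
  dm <- field$dim
  geom <- list(spacing_um = field$spacing_um, origin_um = field$origin_um,
               data = array(0, dm))
  step <- params$step_um %||% (min(field$spacing_um) / 2)
  cos_alpha <- cos(params$alpha_thresh_deg * pi / 180)
  bmask <- if (is.null(brain_mask)) array(TRUE, dm) else brain_mask$data > 0
  if (!all(dim(bmask) == dm) || !all(dim(seed_mask$data) == dm))
    stop("masks must share the orientation field's grid", call. = FALSE)
  seeds <- which(seed_mask$data > 0)
  if (length(seeds) == 0) stop("empty seed mask", call. = FALSE)
  if (!any(field$valid)) stop("orientation field has no valid voxels",
                              call. = FALSE)
  seeds <- seeds[seq(1L, length(seeds), by = as.integer(seed_density))]
  seeds <- utils::head(seeds, params$max_streamlines)
  sidx <- arrayInd(seeds, dm)
  P0 <- index_to_world(geom, sidx)
  n <- nrow(P0)
  V <- cbind(as.vector(field$vx)[seeds], as.vector(field$vy)[seeds],
             as.vector(field$vz)[seeds])
  seed_ok <- field$valid[seeds] & bmask[seeds]
  max_len <- params$max_length_um
  if (!is.finite(max_len)) max_len <- 4 * sqrt(sum((dm * field$spacing_um)^2))
  max_steps <- ceiling(max_len / step)

  track_half <- function(D0) {
    pts <- array(NA_real_, c(max_steps, n, 3))
    P <- P0
    D <- D0
    active <- seed_ok
    len <- numeric(n)
    for (t in seq_len(max_steps)) {
      if (!any(active)) break
      a <- which(active)
      idx <- world_to_index(geom, P[a, , drop = FALSE])
      lin <- linear_index(idx, dm)
      v <- cbind(as.vector(field$vx)[lin], as.vector(field$vy)[lin],
                 as.vector(field$vz)[lin])
      ok <- field$valid[lin]
      dt <- rowSums(v * D[a, , drop = FALSE])
      sgn <- ifelse(dt < 0, -1, 1)
      v <- v * sgn
      ok <- ok & (abs(dt) >= cos_alpha)
      Pn <- P[a, , drop = FALSE] + step * v
      nidx <- world_to_index(geom, Pn)
      inb <- in_bounds(nidx, dm)
      ok <- ok & inb
      ok[ok] <- bmask[linear_index(nidx[ok, , drop = FALSE], dm)]
      stopped <- a[!ok]
      active[stopped] <- FALSE
      amv <- a[ok]
      if (length(amv)) {
        P[amv, ] <- Pn[ok, , drop = FALSE]
        D[amv, ] <- v[ok, , drop = FALSE]
        pts[t, amv, ] <- Pn[ok, , drop = FALSE]
        len[amv] <- len[amv] + step
        active[amv] <- active[amv] & (len[amv] < max_len)
      }
    }
    pts
  }
  fwd <- track_half(V)
  bwd <- track_half(-V)
  out <- vector("list", n)
  for (i in seq_len(n)) {
    f <- fwd[, i, , drop = FALSE]
    b <- bwd[, i, , drop = FALSE]
    nf <- sum(!is.na(f[, 1, 1]))
    nb <- sum(!is.na(b[, 1, 1]))
    m <- matrix(NA_real_, nb + 1L + nf, 3)
    if (nb) m[seq_len(nb), ] <- matrix(b[nb:1, 1, ], ncol = 3)
    m[nb + 1L, ] <- P0[i, ]
    if (nf) m[nb + 1L + seq_len(nf), ] <- matrix(f[seq_len(nf), 1, ],
                                                 ncol = 3)
    out[[i]] <- m
  }
  keep <- vapply(out, nrow, integer(1)) >= 2L
  streamline_set(out[keep], seed_index = seq_len(n)[keep])
}

#' Tract-density and terminal maps from streamlines
#'
#' The tract-density value of a voxel is the number of distinct streamlines
#' visiting it (each streamline counted once per voxel); the terminal value
#' is the number of streamline endpoints (both ends) falling in it, so the
#' terminal map sums to twice the number of streamlines before any masking.
#'
#' @param streams a [streamline_set()].
#' @param geometry a [voxel_grid()] defining the output grid.
#' @return List with `tdi` and `terminals`, both integer [voxel_grid()]s.
#' @export
density_and_terminal_maps <- function(streams, geometry) {
  stopifnot(inherits(streams, "streamline_set"), is_voxel_grid(geometry))
  dm <- dim(geometry$data)
  ntot <- prod(dm)
  tdi <- integer(ntot)
  term <- integer(ntot)
  clipped <- 0L
  for (p in streams$points) {
    idx <- world_to_index(geometry, p)
    inb <- in_bounds(idx, dm)
    clipped <- clipped + sum(!inb)
    lin <- unique(linear_index(idx[inb, , drop = FALSE], dm))
    tdi[lin] <- tdi[lin] + 1L
    ends <- idx[c(1, nrow(p)), , drop = FALSE]
    einb <- in_bounds(ends, dm)
    for (l in linear_index(ends[einb, , drop = FALSE], dm))
      term[l] <- term[l] + 1L
  }
  if (clipped > 0)
    warning(sprintf("%d streamline points outside the grid were clipped",
                    clipped))
  list(tdi = vg_like(geometry, array(tdi, dm)),
       terminals = vg_like(geometry, array(term, dm)))
}

#' Mask out the injection-site component of a terminal map
#'
#' Terminals cluster densely at the seed/injection site (proximal
#' connections and tracer spill-over). The terminal map is binarized
#' (`> threshold`), 26-connected components are labelled, and the largest
#' component — which must intersect the seed mask, otherwise the largest
#' seed-intersecting component is used instead with a warning — is zeroed
#' out, leaving terminals of long-range tracts only.
#'
#' @param terminals integer terminal-count [voxel_grid()].
#' @param seed_mask binary [voxel_grid()] of the seed region.
#' @param threshold binarization threshold (voxels with count `>`
#'   threshold enter the component analysis).
#' @return The masked terminal-count [voxel_grid()].
#' @export
mask_injection_component <- function(terminals, seed_mask, threshold = 0) {
  stopifnot_aligned(terminals, seed_mask, "terminal map and seed mask")
  bin <- terminals$data > threshold
  lab <- cpp_label3d(as.logical(bin), dim(bin))
  ncomp <- max(lab)
  if (ncomp == 0L) return(terminals)
  sizes <- tabulate(lab[lab > 0], ncomp)
  target <- which.max(sizes)
  seed_hits <- unique(lab[seed_mask$data > 0 & lab > 0])
  if (!(target %in% seed_hits)) {
    if (length(seed_hits) == 0) {
      warning("no terminal component intersects the seed; map unchanged")
      return(terminals)
    }
    warning("largest terminal component does not intersect the seed; ",
            "masking the largest seed-intersecting component instead")
    target <- seed_hits[which.max(sizes[seed_hits])]
  }
  out <- terminals$data
  out[lab == target] <- 0L
  vg_like(terminals, out)
}

#' Select streamlines passing through or terminating in a region
#'
#' Passing fibers have at least one point in the region; terminating
#' fibers have an endpoint voxel in it. Terminating streamlines are always
#' a subset of passing ones.
#'
#' @param streams a [streamline_set()].
#' @param region_mask binary [voxel_grid()].
#' @param mode `"passing"` or `"terminating"`.
#' @return The selected [streamline_set()].
#' @export
filter_streamlines <- function(streams, region_mask,
                               mode = c("passing", "terminating")) {
  mode <- match.arg(mode)
  stopifnot(inherits(streams, "streamline_set"))
  dm <- dim(region_mask$data)
  sel <- vapply(streams$points, function(p) {
    idx <- if (mode == "passing") world_to_index(region_mask, p)
    else world_to_index(region_mask, p[c(1, nrow(p)), , drop = FALSE])
    idx <- idx[in_bounds(idx, dm), , drop = FALSE]
    if (nrow(idx) == 0) return(FALSE)
    any(region_mask$data[linear_index(idx, dm)] > 0)
  }, logical(1))
  streamline_set(streams$points[sel], streams$seed_index[sel])
}

#' Per-region connectivity weights from tract maps
#'
#' Passing mode weighs each atlas region by its mean tract density;
#' terminal mode weighs it by the number of (masked) streamline terminals
#' inside it. Output is ranked by weight (descending; ties by ascending
#' id).
#'
#' @param tdi tract-density [voxel_grid()] (passing mode).
#' @param terminals terminal-count [voxel_grid()] (terminal mode), ideally
#'   after [mask_injection_component()].
#' @param labels a [label_volume()] on the same grid.
#' @param mode `"passing"` or `"terminal"`.
#' @return Tibble with `id`, `weight`, `rank`.
#' @export
region_connectivity <- function(tdi = NULL, terminals = NULL, labels,
                                mode = c("passing", "terminal")) {
  mode <- match.arg(mode)
  src <- if (mode == "passing") tdi else terminals
  if (is.null(src)) stop("supply the map matching `mode`", call. = FALSE)
  stopifnot_aligned(src, labels, "map and labels")
  lab <- as.vector(labels$data)
  keep <- lab != 0
  vals <- as.vector(src$data)[keep]
  f <- factor(lab[keep])
  w <- if (mode == "passing") tapply(vals, f, mean) else tapply(vals, f, sum)
  out <- tibble::tibble(id = unname(labels$id_map[names(w)]),
                        weight = as.numeric(w))
  out <- out[order(-out$weight, out$id), ]
  out$rank <- seq_len(nrow(out))
  out
}

#' Read and write streamlines in TCK format
#'
#' The TCK track-file format stores float32 world coordinates in
#' millimetres; coordinates are converted from/to the package-internal
#' micrometres on the way through.
#'
#' @param streams a [streamline_set()].
#' @param path a `.tck` file path.
#' @return `write_tck` returns `path` invisibly; `read_tck` returns a
#'   [streamline_set()].
#' @export
write_tck <- function(streams, path) {
  stopifnot(inherits(streams, "streamline_set"))
  hdr_lines <- c("mrtrix tracks", "datatype: Float32LE",
                 sprintf("count: %d", length(streams$points)))
  # reserve room for the offset line, then finalize
  probe <- paste0(paste(c(hdr_lines, "file: . 0000000000", "END"),
                        collapse = "\n"), "\n")
  offset <- nchar(probe, type = "bytes")
  hdr <- paste0(paste(c(hdr_lines, sprintf("file: . %010d", offset), "END"),
                      collapse = "\n"), "\n")
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar(hdr, con, eos = NULL)
  for (p in streams$points) {
    writeBin(as.vector(t(p / 1000)), con, size = 4L, endian = "little")
    writeBin(rep(NaN, 3), con, size = 4L, endian = "little")
  }
  writeBin(rep(Inf, 3), con, size = 4L, endian = "little")
  invisible(path)
}

#' @rdname write_tck
#' @export
read_tck <- function(path) {
  raw <- readBin(path, "raw", n = file.size(path))
  hdr_end <- grepRaw("END\n", raw, fixed = TRUE)
  if (length(hdr_end) == 0)
    stop("not a TCK file: ", path, call. = FALSE)
  txt <- rawToChar(raw[seq_len(hdr_end + 3L)])
  if (!startsWith(txt, "mrtrix tracks"))
    stop("not a TCK file: ", path, call. = FALSE)
  lines <- strsplit(txt, "\n")[[1]]
  file_line <- grep("^file:", lines, value = TRUE)[1]
  offset <- as.integer(sub("^file:\\s*\\.\\s*", "", file_line))
  vals <- readBin(raw[-seq_len(offset)], "numeric", size = 4L,
                  n = (length(raw) - offset) / 4L, endian = "little")
  m <- matrix(vals, ncol = 3, byrow = TRUE)
  breaks <- which(is.nan(m[, 1]) | is.infinite(m[, 1]))
  pts <- list()
  start <- 1L
  for (b in breaks) {
    if (b > start) pts[[length(pts) + 1L]] <- m[start:(b - 1L), ,
                                                drop = FALSE] * 1000
    start <- b + 1L
    if (is.infinite(m[b, 1])) break
  }
  streamline_set(pts)
}
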