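#' Deterministic synthetic phantoms
#'
#' Generators for every input the pipeline needs, each a pure function of
#' its arguments and seed, shipping its ground truth alongside the data.
#' The RNG algorithm is pinned (Mersenne-Twister / Inversion) so fixtures
#' are reproducible across platforms and R versions.
#'
#' @name phantoms
NULL

with_phantom_rng <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  suppressWarnings(set.seed(seed, kind = "Mersenne-Twister",
                            normal.kind = "Inversion"))
  force(code)
}

#' Tube phantom with known centerlines
#'
#' Bright tubular fiber bundles (straight, curved, or branching) on a dim
#' background with additive Gaussian noise; centerlines and tangents are
#' returned in world micrometres as ground truth.
#'
#' @param shape volume dimensions (voxels).
#' @param spacing_um voxel spacing.
#' @param radius_vox tube radius in voxels (>= 1).
#' @param kind `"straight"` (along `axis`), `"curved"` (circular arc in
#'   the xy-plane), or `"branch"` (straight trunk with an oblique branch).
#' @param axis axis of a straight tube (1, 2, 3).
#' @param arc_radius_vox radius of the curved tube's arc.
#' @param contrast tube intensity above `background`.
#' @param background background intensity.
#' @param snr contrast-to-noise ratio; noise sd = `contrast / snr`
#'   (`Inf` = noise-free).
#' @param seed RNG seed.
#' @return List with `volume` ([voxel_grid()]), `centerlines` (list of
#'   n x 3 world-um matrices), `tangents` (matched unit tangents),
#'   `radius_um`, `contrast`.
#' @export
make_tube_phantom <- function(shape = c(64, 64, 64), spacing_um = c(1, 1, 1),
                              radius_vox = 3,
                              kind = c("straight", "curved", "branch"),
                              axis = 3, arc_radius_vox = 24, contrast = 1,
                              background = 0, snr = 8, seed = 1) {
  kind <- match.arg(kind)
  stopifnot(radius_vox >= 1)
  shape <- as.integer(shape)
  ctr <- (shape + 1) / 2
  step <- 0.5
  line <- function(p0, p1) {
    n <- max(2L, ceiling(sqrt(sum((p1 - p0)^2)) / step))
    t <- seq(0, 1, length.out = n)
    pts <- outer(1 - t, p0) + outer(t, p1)
    tan <- (p1 - p0) / sqrt(sum((p1 - p0)^2))
    list(pts = pts, tan = matrix(tan, n, 3, byrow = TRUE))
  }
  cls <- switch(kind,
    straight = {
      p0 <- ctr; p1 <- ctr
      p0[axis] <- radius_vox + 1
      p1[axis] <- shape[axis] - radius_vox
      list(line(p0, p1))
    },
    curved = {
      # quarter arc in the xy-plane around a corner-ish centre
      cen <- c(ctr[1] - arc_radius_vox / 2, ctr[2] - arc_radius_vox / 2,
               ctr[3])
      th <- seq(0, pi / 2, by = step / arc_radius_vox)
      pts <- cbind(cen[1] + arc_radius_vox * cos(th),
                   cen[2] + arc_radius_vox * sin(th),
                   rep(cen[3], length(th)))
      tan <- cbind(-sin(th), cos(th), 0)
      list(list(pts = pts, tan = tan))
    },
    branch = {
      m <- radius_vox + 1
      trunk <- line(c(ctr[1], ctr[2], m), c(ctr[1], ctr[2], ctr[3]))
      b1 <- line(c(ctr[1], ctr[2], ctr[3]),
                 c(ctr[1], ctr[2], shape[3] - m))
      b2 <- line(c(ctr[1], ctr[2], ctr[3]),
                 c(min(ctr[1] + (shape[3] - ctr[3]) * 0.6, shape[1] - m),
                   ctr[2], shape[3] - m))
      list(trunk, b1, b2)
    })
  arr <- array(background, shape)
  r <- radius_vox
  offs <- as.matrix(expand.grid(-ceiling(r):ceiling(r),
                                -ceiling(r):ceiling(r),
                                -ceiling(r):ceiling(r)))
  offs <- offs[rowSums(offs^2) <= r^2, , drop = FALSE]
  clipped <- FALSE
  for (cl in cls) {
    for (i in seq_len(nrow(cl$pts))) {
      vox <- sweep(offs, 2, round(cl$pts[i, ]), "+")
      inb <- in_bounds(vox, shape)
      if (!all(inb)) clipped <- TRUE
      lin <- linear_index(vox[inb, , drop = FALSE], shape)
      arr[lin] <- background + contrast
    }
  }
  if (clipped) warning("tube partially clipped at the volume boundary")
  vol <- with_phantom_rng(seed, {
    if (is.finite(snr))
      arr <- arr + stats::rnorm(length(arr), sd = contrast / snr)
    arr
  })
  geom <- voxel_grid(vol, spacing_um = spacing_um)
  to_world <- function(pts) index_to_world(geom, pts)
  list(volume = geom,
       centerlines = lapply(cls, function(cl) to_world(cl$pts)),
       tangents = lapply(cls, function(cl) cl$tan),
       radius_um = radius_vox * min(spacing_um), contrast = contrast)
}

#' Blob phantom with known centres
#'
#' Gaussian blobs at Poisson-disc-sampled centres (dart throwing with a
#' minimum separation), an optional linear background gradient, and
#' Gaussian noise at a set peak signal-to-noise ratio. Mimics sparse
#' stained nuclei in a cleared volume with depth-dependent background.
#'
#' @param shape volume dimensions (voxels).
#' @param spacing_um voxel spacing.
#' @param n_blobs requested number of blobs.
#' @param sigma_range_vox range of per-blob Gaussian sigmas.
#' @param min_separation_vox minimum centre-to-centre distance.
#' @param peak blob peak intensity.
#' @param snr peak-to-noise-sd ratio (`Inf` = noise-free).
#' @param gradient_amplitude linear background ramp amplitude across x,
#'   as a fraction of `peak` (0 disables).
#' @param margin_vox keep-out margin from the volume faces, per axis
#'   (scalar recycled). The default keeps blobs away from the x/y faces
#'   but lets them run through the full z extent, as in a subvolume cut
#'   from larger tissue — so every slice of the stack carries signal.
#' @param seed RNG seed.
#' @return List with `volume`, `centers` (n x 3 world um), `sigma_vox`,
#'   `peak`.
#' @export
make_blob_phantom <- function(shape = c(192, 192, 48), spacing_um = c(1, 1, 1),
                              n_blobs = 200, sigma_range_vox = c(1.6, 2.4),
                              min_separation_vox = 8, peak = 1, snr = 8,
                              gradient_amplitude = 0.3,
                              margin_vox = c(4, 4, 0), seed = 1) {
  stopifnot(n_blobs >= 1)
  shape <- as.integer(shape)
  margin_vox <- rep_len(margin_vox, 3L)
  with_phantom_rng(seed, {
    centers <- matrix(NA_real_, 0, 3)
    tries <- 0L
    max_tries <- 200L * n_blobs
    while (nrow(centers) < n_blobs && tries < max_tries) {
      tries <- tries + 1L
      cand <- 1 + margin_vox + stats::runif(3) * (shape - 1 - 2 * margin_vox)
      if (nrow(centers) == 0 ||
          min(rowSums(sweep(centers, 2, cand)^2)) >= min_separation_vox^2)
        centers <- rbind(centers, cand)
    }
    if (nrow(centers) < n_blobs)
      warning(sprintf("packing infeasible: placed %d of %d blobs",
                      nrow(centers), n_blobs))
    sig <- stats::runif(nrow(centers), sigma_range_vox[1],
                        sigma_range_vox[2])
    arr <- array(0, shape)
    for (i in seq_len(nrow(centers))) {
      c0 <- centers[i, ]
      s <- sig[i]
      ext <- ceiling(3 * s)
      rng <- lapply(1:3, function(ax)
        max(1L, floor(c0[ax] - ext)):min(shape[ax], ceiling(c0[ax] + ext)))
      gx <- exp(-(rng[[1]] - c0[1])^2 / (2 * s^2))
      gy <- exp(-(rng[[2]] - c0[2])^2 / (2 * s^2))
      gz <- exp(-(rng[[3]] - c0[3])^2 / (2 * s^2))
      blob <- peak * outer(outer(gx, gy), gz)
      dim(blob) <- c(length(gx), length(gy), length(gz))
      arr[rng[[1]], rng[[2]], rng[[3]]] <-
        pmax(arr[rng[[1]], rng[[2]], rng[[3]]], blob)
    }
    if (gradient_amplitude > 0) {
      ramp <- gradient_amplitude * peak *
        (seq_len(shape[1]) - 1) / (shape[1] - 1)
      arr <- arr + array(ramp, shape)
    }
    if (is.finite(snr))
      arr <- arr + stats::rnorm(length(arr), sd = peak / snr)
    geom <- voxel_grid(arr, spacing_um = spacing_um)
    list(volume = geom,
         centers = index_to_world(geom, centers),
         sigma_vox = sig, peak = peak)
  })
}

#' Toy atlas: nested hierarchy, label volume and projection table
#'
#' Builds a binary-split hierarchy of rectangular regions (first split =
#' left/right hemispheres, then alternating axes) down to the requested
#' depth, the matching leaf-label volume, and a synthetic projection
#' table in the viral-tracing schema with seeded random weights.
#'
#' @param shape volume dimensions; each axis must accommodate the splits.
#' @param spacing_um voxel spacing.
#' @param depth hierarchy depth (>= 6 so the depth/order connectivity
#'   filters are exercisable).
#' @param injection_depth depth of the structures given injection
#'   experiments.
#' @param n_targets_per_injection targets drawn per experiment.
#' @param seed RNG seed.
#' @param dir optional directory; when given, `ontology.json`,
#'   `labels.nii.gz` and `connectivity.csv` are written there.
#' @return List with `labels` ([label_volume()]), `ontology`
#'   ([ontology()]), `connectivity` (tibble), and `paths` when `dir` is
#'   given.
#' @export
make_toy_atlas <- function(shape = c(64, 64, 32), spacing_um = c(25, 25, 25),
                           depth = 6, injection_depth = 3,
                           n_targets_per_injection = 8, seed = 1,
                           dir = NULL) {
  stopifnot(depth >= 6)
  shape <- as.integer(shape)
  axes_cycle <- rep(c(1L, 2L, 3L), length.out = depth)
  n_splits <- tabulate(axes_cycle, 3)
  if (any(shape < 2^n_splits))
    stop("shape too small for requested depth", call. = FALSE)
  # recursive binary splits; node records + voxel boxes
  nodes <- list(list(id = 1L, parent = NA_integer_, depth = 0L,
                     box = rbind(c(1L, 1L, 1L), shape)))
  next_id <- 2L
  frontier <- 1L
  for (d in seq_len(depth)) {
    ax <- axes_cycle[d]
    new_frontier <- integer(0)
    for (fi in frontier) {
      box <- nodes[[fi]]$box
      mid <- (box[1, ax] + box[2, ax] - 1L) %/% 2L
      b1 <- box; b1[2, ax] <- mid
      b2 <- box; b2[1, ax] <- mid + 1L
      for (b in list(b1, b2)) {
        nodes[[next_id]] <- list(id = next_id, parent = nodes[[fi]]$id,
                                 depth = d, box = b)
        new_frontier <- c(new_frontier, next_id)
        next_id <- next_id + 1L
      }
    }
    frontier <- new_frontier
  }
  tab <- tibble::tibble(
    id = vapply(nodes, `[[`, integer(1), "id"),
    parent_id = vapply(nodes, `[[`, integer(1), "parent"),
    depth = vapply(nodes, `[[`, integer(1), "depth"))
  tab$acronym <- ifelse(tab$depth == 0, "root",
                        sprintf("D%d.%d", tab$depth, tab$id))
  tab$name <- paste0("toy structure ", tab$id)
  ont <- ontology(tab)
  lab <- array(0L, shape)
  for (nd in nodes) {
    if (nd$depth != depth) next
    b <- nd$box
    lab[b[1, 1]:b[2, 1], b[1, 2]:b[2, 2], b[1, 3]:b[2, 3]] <- nd$id
  }
  labels <- label_volume(lab, spacing_um = spacing_um)
  # synthetic projection table
  conn <- with_phantom_rng(seed, {
    inj_ids <- ont$nodes$id[ont$nodes$depth == injection_depth]
    rows <- lapply(seq_along(inj_ids), function(i) {
      iid <- inj_ids[i]
      pool <- setdiff(ont$nodes$id[ont$nodes$depth >= injection_depth],
                      c(iid, descendant_ids(ont, iid)))
      tgt <- sample(pool, min(n_targets_per_injection, length(pool)))
      npv <- round(stats::runif(length(tgt), 0.01, 1), 6)
      ivol <- round(stats::runif(1, 0.05, 0.2), 6)
      tibble::tibble(experiment_id = 1000L + i,
                     injection_structure_id = iid,
                     injection_volume_mm3 = ivol,
                     target_structure_id = tgt,
                     hemisphere = sample(c("ipsi", "contra"), length(tgt),
                                         replace = TRUE, prob = c(0.7, 0.3)),
                     strain = "C57BL/6J",
                     projection_volume = npv * ivol,
                     normalized_projection_volume = npv)
    })
    do.call(rbind, rows)
  })
  out <- list(labels = labels, ontology = ont, connectivity = conn)
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    pj <- file.path(dir, "ontology.json")
    jsonlite::write_json(
      data.frame(id = tab$id, acronym = tab$acronym, name = tab$name,
                 parent_id = tab$parent_id, graph_depth = tab$depth,
                 graph_order = ont$nodes$order),
      pj, na = "null", digits = NA)
    pl <- file.path(dir, "labels.nii.gz")
    write_volume(labels, pl)
    pc <- file.path(dir, "connectivity.csv")
    utils::write.csv(conn, pc, row.names = FALSE)
    out$paths <- c(ontology = pj, labels = pl, connectivity = pc)
  }
  out
}

#' Mirror-symmetric intensity pair with planted hemisphere asymmetry
#'
#' A smooth, strictly positive, left-right symmetric base volume whose
#' right-hemisphere intensity is multiplied by `1 - fraction` inside a
#' planted mask; the mirrored twin is the exact left-right flip (the
#' convention used to sample contralateral tract profiles with the same
#' streamline geometry).
#'
#' @param shape volume dimensions (x is the left-right axis).
#' @param spacing_um voxel spacing.
#' @param fraction planted intensity loss in `[0, 1)`.
#' @param noise_sd additive Gaussian noise sd (applied symmetrically
#'   before the asymmetry, so 0 keeps the recovery exact).
#' @param seed RNG seed.
#' @return List with `volume`, `mirrored`, `mask` (planted right-side
#'   [voxel_grid()] mask), `fraction`.
#' @export
make_asymmetric_pair <- function(shape = c(64, 48, 32),
                                 spacing_um = c(1, 1, 1), fraction = 0.2,
                                 noise_sd = 0, seed = 1) {
  stopifnot(fraction >= 0, fraction < 1)
  shape <- as.integer(shape)
  base <- with_phantom_rng(seed, {
    half <- array(stats::runif(prod(c(ceiling(shape[1] / 2), shape[2:3]))),
                  c(ceiling(shape[1] / 2), shape[2:3]))
    half <- gaussian_smooth(half, 4, c(1, 1, 1)) + 1  # smooth, positive
    full <- array(0, shape)
    full[seq_len(dim(half)[1]), , ] <- half
    full[shape[1]:(shape[1] - dim(half)[1] + 1), , ] <- half
    if (noise_sd > 0) {
      nh <- array(stats::rnorm(length(half), sd = noise_sd), dim(half))
      full[seq_len(dim(half)[1]), , ] <-
        full[seq_len(dim(half)[1]), , ] + nh
      full[shape[1]:(shape[1] - dim(half)[1] + 1), , ] <-
        full[shape[1]:(shape[1] - dim(half)[1] + 1), , ] + nh
    }
    full
  })
  mask <- array(FALSE, shape)
  xr <- (shape[1] %/% 2 + 2):(shape[1] - 2)
  yr <- (shape[2] %/% 4):(3 * shape[2] %/% 4)
  zr <- (shape[3] %/% 4):(3 * shape[3] %/% 4)
  mask[xr, yr, zr] <- TRUE
  vol <- base
  vol[mask] <- vol[mask] * (1 - fraction)
  mirrored <- vol[rev(seq_len(shape[1])), , , drop = FALSE]
  list(volume = voxel_grid(vol, spacing_um = spacing_um),
       mirrored = voxel_grid(mirrored, spacing_um = spacing_um),
       mask = voxel_grid(mask, spacing_um = spacing_um),
       fraction = fraction)
}
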