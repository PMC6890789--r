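test_that("a uniform field yields one straight full-span streamline", {
  dm <- c(100, 11, 11)
  f <- uniform_field(dm, c(1, 0, 0))
  seed <- vg(array(0, dm)); seed$data[50, 6, 6] <- 1
  st <- fact_track(f, seed, NULL, sta_params(step_um = 0.5))
  expect_length(st, 1L)
  p <- st$points[[1]]
  expect_equal(nrow(p), 200, tolerance = 1)   # mask extent / step +- 1
  expect_lt(max(abs(p[, 2] - 5)), 1e-9)       # perfectly straight
  expect_gte(diff(range(p[, 1])), 98)
  # step length contract
  expect_true(all(abs(sqrt(rowSums(diff(p)^2)) - 0.5) < 1e-9))
})

test_that("a 45-degree orientation discontinuity terminates at the boundary", {
  dm <- c(40, 11, 11)
  vx <- array(1, dm); vy <- array(0, dm); vz <- array(0, dm)
  rot <- 1 / sqrt(2)
  vx[21:40, , ] <- rot; vy[21:40, , ] <- rot  # 45-degree turn at x = 21
  f <- make_field(vx, vy, vz)
  seed <- vg(array(0, dm)); seed$data[5, 6, 6] <- 1
  st <- fact_track(f, seed, NULL, sta_params(step_um = 0.5,
                                             alpha_thresh_deg = 35))
  p <- st$points[[1]]
  # propagation stops on entering the rotated region (voxel 21 starts at
  # world x = 19.5); no point may have moved along the rotated direction
  expect_lt(max(p[, 2]), 5 + 1e-9)
  expect_lt(max(p[, 1]), 20.5)
  # with a threshold above 45 degrees the streamline crosses
  st2 <- fact_track(f, seed, NULL, sta_params(step_um = 0.5,
                                              alpha_thresh_deg = 60))
  expect_gt(max(st2$points[[1]][, 1]), 21)  # crossed into the rotated zone
})

test_that("sub-threshold turning follows a circle within one voxel", {
  dm <- c(64, 64, 5)
  cx <- 32.5; cy <- 32.5; r <- 20
  idx <- which(array(TRUE, dm), arr.ind = TRUE)
  dx <- idx[, 1] - cx; dy <- idx[, 2] - cy
  nrm <- pmax(sqrt(dx^2 + dy^2), 1e-9)
  f <- make_field(array(-dy / nrm, dm), array(dx / nrm, dm), array(0, dm))
  seed <- vg(array(0, dm)); seed$data[round(cx + r), round(cy), 3] <- 1
  st <- fact_track(f, seed, NULL,
                   sta_params(step_um = 0.5, max_length_um = 2 * pi * r))
  p <- st$points[[1]]
  d <- abs(sqrt((p[, 1] - (cx - 1))^2 + (p[, 2] - (cy - 1))^2) - r)
  expect_lt(mean(d), 1)
  expect_gt(nrow(p), 100)  # actually went around
})

test_that("tracking is invariant to sign flips of the orientation field", {
  dm <- c(30, 9, 9)
  set.seed(17)
  f <- uniform_field(dm, c(1, 0.2, 0))
  flip <- array(sample(c(-1, 1), prod(dm), TRUE), dm)
  f2 <- make_field(f$vx * flip, f$vy * flip, f$vz * flip)
  seed <- vg(array(0, dm)); seed$data[15, 5, 5] <- 1
  st1 <- fact_track(f, seed, NULL, sta_params(step_um = 0.5))
  st2 <- fact_track(f2, seed, NULL, sta_params(step_um = 0.5))
  expect_length(st2, length(st1))
  for (i in seq_along(st1$points)) {
    p1 <- st1$points[[i]]
    p2 <- st2$points[[i]]
    # axial symmetry: the polyline is identical up to traversal direction
    same <- isTRUE(all.equal(p1, p2, tolerance = 1e-9))
    reversed <- isTRUE(all.equal(p1, p2[nrow(p2):1, ], tolerance = 1e-9))
    expect_true(same || reversed)
  }
})

test_that("pure-noise orientations terminate tracks via the angle gate alone", {
  set.seed(23)
  dm <- c(30, 30, 30)
  v <- matrix(rnorm(prod(dm) * 3), ncol = 3)
  v <- v / sqrt(rowSums(v^2))
  f <- make_field(array(v[, 1], dm), array(v[, 2], dm), array(v[, 3], dm))
  seed <- vg(array(0, dm)); seed$data[15, 15, 15] <- 1
  st <- fact_track(f, seed, NULL, sta_params(step_um = 0.5))
  if (length(st) > 0)
    expect_lt(max(vapply(st$points, nrow, integer(1))), 40)
})

test_that("density and terminal maps match brute-force counting", {
  geom <- vg(array(0, c(20, 20, 20)))
  straight <- matrix(c(seq(0, 15, by = 0.5), rep(5, 31), rep(5, 31)),
                     ncol = 3)
  maps <- density_and_terminal_maps(sl(straight), geom)
  expect_true(all(maps$tdi$data[1:16, 6, 6] == 1))
  expect_equal(sum(maps$tdi$data), 16)
  expect_equal(sum(maps$terminals$data), 2)
  maps2 <- density_and_terminal_maps(streamline_set(list(straight,
                                                         straight)), geom)
  expect_true(all(maps2$tdi$data[1:16, 6, 6] == 2))
  # 50 random-walk streamlines vs brute force
  set.seed(31)
  walks <- lapply(1:50, function(i) {
    n <- sample(5:40, 1)
    w <- apply(matrix(rnorm(n * 3, sd = 0.8), n, 3), 2, cumsum) + 9
    pmin(pmax(w, 1), 18)  # keep inside the grid so nothing is clipped
  })
  ss <- streamline_set(walks)
  maps3 <- density_and_terminal_maps(ss, geom)
  tdi_o <- array(0L, c(20, 20, 20)); term_o <- array(0L, c(20, 20, 20))
  for (w in walks) {
    iw <- world_to_index(geom, w)
    ok <- clarityatlas:::in_bounds(iw, c(20L, 20L, 20L))
    lin <- unique(clarityatlas:::linear_index(iw[ok, , drop = FALSE],
                                              c(20L, 20L, 20L)))
    tdi_o[lin] <- tdi_o[lin] + 1L
    for (e in c(1, nrow(w))) {
      ie <- iw[e, , drop = FALSE]
      if (clarityatlas:::in_bounds(ie, c(20L, 20L, 20L)))
        term_o[ie] <- term_o[ie] + 1L
    }
  }
  expect_identical(maps3$tdi$data, tdi_o)
  expect_identical(maps3$terminals$data, term_o)
  expect_equal(sum(term_o), 2 * length(walks))  # both endpoints counted
})

test_that("injection-component masking removes the seed cluster only", {
  geom <- vg(array(0, c(30, 10, 10)))
  term <- vg(array(0L, c(30, 10, 10)))
  term$data[2:6, 4:6, 4:6] <- 3L    # proximal cluster over the seed
  term$data[25:27, 5, 5] <- 2L      # distal cluster
  seedm <- vg_mask(geom, FALSE)
  seedm$data[3:5, 5, 5] <- TRUE
  out <- mask_injection_component(term, seedm)
  expect_true(all(out$data[2:6, , ] == 0))
  expect_identical(out$data[25:27, 5, 5], term$data[25:27, 5, 5])
  expect_equal(sum(out$data), 6L)
  # all terminals in one seed blob: everything removed
  term2 <- vg(array(0L, c(30, 10, 10)))
  term2$data[3:5, 5, 5] <- 4L
  expect_equal(sum(mask_injection_component(term2, seedm)$data), 0L)
  # largest component off-seed: masks the seed-intersecting one instead
  term3 <- vg(array(0L, c(30, 10, 10)))
  term3$data[2:4, 5, 5] <- 1L
  term3$data[20:29, 2:9, 2:9] <- 1L
  expect_warning(out3 <- mask_injection_component(term3, seedm),
                 "seed-intersecting")
  expect_equal(sum(out3$data > 0), 10 * 8 * 8)
})

test_that("passing/terminating selection matches membership oracles", {
  geom <- vg(array(0, c(30, 10, 10)))
  region <- vg_mask(geom, FALSE)
  region$data[10:14, , ] <- TRUE
  crosser <- cbind(seq(0, 29), rep(5, 30), rep(5, 30))
  ender <- cbind(seq(0, 12, by = 0.5), rep(3, 25), rep(3, 25))
  outside <- cbind(seq(20, 29), rep(8, 10), rep(8, 10))
  ss <- streamline_set(list(crosser, ender, outside))
  pass <- filter_streamlines(ss, region, "passing")
  term <- filter_streamlines(ss, region, "terminating")
  expect_equal(length(pass), 2L)
  expect_equal(length(term), 1L)
  expect_true(all(term$seed_index %in% pass$seed_index))  # subset property
  # random sets vs brute-force membership
  set.seed(41)
  walks <- lapply(1:30, function(i) {
    n <- sample(5:30, 1)
    apply(matrix(rnorm(n * 3, sd = 1), n, 3), 2, cumsum) + 12
  })
  ss2 <- streamline_set(walks)
  inreg <- function(p) {
    iw <- world_to_index(geom, p)
    ok <- clarityatlas:::in_bounds(iw, c(30L, 10L, 10L))
    any(region$data[clarityatlas:::linear_index(iw[ok, , drop = FALSE],
                                                c(30L, 10L, 10L))])
  }
  want_pass <- vapply(walks, inreg, logical(1))
  want_term <- vapply(walks, function(p)
    inreg(p[c(1, nrow(p)), , drop = FALSE]), logical(1))
  expect_equal(filter_streamlines(ss2, region, "passing")$seed_index,
               which(want_pass))
  expect_equal(filter_streamlines(ss2, region, "terminating")$seed_index,
               which(want_term))
})

test_that("region connectivity ranks planted terminal regions first", {
  ta <- make_toy_atlas()
  lab <- ta$labels
  dm <- dim(lab$data)
  # all bundles start in the seed region at the volume centre and end in
  # three planted corner regions, traversing several regions on the way
  seed_vox <- matrix(dm %/% 2, 1)
  seed_id <- lab$data[seed_vox]
  corner_vox <- rbind(c(3, 3, 3), c(dm[1] - 3, 3, dm[3] - 3),
                      c(3, dm[2] - 3, dm[3] - 3))
  enders <- lab$data[corner_vox]
  jit <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(1, 1, 0),
               c(0, 0, 1), c(1, 0, 1))
  mk_stream <- function(k, j) {
    start <- index_to_world(lab, seed_vox + jit[j, , drop = FALSE])
    endpt <- index_to_world(lab, corner_vox[k, , drop = FALSE])
    t <- seq(0, 1, length.out = 120)
    outer(1 - t, as.numeric(start)) + outer(t, as.numeric(endpt))
  }
  ss <- streamline_set(mapply(mk_stream, rep(1:3, 2), 1:6,
                              SIMPLIFY = FALSE))
  maps <- density_and_terminal_maps(ss, lab)
  # mask the seed-side terminal cluster, as the terminal workflow does
  seedm <- vg_mask(lab, FALSE)
  seedm$data[seed_vox[1] + (0:1), seed_vox[2] + (0:1),
             seed_vox[3] + (0:1)] <- TRUE
  term <- mask_injection_component(maps$terminals, seedm)
  rc_term <- region_connectivity(terminals = term, labels = lab,
                                 mode = "terminal")
  expect_setequal(rc_term$id[rc_term$rank <= 3], enders)
  expect_true(all(rc_term$weight[rc_term$rank <= 3] == 2))
  expect_true(all(rc_term$weight[rc_term$rank > 3] == 0))
  # regions only traversed: zero terminal weight but nonzero passing weight
  rc_pass <- region_connectivity(tdi = maps$tdi, labels = lab,
                                 mode = "passing")
  traversed <- setdiff(rc_pass$id[rc_pass$weight > 0],
                       c(enders, seed_id))
  expect_gt(length(traversed), 0)
  for (id in traversed)
    expect_equal(rc_term$weight[rc_term$id == id], 0)
})

test_that("tube-seeded streamlines follow the centerline end to end", {
  tp <- make_tube_phantom(shape = c(64, 64, 64), radius_vox = 3, snr = 8,
                          seed = 1)
  # integration scale of the tensor smoothing >= tube radius stabilizes
  # in-tube orientations enough for drift-free full-length tracking
  tf <- structure_tensor_field(tp$volume,
                               sta_params(sigma_dog_um = 1, sigma_g_um = 4))
  of <- orientation_field(tf)
  dm <- dim(tp$volume$data)
  ctr <- (dm + 1) / 2
  idx <- which(array(TRUE, dm), arr.ind = TRUE)
  r2 <- (idx[, 1] - ctr[1])^2 + (idx[, 2] - ctr[2])^2
  seedm <- vg(array(0, dm))
  seedm$data[idx[r2 <= 2^2 & idx[, 3] > 28 & idx[, 3] <= 36, ]] <- 1
  st <- fact_track(of, seedm, NULL, sta_params(step_um = 0.5))
  ok <- vapply(st$points, function(p) {
    lat <- sqrt((p[, 1] - (ctr[1] - 1))^2 + (p[, 2] - (ctr[2] - 1))^2)
    all(lat <= 2) && diff(range(p[, 3])) >= 50
  }, logical(1))
  expect_gte(mean(ok), 0.9)
})

test_that("TCK files round-trip streamlines through millimetre storage", {
  set.seed(61)
  ss <- streamline_set(list(matrix(rnorm(30, sd = 100), 10, 3),
                            matrix(rnorm(15, sd = 100), 5, 3)))
  f <- withr::local_tempfile(fileext = ".tck")
  write_tck(ss, f)
  ss2 <- read_tck(f)
  expect_length(ss2, 2L)
  for (i in 1:2)
    expect_equal(ss2$points[[i]], ss$points[[i]], tolerance = 1e-4)
  expect_error(read_tck(withr::local_tempfile(fileext = ".txt",
                                              lines = "nope")), "TCK")
})
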