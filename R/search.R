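#' Locate a cut section inside a whole-brain volume
#'
#' Coarse-to-fine multi-round similarity search. Round 1 slides a window
#' over the whole volume at a stride of a third of the section size; each
#' later round halves the stride (floor, minimum 1) and searches a window
#' around the incumbent best offset. Every round scores candidates on
#' data low-passed to that round's stride scale (the pyramid), so the
#' basin around the true offset stays wider than the stride; the reported
#' offset and similarity always track the raw (unsmoothed) metric, and
#' the incumbent is re-scored each round, so the reported best similarity
#' is non-increasing across rounds. The similarity is the mean squared
#' intensity difference between section and candidate segment after
#' z-score normalization of both patches (robust to intensity
#' inhomogeneity; `raw_msd = TRUE` compares raw intensities). The
#' returned segment is the best match expanded by `expand` per axis
#' (clipped to the volume) to absorb boundary matching errors.
#'
#' @param whole a [voxel_grid()], the whole-brain volume.
#' @param section a [voxel_grid()] with shape `<=` the whole volume per
#'   axis and the same spacing.
#' @param rounds number of search rounds (default 5, including the tiling
#'   round).
#' @param expand fractional expansion of the final segment per axis
#'   (default 0.15).
#' @param raw_msd disable patch z-scoring.
#' @param beam_width number of well-separated incumbent offsets carried
#'   between rounds. The tiling round can rank a remote look-alike just
#'   above the true basin; refining a few separated candidates in
#'   parallel and reporting the best raw-metric match makes the search
#'   robust to such aliases.
#' @return List with `offset_vox` (1-based corner of the best match),
#'   `similarity`, `final_stride`, `round_trace` (tibble: round, stride,
#'   offset, similarity), `segment` (expanded [voxel_grid()]) and
#'   `segment_offset_vox`.
#' @export
pyramid_search <- function(whole, section, rounds = 5, expand = 0.15,
                           raw_msd = FALSE, beam_width = 4) {
  stopifnot(is_voxel_grid(whole), is_voxel_grid(section))
  if (max(abs(whole$spacing_um - section$spacing_um)) > 1e-6)
    stop("whole and section must share voxel spacing (resample first)",
         call. = FALSE)
  dw <- dim(whole$data)
  ds <- dim(section$data)
  if (any(ds > dw))
    stop("section larger than the whole volume", call. = FALSE)
  if (stats::sd(section$data) == 0)
    stop("all-constant section; similarity is degenerate", call. = FALSE)
  score_on <- function(vol, sec, off) {
    patch <- vol[off[1]:(off[1] + ds[1] - 1),
                 off[2]:(off[2] + ds[2] - 1),
                 off[3]:(off[3] + ds[3] - 1)]
    if (!raw_msd) {
      s <- stats::sd(patch)
      patch <- if (s == 0) patch * 0 else (patch - mean(patch)) / s
    }
    mean((patch - sec)^2)
  }
  prep_sec <- function(sec) {
    if (raw_msd) sec else (sec - mean(sec)) / stats::sd(sec)
  }
  smooth_axes <- function(arr, sig) {
    for (ax in 1:3)
      if (sig[ax] > 0.75)
        arr <- conv_axis(arr, gaussian_kernel(sig[ax]), ax)
    arr
  }
  max_off <- dw - ds + 1L
  sec_raw <- prep_sec(section$data)
  beam <- NULL        # incumbent offsets, ranked by the round's smoothed score
  best_raw <- NULL    # best raw-score offset seen so far (the answer)
  best_sim <- Inf
  stride <- ds
  trace <- list()
  for (r in seq_len(rounds)) {
    if (r == 1L) {
      # overlapping tiles at a third of the section size: worst-case
      # misalignment of ds/6, which keeps the true basin visible to the
      # low-passed similarity of this round
      stride <- pmax(1L, ds %/% 3L)
      grids <- lapply(1:3, function(ax) {
        o <- seq(1L, max_off[ax], by = stride[ax])
        unique(c(o, max_off[ax]))  # cover the far edge
      })
      offs <- as.matrix(expand.grid(grids[[1]], grids[[2]], grids[[3]]))
    } else {
      stride <- pmax(1L, stride %/% 2L)
      offs <- do.call(rbind, lapply(seq_len(nrow(beam)), function(b) {
        grids <- lapply(1:3, function(ax) {
          o <- beam[b, ax] + seq(-2L, 2L) * stride[ax]
          unique(pmin(pmax(o, 1L), max_off[ax]))
        })
        as.matrix(expand.grid(grids[[1]], grids[[2]], grids[[3]]))
      }))
      offs <- offs[!duplicated(offs), , drop = FALSE]
    }
    # pyramid level: score on data low-passed to the round's stride scale,
    # so the basin of the true offset is wider than the search stride
    sig <- stride / 2
    if (any(sig > 0.75)) {
      wh_s <- smooth_axes(whole$data, sig)
      sec_s <- prep_sec(smooth_axes(section$data, sig))
    } else {
      wh_s <- whole$data
      sec_s <- sec_raw
    }
    # lexicographic candidate order makes the smallest-offset tie win
    offs <- offs[order(offs[, 1], offs[, 2], offs[, 3]), , drop = FALSE]
    fine_round <- max(stride) <= 2L
    sims <- numeric(nrow(offs))
    for (i in seq_len(nrow(offs))) {
      sims[i] <- score_on(wh_s, sec_s, offs[i, ])
      if (fine_round) {
        sr <- score_on(whole$data, sec_raw, offs[i, ])
        if (sr < best_sim - 1e-15) {
          best_sim <- sr
          best_raw <- as.integer(offs[i, ])
        }
      }
    }
    # next beam: best candidates, kept mutually separated so distinct
    # basins survive into the refinement rounds
    ord <- order(sims)
    sep <- 2L * stride
    picked <- integer(0)
    for (i in ord) {
      if (length(picked) >= beam_width) break
      if (all(vapply(picked, function(j)
        any(abs(offs[i, ] - offs[j, ]) > sep), logical(1))) ||
        length(picked) == 0L)
        picked <- c(picked, i)
    }
    beam <- offs[picked, , drop = FALSE]
    if (!fine_round) {
      # coarse rounds contribute only their winners to the raw-metric trace
      for (b in seq_len(nrow(beam))) {
        sr <- score_on(whole$data, sec_raw, beam[b, ])
        if (sr < best_sim - 1e-15) {
          best_sim <- sr
          best_raw <- as.integer(beam[b, ])
        }
      }
    }
    trace[[r]] <- tibble::tibble(round = r,
                                 stride = paste(stride, collapse = "x"),
                                 offset_x = best_raw[1],
                                 offset_y = best_raw[2],
                                 offset_z = best_raw[3],
                                 similarity = best_sim)
  }
  best <- best_raw
  margin <- round(ds * expand / 2)
  lo <- pmax(best - margin, 1L)
  hi <- pmin(best + ds - 1L + margin, dw)
  seg <- whole$data[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE]
  segment <- voxel_grid(seg, spacing_um = whole$spacing_um,
                        origin_um = index_to_world(whole, matrix(lo, 1)),
                        axes = whole$axes)
  list(offset_vox = best, similarity = best_sim, final_stride = stride,
       round_trace = do.call(rbind, trace), segment = segment,
       segment_offset_vox = as.integer(lo))
}
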