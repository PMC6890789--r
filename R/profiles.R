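#' Sample along-tract intensity profiles
#'
#' Each streamline is resampled to `n_nodes` equally spaced arc-length
#' positions; the intensity volume is sampled there by trilinear
#' interpolation (points outside the volume clamp to the edge). Profiles
#' are then averaged over bundles of `bundle_size` adjacent streamlines —
#' adjacency meaning consecutive in seed order, which for deterministic
#' lexicographic seeding tracks spatial adjacency.
#'
#' @param intensity a [voxel_grid()].
#' @param streams a [streamline_set()].
#' @param n_nodes nodes per profile (default 100).
#' @param bundle_size streamlines averaged per bundle (default 10).
#' @return A `tract_profile`: matrix `bundles x nodes` of mean intensity,
#'   with the per-streamline node matrix in `attr(, "streamline_profiles")`.
#' @export
sample_profiles <- function(intensity, streams, n_nodes = 100,
                            bundle_size = 10) {
  stopifnot(is_voxel_grid(intensity), inherits(streams, "streamline_set"))
  ns <- length(streams$points)
  if (ns == 0) stop("empty streamline set", call. = FALSE)
  if (ns < bundle_size)
    warning("fewer streamlines than bundle_size; single partial bundle")
  ord <- order(streams$seed_index)
  prof <- matrix(NA_real_, ns, n_nodes)
  for (i in seq_len(ns)) {
    p <- resample_polyline(streams$points[[ord[i]]], n_nodes)
    prof[i, ] <- interp_trilinear(intensity, p)
  }
  bundle <- (seq_len(ns) - 1L) %/% bundle_size + 1L
  nb <- max(bundle)
  out <- matrix(NA_real_, nb, n_nodes)
  for (b in seq_len(nb))
    out[b, ] <- colMeans(prof[bundle == b, , drop = FALSE])
  structure(out, streamline_profiles = prof, class = "tract_profile")
}

# arc-length resampling of an n x 3 polyline to n_nodes points
resample_polyline <- function(p, n_nodes) {
  seg <- sqrt(rowSums(diff(p)^2))
  s <- c(0, cumsum(seg))
  total <- s[length(s)]
  if (total == 0) return(matrix(rep(p[1, ], each = n_nodes), ncol = 3))
  t_out <- seq(0, total, length.out = n_nodes)
  cbind(stats::approx(s, p[, 1], xout = t_out, ties = "ordered")$y,
        stats::approx(s, p[, 2], xout = t_out, ties = "ordered")$y,
        stats::approx(s, p[, 3], xout = t_out, ties = "ordered")$y)
}

#' Hemisphere asymmetry of tract profiles, with a group test
#'
#' For each subject the mean profile (over bundles) is compared between
#' hemispheres: the asymmetry is the mean over nodes of
#' `|contra - ipsi| / mean(contra) * 100` (percent). The signed variant
#' `(contra - ipsi) / mean(contra) * 100` is also reported per node. A
#' two-sided two-sample Student's t-test compares the per-subject
#' asymmetries between the two groups.
#'
#' @param profiles_ipsi,profiles_contra lists of `tract_profile` objects
#'   (or plain matrices), one per subject, matched node counts.
#' @param groups character/factor of group membership per subject (two
#'   levels).
#' @return List with `subjects` (tibble: `subject`, `group`,
#'   `asymmetry_pct`), `signed_profiles` (subjects x nodes matrix), and
#'   `test` (tibble: `t`, `p`, `df`, group means).
#' @export
hemisphere_asymmetry <- function(profiles_ipsi, profiles_contra, groups) {
  stopifnot(length(profiles_ipsi) == length(profiles_contra),
            length(groups) == length(profiles_ipsi))
  n <- length(profiles_ipsi)
  mean_profile <- function(p) {
    m <- unclass(p)
    if (is.matrix(m)) colMeans(m) else as.numeric(m)
  }
  asym <- rep(NA_real_, n)
  signed <- NULL
  for (i in seq_len(n)) {
    pi_ <- mean_profile(profiles_ipsi[[i]])
    pc <- mean_profile(profiles_contra[[i]])
    if (length(pi_) != length(pc))
      stop("node counts differ between hemispheres", call. = FALSE)
    mc <- mean(pc)
    if (mc == 0) {
      warning("subject ", i, " has zero contralateral mean; excluded")
      next
    }
    asym[i] <- mean(abs(pc - pi_)) / mc * 100
    sgn <- (pc - pi_) / mc * 100
    if (is.null(signed)) signed <- matrix(NA_real_, n, length(sgn))
    signed[i, ] <- sgn
  }
  subj <- tibble::tibble(subject = seq_len(n), group = as.character(groups),
                         asymmetry_pct = asym)
  g <- as.character(groups)[is.finite(asym)]
  test <- if (length(unique(g)) == 2 && min(table(g)) >= 2)
    asymmetry_group_test(asym, groups) else NULL
  list(subjects = subj, signed_profiles = signed, test = test)
}

#' Two-sample t-test on per-subject asymmetries
#'
#' @param asymmetry_pct numeric vector of per-subject asymmetries
#'   (`NA` = excluded subject).
#' @param groups two-level group membership.
#' @return Tibble with `t`, `df`, `p`, `mean_1`, `mean_2` and group labels.
#' @export
asymmetry_group_test <- function(asymmetry_pct, groups) {
  g <- as.character(groups)
  keep <- is.finite(asymmetry_pct)
  g <- g[keep]
  a <- asymmetry_pct[keep]
  lev <- unique(g)
  if (length(lev) != 2) stop("need exactly two groups", call. = FALSE)
  if (min(table(g)) < 2) stop("need >= 2 subjects per group", call. = FALSE)
  ht <- stats::t.test(a[g == lev[1]], a[g == lev[2]], var.equal = TRUE)
  tibble::tibble(group_1 = lev[1], group_2 = lev[2],
                 mean_1 = mean(a[g == lev[1]]),
                 mean_2 = mean(a[g == lev[2]]),
                 t = unname(ht$statistic), df = unname(ht$parameter),
                 p = ht$p.value)
}
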