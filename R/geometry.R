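# Trajectory-analysis coordinates: spline-based DNA helical axis,
# nucleosome symmetry axis, sliding coordinate zeta (mapped to base pairs
# via a reference table), DNA rotation coordinate eta, RMSD of the central
# DNA, per-SHL sliding and the loop-size coordinate Delta-R.

#' Least-squares circle fit in a plane
#'
#' Algebraic (Kasa) fit: exact on noiseless circles, stable for the
#' 10-point sets produced by the DNA-axis construction.
#'
#' @param xy numeric matrix (n x 2).
#' @return list with \code{center} (length 2) and \code{radius}.
#' @export
circle_fit <- function(xy) {
  stopifnot(ncol(xy) == 2, nrow(xy) >= 3)
  A <- cbind(xy, 1)
  b <- rowSums(xy^2)
  sol <- qr.solve(A, b)
  cx <- sol[1] / 2; cy <- sol[2] / 2
  r <- sqrt(sol[3] + cx^2 + cy^2)
  list(center = c(cx, cy), radius = r)
}

# plane through points: centroid + unit normal (smallest principal axis)
.plane_fit <- function(p) {
  ctr <- colMeans(p)
  s <- svd(sweep(p, 2, ctr))
  list(center = ctr, normal = s$v[, 3],
       e1 = s$v[, 1], e2 = s$v[, 2])
}

# natural cubic spline through 3D control points, chord-length
# parameterized; returns the points obtained by subdividing each segment
# into n_sub equal parameter steps, with the (linearly interpolated)
# control label of each point in attribute "label"
.spline_subdivide <- function(ctrl, n_sub = 10, labels = seq_len(nrow(ctrl))) {
  t0 <- c(0, cumsum(sqrt(rowSums(diff(ctrl)^2))))
  m <- nrow(ctrl)
  tt <- unlist(lapply(seq_len(m - 1), function(k)
    t0[k] + (0:(n_sub - 1)) / n_sub * (t0[k + 1] - t0[k])))
  tt <- c(tt, t0[m])
  lab <- unlist(lapply(seq_len(m - 1), function(k)
    labels[k] + (0:(n_sub - 1)) / n_sub * (labels[k + 1] - labels[k])))
  lab <- c(lab, labels[m])
  fx <- stats::splinefun(t0, ctrl[, 1], method = "natural")
  fy <- stats::splinefun(t0, ctrl[, 2], method = "natural")
  fz <- stats::splinefun(t0, ctrl[, 3], method = "natural")
  out <- cbind(fx(tt), fy(tt), fz(tt))
  attr(out, "label") <- lab
  out
}

#' Extract the DNA helical axis of a frame
#'
#' Ten contour lines are drawn on the DNA tube as natural cubic splines,
#' contour j connecting every strand-1 phosphate whose base-pair index is
#' congruent to j modulo 10 (one helical repeat apart). Each spline
#' segment is subdivided into 10 equal parameter steps; for a given
#' phosphate, the nearest subdivision point on each of the 10 contours is
#' collected, the 10 points are plane-fitted and projected, and the axis
#' position at that base pair is the center of the fitted circle. Tangents
#' are finite differences of consecutive axis points.
#'
#' @param frame a \code{cg_structure} whose strand 1 has at least 31
#'   phosphates.
#' @param bp optional integer vector of base-pair indices at which the
#'   axis is required (default: the full valid window, i.e. base pairs
#'   with phosphates one helical repeat away on both sides).
#' @return a \code{dna_axis} object: data.frame-like list with \code{bp},
#'   \code{points} (n x 3), \code{tangents} (n x 3, unit), \code{radius}
#'   (fitted circle radii).
#' @export
dna_axis <- function(frame, bp = NULL) {
  ph <- strand1_phosphates(frame)
  if (nrow(ph) < 31)
    stop("strand 1 has only ", nrow(ph),
         " phosphates; at least 31 are needed for the 10-contour axis")
  xyz <- coords(frame)[ph$row, , drop = FALSE]
  valid <- ph$bp[ph$bp %in% (ph$bp + 10) & ph$bp %in% (ph$bp - 10)]
  if (is.null(bp)) {
    bp_out <- valid
  } else {
    if (!all(bp %in% valid))
      stop("base pair(s) ", paste(setdiff(bp, valid), collapse = ","),
           " outside the valid axis window")
    # tangents need neighbours: extend by one bp each side where possible
    bp_out <- sort(unique(c(bp, pmax(min(valid), min(bp) - 1),
                            pmin(max(valid), max(bp) + 1))))
    bp_out <- bp_out[bp_out %in% valid]
  }
  contours <- lapply(0:9, function(j) {
    sel <- which(ph$bp %% 10 == j)
    if (length(sel) < 2) return(NULL)
    .spline_subdivide(xyz[sel, , drop = FALSE], 10, labels = ph$bp[sel])
  })
  pts <- matrix(NA_real_, length(bp_out), 3)
  rad <- numeric(length(bp_out))
  for (k in seq_along(bp_out)) {
    p0 <- xyz[match(bp_out[k], ph$bp), ]
    ten <- t(vapply(contours, function(cc) {
      # search the contour only within one helical repeat of this base
      # pair: the cross-section neighbourhood, so the minimum cannot
      # drift along the strongly curved tube
      lab <- attr(cc, "label")
      loc <- which(abs(lab - bp_out[k]) <= 10)
      if (!length(loc)) loc <- seq_len(nrow(cc))
      d2 <- (cc[loc, 1] - p0[1])^2 + (cc[loc, 2] - p0[2])^2 +
        (cc[loc, 3] - p0[3])^2
      cc[loc[which.min(d2)], ]
    }, numeric(3)))
    pl <- .plane_fit(ten)
    loc <- sweep(ten, 2, pl$center)
    xy <- cbind(loc %*% pl$e1, loc %*% pl$e2)
    cf <- circle_fit(xy)
    pts[k, ] <- pl$center + cf$center[1] * pl$e1 + cf$center[2] * pl$e2
    rad[k] <- cf$radius
  }
  # tangents toward increasing bp by central/one-sided differences
  tg <- matrix(NA_real_, length(bp_out), 3)
  for (k in seq_along(bp_out)) {
    k0 <- max(1, k - 1); k1 <- min(length(bp_out), k + 1)
    if (k1 == k0) stop("cannot form a tangent from a single axis point")
    tg[k, ] <- .unit(pts[k1, ] - pts[k0, ])
  }
  structure(list(bp = bp_out, points = pts, tangents = tg, radius = rad),
            class = "dna_axis")
}

#' Nucleosome symmetry (dyad) axis
#'
#' Total-least-squares straight line through the centers of geometry of
#' the symmetric CA bead pairs across the two copies of each histone
#' (flexible tails excluded). The direction sign is fixed to point from
#' the histone-core centroid toward \code{toward} when given.
#'
#' @param frame a \code{cg_structure}.
#' @param pairs data.frame \code{chain_a, resid_a, chain_b, resid_b};
#'   defaults to the pairs stored in the structure.
#' @param toward optional 3-point used to orient the direction.
#' @return list with \code{point} (on the line) and unit \code{direction}.
#' @export
symmetry_axis <- function(frame, pairs = NULL, toward = NULL) {
  if (is.null(pairs)) pairs <- frame$symmetric_pairs
  if (is.null(pairs) || nrow(pairs) < 2)
    stop("at least 2 symmetric pairs are required")
  xyz <- coords(frame)
  b <- frame$beads
  mid <- t(vapply(seq_len(nrow(pairs)), function(k) {
    ia <- bead_row(frame, pairs$chain_a[k], pairs$resid_a[k], "CA")
    ib <- bead_row(frame, pairs$chain_b[k], pairs$resid_b[k], "CA")
    if (is.na(ia) || is.na(ib))
      stop("symmetric pair ", k, " refers to a missing CA bead")
    if (isTRUE(b$tail[ia]) || isTRUE(b$tail[ib]))
      stop("symmetric pair ", k, " lies on a flexible tail")
    (xyz[ia, ] + xyz[ib, ]) / 2
  }, numeric(3)))
  ctr <- colMeans(mid)
  dev <- sweep(mid, 2, ctr)
  if (max(abs(dev)) < 1e-9)
    stop("all pair midpoints coincide; symmetry axis undefined")
  s <- svd(dev)
  dir <- s$v[, 1]
  if (!is.null(toward)) {
    if (sum(dir * (toward - core_centroid(frame))) < 0) dir <- -dir
  }
  list(point = ctr, direction = dir)
}

#' Normal of the DNA superhelical wrap
#'
#' The smallest-variance principal axis of the strand-1 phosphate cloud,
#' oriented so that the base-pair index increases counter-clockwise around
#' it. Used to give the sliding coordinate a sign.
#'
#' @param frame a \code{cg_structure}.
#' @return unit 3-vector.
#' @export
superhelix_normal <- function(frame) {
  ph <- strand1_phosphates(frame)
  p <- coords(frame)[ph$row, , drop = FALSE]
  ctr <- colMeans(p)
  dev <- sweep(p, 2, ctr)
  n <- svd(dev)$v[, 3]
  cr <- 0
  for (i in seq_len(nrow(dev) - 1)) {
    cr <- cr + sum(n * c(dev[i, 2] * dev[i + 1, 3] - dev[i, 3] * dev[i + 1, 2],
                         dev[i, 3] * dev[i + 1, 1] - dev[i, 1] * dev[i + 1, 3],
                         dev[i, 1] * dev[i + 1, 2] - dev[i, 2] * dev[i + 1, 1]))
  }
  if (cr < 0) n <- -n
  n
}

#' Center of a base pair
#'
#' Centroid of all available beads (P, S, B of both strands) of the base
#' pair.
#' @param frame a \code{cg_structure}.
#' @param bp base-pair index (0-based).
#' @return length-3 numeric vector.
#' @export
bp_center <- function(frame, bp) {
  colMeans(coords(frame)[bp_rows(frame, bp), , drop = FALSE])
}

#' Sliding coordinate zeta of a base pair
#'
#' The signed angle, about the superhelix normal, between the nucleosome
#' symmetry axis and the vector from the histone-core centroid to the
#' center of the tracked base pair. Both vectors are projected onto the
#' plane perpendicular to the normal; the sign is positive when the base
#' pair lies counter-clockwise (increasing bp index) of the symmetry axis.
#'
#' @param frame a \code{cg_structure}.
#' @param bp tracked base-pair index.
#' @param sym symmetry axis (from \code{\link{symmetry_axis}}); computed
#'   if \code{NULL}.
#' @param normal superhelix normal; computed if \code{NULL}.
#' @return signed angle in degrees.
#' @export
sliding_zeta <- function(frame, bp, sym = NULL, normal = NULL) {
  if (is.null(normal)) normal <- superhelix_normal(frame)
  if (is.null(sym)) sym <- symmetry_axis(frame, toward = bp_center(frame, bp))
  a <- sym$direction
  b <- bp_center(frame, bp) - core_centroid(frame)
  ap <- a - sum(a * normal) * normal
  bp_ <- b - sum(b * normal) * normal
  cr <- c(ap[2] * bp_[3] - ap[3] * bp_[2],
          ap[3] * bp_[1] - ap[1] * bp_[3],
          ap[1] * bp_[2] - ap[2] * bp_[1])
  .deg(atan2(sum(normal * cr), sum(ap * bp_)))
}

#' Reference table mapping base-pair index to zeta
#'
#' Built from one (initial) frame: zeta is evaluated for every base pair
#' in the window and unwrapped along the index so the table is strictly
#' monotone; it is the lookup used to convert measured zeta angles to slid
#' base pairs.
#'
#' @param frame the reference \code{cg_structure}.
#' @param bp_range integer vector of base-pair indices (ordered).
#' @param sym,normal optional precomputed axes.
#' @return a \code{zeta_table} data.frame with columns \code{bp, zeta}.
#' @export
zeta_table <- function(frame, bp_range, sym = NULL, normal = NULL) {
  if (!length(bp_range)) stop("empty base-pair range")
  if (is.null(normal)) normal <- superhelix_normal(frame)
  if (is.null(sym))
    sym <- symmetry_axis(frame,
                         toward = bp_center(frame, stats::median(bp_range)))
  z <- vapply(bp_range, function(b)
    sliding_zeta(frame, b, sym = sym, normal = normal), 0)
  z <- .unwrap_deg(z)
  d <- diff(z)
  if (!(all(d > 0) || all(d < 0)))
    stop("zeta is not strictly monotone over the requested window; ",
         "narrow the bp range")
  structure(data.frame(bp = bp_range, zeta = z), class = c("zeta_table",
                                                           "data.frame"))
}

# unwrap a degree series: remove +-360 jumps between consecutive entries
.unwrap_deg <- function(z) {
  if (length(z) < 2) return(z)
  dz <- diff(z)
  corr <- cumsum(c(0, -360 * round(dz / 360)))
  z + corr
}

#' Convert a zeta angle to slid base pairs
#'
#' Table entries map exactly to their integer base pair; interior angles
#' are linearly interpolated between the two neighbouring entries. Angles
#' outside the table window are linearly extrapolated from the terminal
#' segment, with a warning. The incoming angle is first aligned to the
#' table's branch by adding the multiple of 360 degrees closest to the
#' window.
#'
#' @param zeta angle in degrees (scalar or vector).
#' @param table a \code{\link{zeta_table}}.
#' @return base-pair position(s), fractional.
#' @export
zeta_to_bp <- function(zeta, table) {
  if (is.null(table) || !nrow(table)) stop("empty zeta table")
  zt <- table$zeta
  mid <- mean(range(zt))
  vapply(zeta, function(z) {
    z <- z + 360 * round((mid - z) / 360)
    if (z < min(zt) || z > max(zt)) {
      warning("zeta ", format(z, digits = 4),
              " outside the table window; extrapolating")
      if (abs(z - zt[1]) < abs(z - zt[length(zt)])) {
        k <- 1
      } else {
        k <- nrow(table) - 1
      }
      return(table$bp[k] + (z - zt[k]) / (zt[k + 1] - zt[k]) *
               (table$bp[k + 1] - table$bp[k]))
    }
    stats::approx(zt, table$bp, xout = z)$y
  }, 0)
}

#' Rotation coordinate eta of a base pair
#'
#' The signed angle, in the plane perpendicular to the local DNA tangent,
#' from the vector pointing from the DNA axis to the histone-core centroid
#' to the vector pointing from the DNA axis to the strand-1 phosphate of
#' the tracked base pair. Positive rotation is right-handed about the
#' tangent oriented toward increasing base-pair index. Use
#' \code{\link{analyze_trajectory}} for per-trajectory unwrapping.
#'
#' @param frame a \code{cg_structure}.
#' @param bp tracked base-pair index (must lie in the axis window).
#' @param axis optional precomputed \code{\link{dna_axis}} covering
#'   \code{bp}.
#' @return angle in degrees, in (-180, 180].
#' @export
rotation_eta <- function(frame, bp, axis = NULL) {
  if (is.null(axis)) axis <- dna_axis(frame, bp = bp)
  k <- match(bp, axis$bp)
  if (is.na(k)) stop("base pair ", bp, " outside the DNA-axis window")
  ph <- strand1_phosphates(frame)
  pr <- ph$row[match(bp, ph$bp)]
  if (is.na(pr)) stop("base pair ", bp, " has no strand-1 phosphate")
  o <- axis$points[k, ]
  t <- axis$tangents[k, ]
  v_ph <- coords(frame)[pr, ] - o
  v_ref <- core_centroid(frame) - o
  v_ph <- v_ph - sum(v_ph * t) * t
  v_ref <- v_ref - sum(v_ref * t) * t
  cr <- c(v_ref[2] * v_ph[3] - v_ref[3] * v_ph[2],
          v_ref[3] * v_ph[1] - v_ref[1] * v_ph[3],
          v_ref[1] * v_ph[2] - v_ref[2] * v_ph[1])
  .deg(atan2(sum(t * cr), sum(v_ref * v_ph)))
}

#' Sliding and rotation coordinates along a trajectory
#'
#' For the base pair initially at the dyad (or any tracked base pair):
#' per frame, the sliding angle zeta, its conversion to slid base pairs
#' through the initial-frame reference table, and the unwrapped DNA
#' rotation coordinate eta.
#'
#' @param traj a \code{cg_trajectory}.
#' @param tracked_bp base-pair index to follow (default: the topology's
#'   dyad if it carries a superhelix spec, else the central base pair).
#' @param table_halfwidth half-width (bp) of the zeta reference table
#'   around the tracked base pair (default 30).
#' @param smooth optional trailing moving-average window (frames) applied
#'   to the returned series; 0 (default) disables smoothing.
#' @return data.frame with columns \code{frame, zeta, eta, bp_shift}
#'   (\code{bp_shift} in bp relative to the tracked base pair's initial
#'   position).
#' @export
analyze_trajectory <- function(traj, tracked_bp = NULL, table_halfwidth = 30,
                               smooth = 0) {
  topo <- traj$topology
  if (is.null(tracked_bp)) {
    sp <- attr(topo, "spec")
    tracked_bp <- if (!is.null(sp)) sp$linker_bp + (sp$n_wrapped_bp - 1) / 2
    else floor(topo$n_bp / 2)
  }
  f1 <- frame_structure(traj, 1)
  rng <- max(0, tracked_bp - table_halfwidth):
    min(topo$n_bp - 1, tracked_bp + table_halfwidth)
  tab <- zeta_table(f1, rng)
  dir_prev <- NULL
  out <- lapply(seq_len(n_frames(traj)), function(i) {
    fr <- frame_structure(traj, i)
    nrm <- superhelix_normal(fr)
    sym <- symmetry_axis(fr, toward = bp_center(fr, tracked_bp))
    if (!is.null(dir_prev) && sum(sym$direction * dir_prev) < 0)
      sym$direction <- -sym$direction
    dir_prev <<- sym$direction
    z <- sliding_zeta(fr, tracked_bp, sym = sym, normal = nrm)
    ax <- dna_axis(fr, bp = tracked_bp)
    e <- rotation_eta(fr, tracked_bp, axis = ax)
    data.frame(frame = i, zeta = z, eta = e)
  })
  out <- do.call(rbind, out)
  out$eta <- .unwrap_deg(out$eta)
  out$bp_shift <- zeta_to_bp(out$zeta, tab) - tracked_bp
  if (smooth > 1) {
    ma <- function(x) stats::filter(x, rep(1 / smooth, smooth), sides = 1)
    out$zeta <- as.numeric(ma(out$zeta))
    out$eta <- as.numeric(ma(out$eta))
    out$bp_shift <- as.numeric(ma(out$bp_shift))
  }
  out
}

#' RMSD of the central DNA after superposition on the histone core
#'
#' Optimal least-squares superposition (Kabsch) of the frame onto the
#' reference using the non-tail histone beads, followed by the RMSD over
#' the beads of the central base pairs (default the 20 bp around the
#' dyad): the drift measure for nucleosomal DNA relative to the core.
#'
#' @param frame,reference \code{cg_structure}s with identical bead tables.
#' @param central_bp how many central base pairs to measure (default 20).
#' @param tracked_bp center of the measured window (default: dyad as in
#'   \code{\link{analyze_trajectory}}).
#' @return RMSD in Angstrom.
#' @export
rmsd_central <- function(frame, reference, central_bp = 20,
                         tracked_bp = NULL) {
  if (is.null(tracked_bp)) {
    sp <- attr(reference, "spec")
    tracked_bp <- if (!is.null(sp)) sp$linker_bp + (sp$n_wrapped_bp - 1) / 2
    else floor(reference$n_bp / 2)
  }
  fit_rows <- reference$core_rows
  if (length(fit_rows) < 3) stop("fewer than 3 histone-core beads to fit on")
  half <- floor(central_bp / 2)
  bps <- max(0, tracked_bp - half):min(reference$n_bp - 1,
                                       tracked_bp + half - 1 + central_bp %% 2)
  meas_rows <- unlist(lapply(bps, function(b) bp_rows(reference, b)))
  fitted <- bio3d::fit.xyz(fixed = as.numeric(t(coords(reference))),
                           mobile = as.numeric(t(coords(frame))),
                           fixed.inds = bio3d::atom2xyz(fit_rows),
                           mobile.inds = bio3d::atom2xyz(fit_rows))
  fxyz <- matrix(fitted, ncol = 3, byrow = TRUE)
  d <- fxyz[meas_rows, , drop = FALSE] -
    coords(reference)[meas_rows, , drop = FALSE]
  sqrt(mean(rowSums(d^2)))
}

#' Per-SHL sliding coordinates along a trajectory
#'
#' Follows the base pairs initially at the requested superhelical
#' locations; each SHL has its own local zeta reference table, so
#' cooperative (simultaneous) and sequential (loop-propagated) motion can
#' be distinguished.
#'
#' @param traj a \code{cg_trajectory}.
#' @param shls numeric vector of superhelical locations (e.g.
#'   \code{c(0, 2, 4, 6)}).
#' @param bp_per_turn base pairs per helical turn used to map SHL to base
#'   pairs (default 10.17, the nucleosomal average; use the fixture's
#'   twist for synthetic data).
#' @param dyad_bp dyad base-pair index (default as in
#'   \code{\link{analyze_trajectory}}).
#' @param table_halfwidth half-width of each local zeta table (default 15).
#' @return data.frame with columns \code{frame, shl, bp_shift}.
#' @export
shl_sliding <- function(traj, shls = c(0, 2, 4, 6), bp_per_turn = 10.17,
                        dyad_bp = NULL, table_halfwidth = 15) {
  topo <- traj$topology
  if (is.null(dyad_bp)) {
    sp <- attr(topo, "spec")
    dyad_bp <- if (!is.null(sp)) sp$linker_bp + (sp$n_wrapped_bp - 1) / 2
    else floor(topo$n_bp / 2)
  }
  f1 <- frame_structure(traj, 1)
  nrm1 <- superhelix_normal(f1)
  out <- list()
  for (h in shls) {
    b0 <- dyad_bp + round(bp_per_turn * h)
    if (b0 < table_halfwidth || b0 > topo$n_bp - 1 - table_halfwidth)
      stop("SHL ", h, " maps outside the analyzable window")
    rng <- (b0 - table_halfwidth):(b0 + table_halfwidth)
    sym1 <- symmetry_axis(f1, toward = bp_center(f1, dyad_bp))
    tab <- zeta_table(f1, rng, sym = sym1, normal = nrm1)
    for (i in seq_len(n_frames(traj))) {
      fr <- frame_structure(traj, i)
      nrm <- superhelix_normal(fr)
      sym <- symmetry_axis(fr, toward = bp_center(fr, dyad_bp))
      if (sum(sym$direction * sym1$direction) < 0)
        sym$direction <- -sym$direction
      z <- sliding_zeta(fr, b0, sym = sym, normal = nrm)
      out[[length(out) + 1]] <- data.frame(
        frame = i, shl = h, bp_shift = zeta_to_bp(z, tab) - b0)
    }
  }
  do.call(rbind, out)
}

#' Loop-size coordinate Delta-R
#'
#' The increase, relative to a reference structure, of the distance
#' between a base pair's center and the histone-core centroid. Values
#' above about 1 Angstrom indicate extra base pairs stored in a local
#' loop (bulge) defect.
#'
#' @param frame,reference \code{cg_structure}s sharing a bead table.
#' @param bp base-pair index (or vector of indices).
#' @return Delta-R in Angstrom (vectorized over \code{bp}).
#' @export
loop_delta_r <- function(frame, reference, bp) {
  vapply(bp, function(b) {
    d1 <- sqrt(sum((bp_center(frame, b) - core_centroid(frame))^2))
    d0 <- sqrt(sum((bp_center(reference, b) - core_centroid(reference))^2))
    d1 - d0
  }, 0)
}
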