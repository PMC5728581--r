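# Residence distributions, free-energy surfaces and reweighting of the
# ensemble to different hydrogen-bond strengths.
#
# A frame-record table holds, per saved frame: the sliding coordinate
# (bp_shift, bp), the rotation coordinate (eta, degrees) and the
# hydrogen-bond energy v_hb (kBT) evaluated at the reference bond strength
# epsilon. Because the bond potential is exactly linear in epsilon, the
# ensemble can be reweighted to any other strength epsilon' with
# per-frame weights w ~ exp(-(epsilon'/epsilon - 1) * v_hb).

#' Assemble a frame-record table
#'
#' @param bp_shift sliding coordinate per frame, bp.
#' @param eta rotation coordinate per frame, degrees (optional).
#' @param v_hb hydrogen-bond energy per frame at the reference strength,
#'   kBT (non-positive under the attractive convention; optional, needed
#'   only for reweighting).
#' @param traj_id trajectory identifier per frame (default 1), used for
#'   burn-in and block bootstrap.
#' @param frame frame number within each trajectory.
#' @return a \code{frame_records} data.frame.
#' @export
frame_records <- function(bp_shift, eta = NA_real_, v_hb = NA_real_,
                          traj_id = 1L, frame = NULL) {
  n <- length(bp_shift)
  if (is.null(frame)) {
    frame <- stats::ave(seq_len(n), rep(traj_id, length.out = n),
                        FUN = seq_along)
  }
  d <- data.frame(traj_id = rep(traj_id, length.out = n),
                  frame = frame, bp_shift = bp_shift,
                  eta = rep(eta, length.out = n),
                  v_hb = rep(v_hb, length.out = n))
  if (any(!is.na(d$v_hb) & d$v_hb > 1e-9))
    warning("positive v_hb values found; the attractive sign convention ",
            "expects v_hb <= 0")
  class(d) <- c("frame_records", "data.frame")
  d
}

#' Discard initial frames of each trajectory
#'
#' Removes the first \code{n_discard} frames of every independent
#' trajectory to eliminate initial-configuration bias. Trajectories
#' shorter than the burn-in are dropped with a warning.
#'
#' @param records a \code{frame_records} data.frame.
#' @param n_discard frames to discard per trajectory.
#' @return the filtered records.
#' @export
burn_in <- function(records, n_discard) {
  stopifnot(n_discard >= 0)
  keep <- logical(nrow(records))
  for (id in unique(records$traj_id)) {
    sel <- which(records$traj_id == id)
    o <- sel[order(records$frame[sel])]
    if (length(o) <= n_discard) {
      warning("trajectory ", id, " has <= ", n_discard,
              " frames; dropped entirely")
      next
    }
    keep[if (n_discard > 0) o[-seq_len(n_discard)] else o] <- TRUE
  }
  records[keep, , drop = FALSE]
}

#' Residence distribution of the sliding coordinate
#'
#' Normalized histogram of the slid base pairs, bins of width
#' \code{bin_width} centered on multiples of the width (so integer-bp
#' states fall at bin centers).
#'
#' @param records a \code{frame_records} data.frame (or numeric vector of
#'   bp shifts).
#' @param bin_width bin width in bp (default 1).
#' @param weights optional per-record weights.
#' @return data.frame with columns \code{bp} (bin center), \code{count},
#'   \code{p} (probability mass, summing to 1).
#' @export
residence_distribution <- function(records, bin_width = 1, weights = NULL) {
  x <- if (is.data.frame(records)) records$bp_shift else records
  if (!length(x)) stop("no records")
  if (is.null(weights)) weights <- rep(1, length(x))
  ctr <- round(x / bin_width)
  lev <- seq(min(ctr), max(ctr))
  cnt <- vapply(lev, function(l) sum(weights[ctr == l]), 0)
  data.frame(bp = lev * bin_width, count = cnt, p = cnt / sum(cnt))
}

# shared binning helper: 1D or 2D weighted histogram
.bin_edges <- function(x, width) {
  lo <- floor(min(x) / width) * width - width / 2
  hi <- ceiling(max(x) / width) * width + width / 2
  seq(lo, hi, by = width)
}

#' Free-energy surface from sampled coordinates
#'
#' Histogram-based estimate F = -ln P in kBT over the sliding coordinate
#' and, optionally, the rotation coordinate; the minimum is shifted to
#' zero and empty bins are left masked (NA) rather than pseudocounted.
#'
#' @param records a \code{frame_records} data.frame.
#' @param coords which coordinates to bin: \code{"bp_shift"},
#'   \code{"eta"} or both (default \code{"bp_shift"}).
#' @param bin_bp bin width for the sliding coordinate, bp (default 0.25).
#' @param bin_eta bin width for the rotation coordinate, degrees
#'   (default 9).
#' @param weights optional per-record weights (used by
#'   \code{\link{reweight_surface}}).
#' @return a \code{free_energy_surface}: list with \code{edges} (list of
#'   bin-edge vectors), \code{mids}, \code{counts}, \code{F} (kBT, NA on
#'   empty bins), \code{ess} (effective sample size).
#' @export
free_energy_surface <- function(records, coords = "bp_shift",
                                bin_bp = 0.25, bin_eta = 9,
                                weights = NULL) {
  stopifnot(all(coords %in% c("bp_shift", "eta")))
  if (!nrow(records)) stop("no records")
  w <- if (is.null(weights)) rep(1, nrow(records)) else weights
  stopifnot(length(w) == nrow(records), all(w >= 0))
  vals <- lapply(coords, function(cn) records[[cn]])
  widths <- vapply(coords, function(cn)
    if (cn == "bp_shift") bin_bp else bin_eta, 0)
  edges <- Map(.bin_edges, vals, widths)
  idx <- Map(function(v, e) findInterval(v, e, rightmost.closed = TRUE),
             vals, edges)
  dims <- vapply(edges, function(e) length(e) - 1L, 0L)
  counts <- array(0, dim = dims)
  flat <- if (length(coords) == 1) idx[[1]]
  else (idx[[2]] - 1L) * dims[1] + idx[[1]]
  for (k in seq_along(flat)) counts[flat[k]] <- counts[flat[k]] + w[k]
  p <- counts / sum(counts)
  F <- -log(p)
  F[!is.finite(F)] <- NA
  F <- F - min(F, na.rm = TRUE)
  structure(list(edges = edges,
                 mids = lapply(edges, function(e) (e[-1] + e[-length(e)]) / 2),
                 coords = coords, counts = counts, F = F,
                 ess = sum(w)^2 / sum(w^2)),
            class = "free_energy_surface")
}

#' @export
print.free_energy_surface <- function(x, ...) {
  cat("free_energy_surface over", paste(x$coords, collapse = " x "),
      "(", paste(dim(as.array(x$counts)), collapse = " x "), "bins );",
      "ESS", format(x$ess, digits = 4), "\n")
  invisible(x)
}

#' Free-energy difference between two sliding states
#'
#' Convenience accessor: F at the bin containing \code{bp_b} minus F at
#' the bin containing \code{bp_a}, for a surface over the sliding
#' coordinate.
#'
#' @param fes a \code{free_energy_surface} over \code{bp_shift}.
#' @param bp_a,bp_b sliding-coordinate values (bp).
#' @return free-energy difference in kBT (NA if either bin is empty).
#' @export
fes_delta <- function(fes, bp_a, bp_b) {
  stopifnot(identical(fes$coords, "bp_shift"))
  e <- fes$edges[[1]]
  ia <- findInterval(bp_a, e, rightmost.closed = TRUE)
  ib <- findInterval(bp_b, e, rightmost.closed = TRUE)
  fes$F[ib] - fes$F[ia]
}

#' Reweight the free-energy surface to a different bond strength
#'
#' Uses the exact linearity of the hydrogen-bond potential in its energy
#' constant: a frame sampled at reference strength \code{eps_ref} with
#' bond energy \code{v_hb} carries weight
#' \eqn{w \propto \exp(-(\epsilon'/\epsilon - 1)\, V_{hb})} in the
#' ensemble at strength \code{eps_prime}. Only the bond term enters the
#' weight; all other interaction terms are strength-independent. The
#' effective sample size \eqn{(\sum w)^2 / \sum w^2} is reported on the
#' returned surface and shrinks as eps_prime moves away from eps_ref.
#'
#' @param records a \code{frame_records} data.frame with finite
#'   \code{v_hb}.
#' @param eps_prime target bond strength, kBT.
#' @param eps_ref reference bond strength the records were sampled at,
#'   kBT (default 1.2).
#' @param ... binning arguments passed to
#'   \code{\link{free_energy_surface}}.
#' @return a \code{free_energy_surface} at the target strength.
#' @export
reweight_surface <- function(records, eps_prime, eps_ref = 1.2, ...) {
  if (eps_ref == 0) stop("reference epsilon must be non-zero")
  if (any(!is.finite(records$v_hb)))
    stop("all records need a finite v_hb for reweighting")
  lw <- -(eps_prime / eps_ref - 1) * records$v_hb
  w <- exp(lw - max(lw))   # stabilized; normalization cancels in P
  free_energy_surface(records, weights = w, ...)
}
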