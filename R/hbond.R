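# Sliding-invariant coarse-grained histone-DNA hydrogen-bond potential.
#
# Each native bond i (a protein CA donor with reference geometry r0,
# theta0, phi0) is evaluated against *every* DNA phosphate j, so the
# potential is invariant under a rotation-coupled repositioning of the
# DNA: a phosphate bound to the protein is simply replaced by the next one
# in the same relative orientation. Specificity comes from the narrow
# distance and angle windows (sigma = 1 Angstrom, delta_phi = 10 degrees),
# which prevent neighbouring phosphates from being double-counted.

#' Hydrogen-bond distance factor
#'
#' Gaussian distance dependence \eqn{f(\Delta r) = \exp(-\Delta r^2/\sigma^2)}.
#'
#' @param dr deviation from the native distance, Angstrom.
#' @param sigma width, Angstrom (default 1).
#' @return value in (0, 1]; 1 at \code{dr = 0}.
#' @examples
#' f_dist(0)   # 1
#' f_dist(1)   # exp(-1)
#' @export
f_dist <- function(dr, sigma = 1) {
  stopifnot(sigma > 0)
  exp(-(dr / sigma)^2)
}

#' Hydrogen-bond angle factor
#'
#' Piecewise angular dependence: 1 inside the tolerance window
#' \code{|dphi| <= delta_phi}, a smooth cosine-squared shoulder
#' \eqn{1 - \cos^2(\pi \Delta\phi / (2\Delta_{tol}))} on
#' \code{(delta_phi, 2 delta_phi]}, and exactly 0 beyond twice the
#' tolerance (compact support). Continuous everywhere.
#'
#' @param dphi deviation from the native angle, degrees.
#' @param delta_phi tolerance window, degrees (default 10).
#' @return value in [0, 1].
#' @examples
#' g_ang(0)     # 1
#' g_ang(15)    # 0.5
#' g_ang(20)    # 0
#' @export
g_ang <- function(dphi, delta_phi = 10) {
  stopifnot(delta_phi > 0)
  a <- abs(dphi)
  out <- numeric(length(a))
  out[a <= delta_phi] <- 1
  mid <- a > delta_phi & a <= 2 * delta_phi
  out[mid] <- 1 - cos(pi * a[mid] / (2 * delta_phi))^2
  out
}

#' Construct a hydrogen-bond model
#'
#' @param bonds data.frame with one row per native bond: columns
#'   \code{donor_chain, donor_resid} (the HB-forming protein CA bead) and
#'   reference geometry \code{r0} (Angstrom), \code{theta0}, \code{phi0}
#'   (degrees).
#' @param epsilon bond strength in kBT (default 1.2; values in roughly
#'   1.2--2.4 kBT keep a nucleosome stable at low salt yet allow
#'   disassembly at high salt).
#' @param sigma distance width in Angstrom (default 1).
#' @param delta_phi angular tolerance in degrees (default 10).
#' @return an object of class \code{hbond_model}.
#' @export
hbond_model <- function(bonds, epsilon = 1.2, sigma = 1, delta_phi = 10) {
  stopifnot(is.data.frame(bonds), epsilon >= 0, sigma > 0, delta_phi > 0)
  need <- c("donor_chain", "donor_resid", "r0", "theta0", "phi0")
  miss <- setdiff(need, names(bonds))
  if (length(miss)) stop("bond table lacks column(s): ",
                         paste(miss, collapse = ", "))
  if (any(bonds$r0 <= 0)) stop("r0 must be positive")
  if (any(bonds$theta0 < 0 | bonds$theta0 > 180 |
          bonds$phi0 < 0 | bonds$phi0 > 180))
    stop("native angles must lie in [0, 180] degrees")
  structure(list(bonds = bonds, epsilon = epsilon, sigma = sigma,
                 delta_phi = delta_phi),
            class = "hbond_model")
}

#' @export
print.hbond_model <- function(x, ...) {
  cat("hbond_model:", nrow(x$bonds), "native bonds; epsilon =", x$epsilon,
      "kBT, sigma =", x$sigma, "A, delta_phi =", x$delta_phi, "deg\n")
  invisible(x)
}

#' Read / write a hydrogen-bond list
#'
#' Tab-separated columns: donor_chain, donor_resid, r0, theta0, phi0.
#'
#' @param path file path.
#' @param model an \code{hbond_model} (for writing).
#' @param ... parameters passed to \code{\link{hbond_model}} when reading.
#' @return \code{read_hbond_model}: an \code{hbond_model};
#'   \code{write_hbond_model}: \code{path}, invisibly.
#' @export
read_hbond_model <- function(path, ...) {
  d <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  hbond_model(d, ...)
}

#' @rdname read_hbond_model
#' @export
write_hbond_model <- function(model, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# nucleoslide hbond list (epsilon=%g sigma=%g delta_phi=%g)",
                     model$epsilon, model$sigma, model$delta_phi), con)
  utils::write.table(model$bonds, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Geometry of a candidate hydrogen bond
#'
#' For donor CA bead i and phosphate j: \code{r} is the CA--P distance;
#' \code{theta} is the angle between the CA-to-phosphate vector and the
#' vector connecting the donor's two chain neighbours (residues i-1 and
#' i+1); \code{phi} is the angle at the phosphate between the donor CA and
#' the sugar bead of the phosphate's own nucleotide.
#'
#' @param frame a \code{cg_structure}.
#' @param donor_chain,donor_resid the donor CA bead.
#' @param p_chain,p_resid the phosphate's nucleotide.
#' @return list with elements \code{r} (Angstrom), \code{theta},
#'   \code{phi} (degrees).
#' @export
bond_geometry <- function(frame, donor_chain, donor_resid, p_chain, p_resid) {
  xyz <- coords(frame)
  i_d <- bead_row(frame, donor_chain, donor_resid, "CA")
  i_m <- bead_row(frame, donor_chain, donor_resid - 1, "CA")
  i_p <- bead_row(frame, donor_chain, donor_resid + 1, "CA")
  if (is.na(i_d)) stop("donor ", donor_chain, ":", donor_resid, " not found")
  if (is.na(i_m) || is.na(i_p))
    stop("donor ", donor_chain, ":", donor_resid,
         " lacks a chain neighbour; bond geometry undefined at termini")
  j_p <- bead_row(frame, p_chain, p_resid, "P")
  j_s <- bead_row(frame, p_chain, p_resid, "S")
  if (is.na(j_p)) stop("phosphate ", p_chain, ":", p_resid, " not found")
  if (is.na(j_s)) stop("nucleotide ", p_chain, ":", p_resid, " has no sugar bead")
  ca <- xyz[i_d, ]; p <- xyz[j_p, ]; s <- xyz[j_s, ]
  v_cp <- p - ca
  v_nn <- xyz[i_p, ] - xyz[i_m, ]
  list(r = sqrt(sum(v_cp^2)),
       theta = .vec_angle(v_cp, v_nn),
       phi = .vec_angle(ca - p, s - p))
}

#' Extract native hydrogen-bond parameters from reference structures
#'
#' Measures the bond geometry of each listed donor/phosphate pair in each
#' reference structure and averages the available copies (e.g. two crystal
#' structures and the two symmetric halves of the nucleosome). Pairs may be
#' grouped via a \code{group} column so symmetry-related copies share one
#' averaged parameter set; by default each donor is its own group. Donors
#' on flexible tails are rejected: the geometric bond evaluation assumes a
#' stable near-native protein conformation.
#'
#' @param refs a \code{cg_structure} or list of them.
#' @param hb_pairs data.frame with columns \code{donor_chain, donor_resid,
#'   p_chain, p_resid} and optionally \code{group}; defaults to the pair
#'   table carried by the first reference.
#' @param epsilon,sigma,delta_phi model parameters
#'   (see \code{\link{hbond_model}}).
#' @return an \code{hbond_model} with one bond per listed donor, native
#'   geometry averaged over all available copies.
#' @export
extract_hbond_model <- function(refs, hb_pairs = NULL, epsilon = 1.2,
                                sigma = 1, delta_phi = 10) {
  if (inherits(refs, "cg_structure")) refs <- list(refs)
  if (is.null(hb_pairs)) hb_pairs <- refs[[1]]$hb_pairs
  if (is.null(hb_pairs)) stop("no hydrogen-bond pair list supplied")
  if (is.null(hb_pairs$group))
    hb_pairs$group <- paste(hb_pairs$donor_chain, hb_pairs$donor_resid)
  # reject tail donors
  for (s in refs) {
    b <- s$beads
    for (k in seq_len(nrow(hb_pairs))) {
      row <- bead_row(s, hb_pairs$donor_chain[k], hb_pairs$donor_resid[k], "CA")
      if (!is.na(row) && isTRUE(b$tail[row]))
        stop("donor ", hb_pairs$donor_chain[k], ":", hb_pairs$donor_resid[k],
             " is on a flexible tail; tails are excluded from the bond list")
    }
  }
  geo <- do.call(rbind, lapply(refs, function(s) {
    do.call(rbind, lapply(seq_len(nrow(hb_pairs)), function(k) {
      g <- tryCatch(bond_geometry(s, hb_pairs$donor_chain[k],
                                  hb_pairs$donor_resid[k],
                                  hb_pairs$p_chain[k], hb_pairs$p_resid[k]),
                    error = function(e) NULL)
      if (is.null(g)) return(NULL)
      data.frame(k = k, r = g$r, theta = g$theta, phi = g$phi)
    }))
  }))
  if (is.null(geo) || !nrow(geo))
    stop("none of the listed bonds could be measured in the references")
  geo$group <- hb_pairs$group[geo$k]
  gm <- stats::aggregate(geo[, c("r", "theta", "phi")],
                         by = list(group = geo$group), FUN = mean)
  measured <- unique(geo$k)
  bonds <- data.frame(
    donor_chain = hb_pairs$donor_chain[measured],
    donor_resid = hb_pairs$donor_resid[measured],
    r0 = gm$r[match(hb_pairs$group[measured], gm$group)],
    theta0 = gm$theta[match(hb_pairs$group[measured], gm$group)],
    phi0 = gm$phi[match(hb_pairs$group[measured], gm$group)])
  hbond_model(bonds, epsilon = epsilon, sigma = sigma, delta_phi = delta_phi)
}

#' Hydrogen-bond energy of a frame
#'
#' Evaluates the sliding-invariant bond potential: for each native bond i,
#' the occupancy \eqn{\sum_j f(r_{ij}-r_{i,0})\, g(\theta_{ij}-\theta_{i,0})
#' \, g(\phi_{ij}-\phi_{i,0})} summed over all DNA phosphates j of both
#' strands; the total energy is \eqn{-\epsilon \sum_i occupancy_i}, so a
#' perfectly formed bond contributes \eqn{-\epsilon} (attractive sign
#' convention; the raw positive occupancies are also returned). Phosphates
#' farther than \code{r0 + 6 sigma} from the donor contribute less than
#' 1e-15 and are skipped.
#'
#' @param frame a \code{cg_structure}.
#' @param model an \code{hbond_model}.
#' @return list with \code{energy} (kBT) and \code{occupancy} (numeric
#'   vector, one entry per native bond).
#' @export
hb_energy <- function(frame, model) {
  stopifnot(inherits(model, "hbond_model"))
  xyz <- coords(frame)
  b <- frame$beads
  p_rows <- frame$phosphate_rows
  if (!length(p_rows)) stop("frame contains no phosphate beads")
  # sugar bead of each phosphate's nucleotide
  s_rows <- vapply(p_rows, function(i)
    bead_row(frame, b$chain[i], b$resid[i], "S"), 0L)
  keep <- !is.na(s_rows)
  p_rows <- p_rows[keep]; s_rows <- s_rows[keep]
  P <- xyz[p_rows, , drop = FALSE]
  S <- xyz[s_rows, , drop = FALSE]

  occ <- numeric(nrow(model$bonds))
  for (i in seq_len(nrow(model$bonds))) {
    bd <- model$bonds[i, ]
    i_d <- bead_row(frame, bd$donor_chain, bd$donor_resid, "CA")
    i_m <- bead_row(frame, bd$donor_chain, bd$donor_resid - 1, "CA")
    i_p <- bead_row(frame, bd$donor_chain, bd$donor_resid + 1, "CA")
    if (is.na(i_d) || is.na(i_m) || is.na(i_p))
      stop("donor ", bd$donor_chain, ":", bd$donor_resid,
           " (or a chain neighbour) missing from the frame")
    ca <- xyz[i_d, ]
    v_nn <- xyz[i_p, ] - xyz[i_m, ]
    d <- sweep(P, 2, ca)                       # CA -> P vectors
    r <- sqrt(rowSums(d^2))
    near <- which(abs(r - bd$r0) <= 6 * model$sigma)
    if (!length(near)) next
    dn <- d[near, , drop = FALSE]
    rn <- r[near]
    cth <- (dn %*% v_nn) / (rn * sqrt(sum(v_nn^2)))
    theta <- .deg(acos(pmax(-1, pmin(1, cth))))
    v_pc <- -dn                                 # P -> CA
    v_ps <- S[near, , drop = FALSE] - P[near, , drop = FALSE]
    cph <- rowSums(v_pc * v_ps) / (rn * sqrt(rowSums(v_ps^2)))
    phi <- .deg(acos(pmax(-1, pmin(1, cph))))
    occ[i] <- sum(f_dist(rn - bd$r0, model$sigma) *
                    g_ang(theta - bd$theta0, model$delta_phi) *
                    g_ang(phi - bd$phi0, model$delta_phi))
  }
  list(energy = -model$epsilon * sum(occ), occupancy = occ)
}
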