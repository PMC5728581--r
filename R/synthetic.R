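# Synthetic fixtures: idealized superhelical nucleosomes and kinematic
# sliding trajectories with known ground truth.
#
# The fixture is not a physical simulator. DNA beads are placed on an
# analytic left-handed superhelical path; pseudo-histone hydrogen-bond
# donor sites sit at every half-integer superhelical location (SHL), where
# the minor groove faces the core. Trajectories are generated by moving the
# sequence register along the path (screw), rigidly shifting it without
# rotation (jump), or propagating a bulge defect (loop), so every analysis
# coordinate has a closed-form ground truth.

#' Specification of the ideal superhelix fixture
#'
#' Geometric parameters of the idealized nucleosome. The DNA twist defaults
#' to exactly 10.0 bp/turn (rather than the physical ~10.17) so that
#' rotation-coupling tests have a closed-form 36 deg/bp slope; radius and
#' pitch default to canonical nucleosome values.
#'
#' @param n_wrapped_bp wrapped base pairs (default 147; must be odd so the
#'   dyad falls on a base pair).
#' @param radius superhelix radius in Angstrom (default 41.9).
#' @param pitch superhelix pitch in Angstrom per superhelical turn
#'   (default 25.9).
#' @param dna_twist DNA helical twist in bp per turn (default 10.0).
#' @param dna_radius phosphate radial distance from the DNA axis in
#'   Angstrom (default 9.4).
#' @param linker_bp linker length per side in bp (default 38).
#' @param rise arc length per bp along the path in Angstrom (default 3.4).
#' @param strand_sep azimuthal separation of the two strands' phosphates
#'   across the minor groove, degrees (default 120).
#' @param hb_length native donor-phosphate hydrogen-bond distance in
#'   Angstrom (default 5.0).
#' @return a \code{superhelix_spec} list.
#' @export
superhelix_spec <- function(n_wrapped_bp = 147, radius = 41.9, pitch = 25.9,
                            dna_twist = 10.0, dna_radius = 9.4,
                            linker_bp = 38, rise = 3.4, strand_sep = 120,
                            hb_length = 5.0) {
  stopifnot(n_wrapped_bp > 0, radius > 0, pitch > 0, dna_twist > 0,
            dna_radius > 0, linker_bp >= 0, rise > 0, hb_length > 0)
  if (n_wrapped_bp %% 2 == 0)
    stop("n_wrapped_bp must be odd so that the dyad falls on a base pair")
  L_turn <- sqrt((2 * pi * radius)^2 + pitch^2)
  turns <- n_wrapped_bp * rise / L_turn
  half_wrap <- (n_wrapped_bp - 1) / 2
  # donor sites at all half-integer SHLs fully inside the wrap
  max_shl <- floor((half_wrap / dna_twist) - 0.5) + 0.5
  shls <- seq(0.5, max_shl, by = 1)
  shls <- sort(c(-shls, shls))
  structure(list(n_wrapped_bp = as.integer(n_wrapped_bp), radius = radius,
                 pitch = pitch, dna_twist = dna_twist,
                 dna_radius = dna_radius, linker_bp = as.integer(linker_bp),
                 rise = rise, strand_sep = strand_sep, hb_length = hb_length,
                 L_turn = L_turn, turns = turns, shls = shls),
            class = "superhelix_spec")
}

# Path frame at slot coordinate s (bp from the dyad along the path).
# Returns origin point and orthonormal frame (t toward increasing s,
# u toward the superhelix axis, v = t x u). Vectorized over s.
.path_frame <- function(spec, s) {
  s <- as.numeric(s)
  half_wrap <- (spec$n_wrapped_bp - 1) / 2
  omega <- 2 * pi * spec$rise / spec$L_turn    # azimuth advance per bp (rad)
  sc <- pmin(pmax(s, -half_wrap), half_wrap)   # clamp: linkers extend straight
  phi <- omega * sc
  cx <- spec$radius * cos(phi)
  cy <- spec$radius * sin(phi)
  cz <- -spec$pitch * phi / (2 * pi)
  # tangent of the superhelix (unnormalized): d/dphi
  tx <- -spec$radius * sin(phi)
  ty <- spec$radius * cos(phi)
  tz <- rep(-spec$pitch / (2 * pi), length(phi))
  tn <- sqrt(tx^2 + ty^2 + tz^2)
  tx <- tx / tn; ty <- ty / tn; tz <- tz / tn
  # linker: straight continuation along the end tangent
  ext <- (s - sc) * spec$rise
  cx <- cx + ext * tx; cy <- cy + ext * ty; cz <- cz + ext * tz
  # u: toward the superhelix axis, orthogonalized against t
  ux <- -cos(phi); uy <- -sin(phi); uz <- rep(0, length(phi))
  dot <- ux * tx + uy * ty + uz * tz
  ux <- ux - dot * tx; uy <- uy - dot * ty; uz <- uz - dot * tz
  un <- sqrt(ux^2 + uy^2 + uz^2)
  ux <- ux / un; uy <- uy / un; uz <- uz / un
  vx <- ty * uz - tz * uy
  vy <- tz * ux - tx * uz
  vz <- tx * uy - ty * ux
  list(c = cbind(cx, cy, cz), t = cbind(tx, ty, tz),
       u = cbind(ux, uy, uz), v = cbind(vx, vy, vz))
}

# point at angle alpha (deg) and radius r around the local DNA axis at slot s
.around_axis <- function(fr, i, r, alpha) {
  a <- .rad(alpha)
  fr$c[i, ] + r * (cos(a) * fr$u[i, ] + sin(a) * fr$v[i, ])
}

# Azimuthal phase (deg) of the strand-1 / strand-2 phosphate at slot s.
# Phases are tied to the slot, so a register advance (screw motion)
# reproduces identical geometry around the histone sites; phase0 rotates
# the whole DNA rigidly about its own axis (used by jump trajectories).
.phase1 <- function(spec, s, phase0 = 0) {
  180 - spec$strand_sep / 2 + 360 / spec$dna_twist * s + phase0
}
.phase2 <- function(spec, s, phase0 = 0) {
  180 + spec$strand_sep / 2 + 360 / spec$dna_twist * s + phase0
}

# offsets of sugar and base beads relative to the phosphate phase;
# strand 2 mirrors strand 1 so the construction is exactly C2-symmetric
.SUGAR_DA <- -25; .BASE_DA <- -55
.SUGAR_R <- 7.4; .BASE_R <- 2.5

# DNA coordinates for all nucleotides, in topology bead order.
# shift: register advance in bp (screw); phase0: rigid DNA rotation (deg);
# bulge: optional function(slot) -> radial outward displacement (Angstrom).
.dna_coords <- function(spec, shift = 0, phase0 = 0, bulge = NULL) {
  n_total <- spec$n_wrapped_bp + 2 * spec$linker_bp
  dyad <- spec$linker_bp + (spec$n_wrapped_bp - 1) / 2
  bp <- 0:(n_total - 1)
  slot <- bp - dyad + shift
  fr <- .path_frame(spec, slot)
  if (!is.null(bulge)) {
    # displace the local DNA axis radially away from the superhelix axis
    d <- bulge(slot)
    fr$c <- fr$c - d * fr$u
  }
  place <- function(r, alpha) {
    a <- .rad(alpha)
    fr$c + r * (cos(a) * fr$u + sin(a) * fr$v)
  }
  a1 <- .phase1(spec, slot, phase0)
  a2 <- .phase2(spec, slot, phase0)
  p1 <- place(spec$dna_radius, a1)
  s1 <- place(.SUGAR_R, a1 + .SUGAR_DA)
  b1 <- place(.BASE_R, a1 + .BASE_DA)
  p2 <- place(spec$dna_radius, a2)
  s2 <- place(.SUGAR_R, a2 - .SUGAR_DA)
  b2 <- place(.BASE_R, a2 - .BASE_DA)
  # strand 1 runs bp 0..N-1 (5'->3'), strand 2 antiparallel bp N-1..0;
  # 5'-terminal nucleotides carry no phosphate bead
  rows1 <- lapply(bp, function(b) {
    i <- b + 1
    m <- rbind(if (b > 0) p1[i, ], s1[i, ], b1[i, ])
    m
  })
  rows2 <- lapply(rev(bp), function(b) {
    i <- b + 1
    m <- rbind(if (b < n_total - 1) p2[i, ], s2[i, ], b2[i, ])
    m
  })
  do.call(rbind, c(rows1, rows2))
}

# Histone pseudo-site coordinates (static across trajectories).
# Each half-integer SHL carries two donor triplets, one facing each
# strand's phosphate; triplet = donor CA flanked by two chain neighbors.
.histone_coords <- function(spec) {
  dyad_slot <- spec$shls * spec$dna_twist
  fr <- .path_frame(spec, dyad_slot)
  r_d <- spec$dna_radius + spec$hb_length
  out <- list()
  for (i in seq_along(dyad_slot)) {
    s <- dyad_slot[i]
    for (side in 1:2) {
      alpha <- if (side == 1) .phase1(spec, s) else .phase2(spec, s)
      d <- .around_axis(fr, i, r_d, alpha)
      # flanking neighbors 3.8 A along the local v direction
      nb <- 3.8 * fr$v[i, ]
      out[[length(out) + 1]] <- rbind(d - nb, d, d + nb)
    }
  }
  do.call(rbind, out)
}

#' Build an idealized superhelical nucleosome
#'
#' Places DNA phosphate/sugar/base beads on an analytic left-handed
#' superhelical path with the specified twist, and pseudo-histone CA
#' triplets at every half-integer SHL (two per site, one facing each
#' strand's phosphate). Each donor defines one native hydrogen bond whose
#' reference geometry follows from the construction. The structure is
#' exactly C2-symmetric about the dyad axis, and the symmetric donor pairs
#' are recorded for the symmetry-axis fit.
#'
#' @param spec a \code{superhelix_spec}.
#' @return a \code{cg_structure}; the spec, register shift and donor table
#'   are carried in attributes \code{"spec"}, \code{"shift"} and in
#'   \code{$hb_pairs}.
#' @export
build_ideal_nucleosome <- function(spec = superhelix_spec()) {
  stopifnot(inherits(spec, "superhelix_spec"))
  n_total <- spec$n_wrapped_bp + 2 * spec$linker_bp
  dyad <- spec$linker_bp + (spec$n_wrapped_bp - 1) / 2
  n_sites <- length(spec$shls)

  # protein chain H: 2 triplets per site, residues consecutive
  hx <- .histone_coords(spec)
  n_prot <- nrow(hx)
  prot <- data.frame(chain = "H", resid = seq_len(n_prot), kind = "CA",
                     x = hx[, 1], y = hx[, 2], z = hx[, 3],
                     charge = 0, radius = DEFAULT_RADII[["CA"]], tail = FALSE)
  donor_resid <- seq(2, n_prot, by = 3)         # middle bead of each triplet
  prot$charge[donor_resid] <- 1                  # arginine/lysine-like donors

  dxyz <- .dna_coords(spec)
  dna_rows <- function(chain, bps, five_prime_bp) {
    do.call(rbind, lapply(bps, function(b) {
      kinds <- c(if (b != five_prime_bp) "P", "S", "B")
      data.frame(chain = chain, resid = b + 1L, kind = kinds,
                 x = 0, y = 0, z = 0,
                 charge = ifelse(kinds == "P", -1, 0),
                 radius = unname(DEFAULT_RADII[kinds]), tail = FALSE)
    }))
  }
  dna1 <- dna_rows("I", 0:(n_total - 1), 0)
  dna2 <- dna_rows("J", (n_total - 1):0, n_total - 1)
  beads <- rbind(prot, dna1, dna2)
  beads[beads$kind != "CA", c("x", "y", "z")] <- dxyz

  # native bond list: donor k at site i (slot s) faces its strand's
  # phosphate at that slot
  slot <- rep(spec$shls * spec$dna_twist, each = 2)
  side <- rep(1:2, n_sites)
  bp_at_slot <- slot + dyad
  hb_pairs <- data.frame(
    donor_chain = "H", donor_resid = donor_resid,
    p_chain = ifelse(side == 1, "I", "J"),
    p_resid = bp_at_slot + 1L)

  # C2 pairs: site at SHL +h / side 1 maps to SHL -h / side 2, and the
  # flanking neighbors swap; list all bead pairs of each donor triplet
  site_of <- function(shl, sd) 2 * (match(shl, spec$shls) - 1) + sd
  pairs <- list()
  for (i in seq_len(n_sites)) {
    h <- spec$shls[i]
    if (h < 0) next
    for (sd in 1:2) {
      a0 <- 3 * (site_of(h, sd) - 1)        # bead offset of this triplet
      b0 <- 3 * (site_of(-h, 3 - sd) - 1)   # its C2 image triplet
      pairs[[length(pairs) + 1]] <- data.frame(
        chain_a = "H", resid_a = a0 + c(1, 2, 3),
        chain_b = "H", resid_b = b0 + c(3, 2, 1))
    }
  }
  out <- cg_structure(beads, strand1 = "I", strand2 = "J",
                      symmetric_pairs = do.call(rbind, pairs),
                      hb_pairs = hb_pairs)
  attr(out, "spec") <- spec
  attr(out, "shift") <- 0
  attr(out, "phase0") <- 0
  out
}

# regenerate DNA coordinates of an ideal-nucleosome structure
.regen_dna <- function(structure, shift, phase0 = 0, bulge = NULL) {
  spec <- attr(structure, "spec")
  if (is.null(spec)) stop("structure does not carry a superhelix spec")
  xyz <- coords(structure)
  xyz[structure$beads$kind != "CA", ] <- .dna_coords(spec, shift, phase0, bulge)
  coords(structure) <- xyz
  attr(structure, "shift") <- shift
  attr(structure, "phase0") <- phase0
  structure
}

#' Advance the DNA register by a screw (corkscrew) motion
#'
#' Re-places the DNA with its sequence register advanced by \code{n_bp}
#' along the unchanged spatial path: every phosphate previously bound to a
#' histone site is replaced by the next one in exactly the same geometry,
#' the signature of rotation-coupled sliding. The tracked base pair's
#' rotational phase advances by 360/twist degrees per bp.
#'
#' @param structure a structure built by \code{\link{build_ideal_nucleosome}}.
#' @param n_bp signed register advance in bp.
#' @return the structure with regenerated DNA coordinates.
#' @export
advance_screw <- function(structure, n_bp) {
  spec <- attr(structure, "spec")
  if (is.null(spec)) stop("structure does not carry a superhelix spec")
  shift <- attr(structure, "shift") + n_bp
  if (abs(shift) > spec$linker_bp)
    stop("register advance ", shift, " bp exhausts the ", spec$linker_bp,
         "-bp linker reserve")
  .regen_dna(structure, shift, attr(structure, "phase0"))
}

#' Specification of a synthetic sliding trajectory
#'
#' @param mode one of \code{"screw"} (rotation-coupled 1-bp steps),
#'   \code{"jump"} (rotation-uncoupled rigid shifts, default 5 bp),
#'   \code{"loop"} (a bulge defect nucleating at one end and propagating
#'   SHL by SHL), \code{"static"}.
#' @param step_bp step size per event in bp (default 1 for screw, 5 for
#'   jump and loop).
#' @param n_frames number of frames.
#' @param noise_sd isotropic Gaussian positional noise per bead per frame,
#'   Angstrom (default 0).
#' @param seed RNG seed for reproducible step directions and noise.
#' @param sweep optional length-2 numeric: instead of a random walk, ramp
#'   the register deterministically from \code{sweep[1]} to \code{sweep[2]}
#'   bp across the frames.
#' @param range_bp reflecting boundary of the random walk, bp. Jump walks
#'   default to 10 bp (the five-state -10..+10 landscape of a strong
#'   positioning sequence); screw walks default to the linker reserve.
#' @param loop_bp extra base pairs stored in the loop defect (default 10).
#' @param bulge_amp radial amplitude of the loop bulge, Angstrom
#'   (default 4).
#' @return a \code{trajectory_spec} list.
#' @export
trajectory_spec <- function(mode = c("screw", "jump", "loop", "static"),
                            step_bp = NULL, n_frames = 100, noise_sd = 0,
                            seed = 1, sweep = NULL, range_bp = NULL,
                            loop_bp = 10, bulge_amp = 4) {
  mode <- match.arg(mode)
  if (is.null(step_bp)) step_bp <- switch(mode, screw = 1, jump = 5,
                                          loop = 5, static = 0)
  if (is.null(range_bp) && mode == "jump") range_bp <- 10
  stopifnot(n_frames >= 1, noise_sd >= 0)
  structure(list(mode = mode, step_bp = step_bp, n_frames = n_frames,
                 noise_sd = noise_sd, seed = seed, sweep = sweep,
                 range_bp = range_bp, loop_bp = loop_bp,
                 bulge_amp = bulge_amp),
            class = "trajectory_spec")
}

#' Generate a synthetic sliding trajectory
#'
#' Screw mode advances the register by \code{step_bp} (random sign, or a
#' deterministic ramp if \code{sweep} is given) per frame, with the DNA
#' rotational phase coupled to the advance (36 deg/bp at 10 bp/turn). Jump
#' mode shifts the register while counter-rotating the DNA so its phase at
#' any fixed base pair stays constant: sliding without rotation. Loop mode
#' propagates a bulge of \code{loop_bp} extra base pairs from the positive-
#' SHL end across the wrap, shifting the register behind the moving front.
#'
#' @param structure a structure from \code{\link{build_ideal_nucleosome}}.
#' @param spec a \code{\link{trajectory_spec}}.
#' @return a \code{cg_trajectory}; element \code{truth} is a data.frame of
#'   per-frame ground truth (\code{frame, shift_bp, phase0_deg}).
#' @export
make_trajectory <- function(structure, spec = trajectory_spec()) {
  stopifnot(inherits(spec, "trajectory_spec"))
  sh_spec <- attr(structure, "spec")
  if (is.null(sh_spec)) stop("structure does not carry a superhelix spec")
  set.seed(spec$seed)
  n <- spec$n_frames
  tau <- 360 / sh_spec$dna_twist

  if (spec$mode %in% c("screw", "jump")) {
    if (!is.null(spec$sweep)) {
      shifts <- round(seq(spec$sweep[1], spec$sweep[2], length.out = n))
    } else if (spec$mode == "static" || spec$step_bp == 0) {
      shifts <- rep(0, n)
    } else {
      steps <- sample(c(-1, 1), n - 1, replace = TRUE) * spec$step_bp
      lim <- min(spec$range_bp %||% Inf, sh_spec$linker_bp - spec$step_bp)
      shifts <- Reduce(function(s, d) {
        if (abs(s + d) > lim) s - d else s + d   # reflecting boundary
      }, steps, init = 0, accumulate = TRUE)
    }
    phase0 <- if (spec$mode == "jump") -tau * shifts else rep(0, n)
    frames <- lapply(seq_len(n), function(i)
      coords(.regen_dna(structure, shifts[i], phase0[i])))
  } else if (spec$mode == "static") {
    shifts <- rep(0, n); phase0 <- rep(0, n)
    frames <- lapply(seq_len(n), function(i) coords(structure))
  } else { # loop: bulge front moves from the +SHL end toward the -SHL end
    half_wrap <- (sh_spec$n_wrapped_bp - 1) / 2
    fronts <- seq(half_wrap, -half_wrap, length.out = n)
    shifts <- numeric(n); phase0 <- rep(0, n)
    frames <- vector("list", n)
    for (i in seq_len(n)) {
      p <- fronts[i]
      bulge <- local({
        p0 <- p
        amp <- spec$bulge_amp
        function(slot) amp * exp(-((slot - p0) / 5)^2)
      })
      # base pairs behind the front (already passed by the loop) are
      # shifted by loop_bp; implemented as a per-bp register offset
      frames[[i]] <- .loop_frame(structure, sh_spec, p, spec$loop_bp, bulge)
      shifts[i] <- NA   # register is position-dependent during propagation
    }
  }

  if (spec$noise_sd > 0) {
    frames <- lapply(frames, function(f)
      f + matrix(stats::rnorm(length(f), 0, spec$noise_sd), ncol = 3))
  }
  traj <- cg_trajectory(structure, frames)
  traj$truth <- data.frame(frame = seq_len(n), shift_bp = shifts,
                           phase0_deg = phase0)
  traj
}

# Loop-defect frame: base pairs on the nucleation side of the front carry
# an extra register advance of loop_bp (stored in the bulge); the advance
# blends across the bulge window so the strand stays continuous.
.loop_frame <- function(structure, sh_spec, front, loop_bp, bulge) {
  n_total <- sh_spec$n_wrapped_bp + 2 * sh_spec$linker_bp
  dyad <- sh_spec$linker_bp + (sh_spec$n_wrapped_bp - 1) / 2
  bp <- 0:(n_total - 1)
  slot0 <- bp - dyad
  # smooth step from 0 (ahead of the front) to loop_bp (behind it)
  adv <- loop_bp / (1 + exp(-(slot0 - front) / 2))
  slot <- slot0 + adv
  fr <- .path_frame(sh_spec, slot)
  fr$c <- fr$c - bulge(slot0) * fr$u
  place <- function(r, alpha) {
    a <- .rad(alpha)
    fr$c + r * (cos(a) * fr$u + sin(a) * fr$v)
  }
  a1 <- .phase1(sh_spec, slot)
  a2 <- .phase2(sh_spec, slot)
  xyz <- coords(structure)
  p1 <- place(sh_spec$dna_radius, a1); s1 <- place(.SUGAR_R, a1 + .SUGAR_DA)
  b1 <- place(.BASE_R, a1 + .BASE_DA)
  p2 <- place(sh_spec$dna_radius, a2); s2 <- place(.SUGAR_R, a2 - .SUGAR_DA)
  b2 <- place(.BASE_R, a2 - .BASE_DA)
  rows1 <- do.call(rbind, lapply(bp, function(b) {
    i <- b + 1
    rbind(if (b > 0) p1[i, ], s1[i, ], b1[i, ])
  }))
  rows2 <- do.call(rbind, lapply(rev(bp), function(b) {
    i <- b + 1
    rbind(if (b < n_total - 1) p2[i, ], s2[i, ], b2[i, ])
  }))
  xyz[structure$beads$kind != "CA", ] <- rbind(rows1, rows2)
  xyz
}

## ------------------------------------------------------ sequence library

# The four nucleosomal sequences over the +-4 SHL region around the dyad
# (strand 1). The 601 and polyCG-601 rows are fixed reference sequences;
# polyCG and polyAA are uniform and can be generated to any length.
SEQ_601_CENTRAL <- paste0(
  "TCGTAGACAGCTCTAGCACCGCTTAAACGCACGTACGCGCTGTCCCCCGCG",
  "TTTTAACCGCCAAGGGGATTACTCCCTAGT")
SEQ_POLYCG601_CENTRAL <- paste0(
  "CGCGCGCGCGCGCGCGCGCGCGTTAAAGCGCGCGCGCGCGCGCGCGCGCGCG",
  "TTTAAGCGCGCGCGCGCGCGCGCGCGCGC")

#' Generate a polyCG or polyAA sequence
#'
#' @param n length in bp.
#' @return character sequence of length \code{n}; polyCG alternates C/G
#'   starting on C.
#' @export
poly_cg <- function(n) substr(strrep("CG", ceiling(n / 2)), 1, n)

#' @rdname poly_cg
#' @export
poly_aa <- function(n) strrep("A", n)

#' The four nucleosomal DNA sequence constructs
#'
#' Returns the library of sequences used to probe sequence-dependent
#' sliding: the central region (about +-4 SHL around the dyad) of the
#' Widom 601 strong positioning sequence; polyCG and polyAA uniform
#' sequences; and polyCG-601, a polyCG background carrying the two
#' TTAAA/TTTAA positioning motifs at the same offsets as in 601. Only the
#' central 601 region is shipped; a full 145-bp 601 core can be supplied by
#' the user via \code{\link{sequence_construct}}.
#'
#' @param length optional length in bp for the uniform sequences (polyCG,
#'   polyAA); defaults to the length of the shipped central regions.
#' @return named list of \code{sequence_construct} objects.
#' @export
make_sequences <- function(length = NULL) {
  n0 <- nchar(SEQ_601_CENTRAL)
  n <- if (is.null(length)) n0 else length
  list(
    `601` = sequence_construct("601", SEQ_601_CENTRAL),
    polyCG = sequence_construct("polyCG", poly_cg(n)),
    polyAA = sequence_construct("polyAA", poly_aa(n)),
    `polyCG-601` = sequence_construct("polyCG-601", SEQ_POLYCG601_CENTRAL))
}
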