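# Non-bonded histone-DNA interaction terms and the contact-count
# observable used for salt-titration (unwrapping) curves.

#' Non-bonded interaction parameters
#'
#' DNA-DNA electrostatics uses a reduced phosphate charge of -0.6e
#' (accounting for Oosawa-Manning counter-ion condensation), while
#' protein-DNA electrostatics uses the full -1e phosphate charge; the two
#' interaction classes are evaluated with separate charge values rather
#' than by mutating bead state. The solvent dielectric is either the
#' empirical temperature- and salt-dependent model used with
#' coarse-grained DNA forcefields, or a constant.
#'
#' @param ionic_strength monovalent salt concentration, mol/L.
#' @param temperature Kelvin.
#' @param dna_dna_phosphate_charge phosphate charge (e) for DNA-DNA pairs.
#' @param protein_dna_phosphate_charge phosphate charge (e) for
#'   protein-DNA pairs.
#' @param exv_epsilon excluded-volume energy scale, kBT (default 0.2
#'   kcal/mol converted; an approximation, user-adjustable).
#' @param radius_scale uniform scaling of bead radii in the excluded
#'   volume term (default 1.1).
#' @param permittivity \code{"empirical"} or a numeric constant (e.g. 78).
#' @return an \code{interaction_params} list.
#' @export
interaction_params <- function(ionic_strength = 0.2, temperature = 300,
                               dna_dna_phosphate_charge = -0.6,
                               protein_dna_phosphate_charge = -1.0,
                               exv_epsilon = kcal_to_kbt(0.2),
                               radius_scale = 1.1,
                               permittivity = "empirical") {
  if (ionic_strength <= 0) stop("ionic_strength must be positive (mol/L)")
  stopifnot(temperature > 0, radius_scale > 0, exv_epsilon >= 0)
  structure(list(ionic_strength = ionic_strength, temperature = temperature,
                 dna_dna_phosphate_charge = dna_dna_phosphate_charge,
                 protein_dna_phosphate_charge = protein_dna_phosphate_charge,
                 exv_epsilon = exv_epsilon, radius_scale = radius_scale,
                 permittivity = permittivity),
            class = "interaction_params")
}

#' Solvent relative permittivity
#'
#' The empirical model combines a quadratic temperature dependence with a
#' cubic salt-concentration correction, as used with coarse-grained DNA
#' forcefields; alternatively a constant value can be requested.
#'
#' @param params an \code{interaction_params}.
#' @return dimensionless relative permittivity.
#' @export
permittivity <- function(params) {
  if (is.numeric(params$permittivity)) return(params$permittivity)
  T <- params$temperature
  C <- params$ionic_strength
  eT <- 249.4 - 0.788 * T + 7.2e-4 * T^2
  aC <- 1.000 - 0.2551 * C + 5.151e-2 * C^2 - 6.889e-3 * C^3
  eT * aC
}

#' Bjerrum length in Angstrom
#' @param params an \code{interaction_params}.
#' @return Bjerrum length (Angstrom) at the params' temperature and
#'   dielectric.
#' @export
bjerrum_length <- function(params) {
  # e^2 / (4 pi eps0 eps_r kB T); 1.671e5 A at eps_r * T = 1
  167100.9 / (permittivity(params) * params$temperature)
}

#' Debye screening length in Angstrom
#' @param params an \code{interaction_params}.
#' @return Debye length (Angstrom).
#' @export
debye_length <- function(params) {
  # sqrt(eps0 eps_r kB T / (2 NA e^2 1000 I)); I in mol/L, result in A
  0.019883 * sqrt(permittivity(params) * params$temperature /
                    params$ionic_strength)
}

#' Excluded-volume energy between histone and DNA beads
#'
#' A purely repulsive r^-12 potential,
#' \eqn{\sum \epsilon_{ev} (\sigma_{ij}/r_{ij})^{12}} over protein-DNA bead
#' pairs, with \eqn{\sigma_{ij} = s\,(R_i + R_j)/2} from the per-bead radii
#' scaled by \code{radius_scale}. Pairs whose contribution falls below
#' 1e-12 kBT are skipped.
#'
#' @param frame a \code{cg_structure} with per-bead radii.
#' @param params an \code{interaction_params}.
#' @return energy in kBT.
#' @export
excluded_volume <- function(frame, params = interaction_params()) {
  xyz <- coords(frame)
  b <- frame$beads
  ip <- which(b$kind == "CA")
  id <- which(b$kind != "CA")
  if (!length(ip) || !length(id)) return(0)
  # distance beyond which even the largest pair is < 1e-12 kBT
  sig_max <- params$radius_scale * max(b$radius)
  r_max <- sig_max * (params$exv_epsilon / 1e-12)^(1 / 12)
  e <- 0
  for (i in ip) {
    d2 <- (xyz[id, 1] - xyz[i, 1])^2 + (xyz[id, 2] - xyz[i, 2])^2 +
      (xyz[id, 3] - xyz[i, 3])^2
    if (any(d2 == 0)) stop("coincident protein and DNA beads (singularity)")
    sig <- params$radius_scale * (b$radius[i] + b$radius[id]) / 2
    near <- d2 < r_max^2
    if (!any(near)) next
    e <- e + sum(params$exv_epsilon * (sig[near]^2 / d2[near])^6)
  }
  e
}

#' Debye-Hueckel electrostatic energy
#'
#' Screened Coulomb energy
#' \eqn{\sum_{i<j} l_B q_i q_j \exp(-r_{ij}/\lambda_D)/r_{ij}} in kBT, with
#' the Bjerrum length \eqn{l_B} and Debye length \eqn{\lambda_D} derived
#' from the ionic strength, temperature and permittivity model. Phosphate
#' charges are taken per interaction class: the protein-DNA class uses the
#' full charge, the DNA-DNA class the condensation-reduced one. Pairs
#' within the same molecule class (protein-protein) use bead-table charges.
#'
#' @param frame a \code{cg_structure} with bead charges.
#' @param params an \code{interaction_params}.
#' @param classes which interaction classes to include; any of
#'   \code{"protein-dna"}, \code{"dna-dna"}, \code{"protein-protein"}.
#' @return energy in kBT.
#' @export
debye_huckel <- function(frame, params = interaction_params(),
                         classes = c("protein-dna", "dna-dna")) {
  xyz <- coords(frame)
  b <- frame$beads
  lb <- bjerrum_length(params)
  ld <- debye_length(params)
  is_prot <- b$kind == "CA"
  pair_energy <- function(ii, jj, qi, qj, upper_tri) {
    if (!length(ii) || !length(jj)) return(0)
    e <- 0
    for (a in seq_along(ii)) {
      i <- ii[a]
      if (qi[a] == 0) next
      jsel <- if (upper_tri) jj[jj > i] else jj
      qsel <- if (upper_tri) qj[jj > i] else qj
      if (!length(jsel)) next
      r <- sqrt((xyz[jsel, 1] - xyz[i, 1])^2 + (xyz[jsel, 2] - xyz[i, 2])^2 +
                  (xyz[jsel, 3] - xyz[i, 3])^2)
      if (any(r == 0)) stop("coincident charged beads (singularity)")
      e <- e + sum(lb * qi[a] * qsel * exp(-r / ld) / r)
    }
    e
  }
  e <- 0
  if ("protein-dna" %in% classes) {
    ip <- which(is_prot)
    id <- which(!is_prot)
    qd <- ifelse(b$kind[id] == "P", params$protein_dna_phosphate_charge, 0)
    e <- e + pair_energy(ip, id, b$charge[ip], qd, upper_tri = FALSE)
  }
  if ("dna-dna" %in% classes) {
    id <- which(b$kind == "P")
    qd <- rep(params$dna_dna_phosphate_charge, length(id))
    e <- e + pair_energy(id, id, qd, qd, upper_tri = TRUE)
  }
  if ("protein-protein" %in% classes) {
    ip <- which(is_prot)
    e <- e + pair_energy(ip, ip, b$charge[ip], b$charge[ip], upper_tri = TRUE)
  }
  e
}

#' Count DNA phosphates in contact with the histone core
#'
#' A phosphate is in contact when its minimum distance to any non-tail
#' histone bead is at most \code{cutoff} (default 12 Angstrom, i.e.
#' 1.2 nm). Linker phosphates are counted like any others, so a wrapped
#' linker contributes contacts.
#'
#' @param frame a \code{cg_structure}.
#' @param cutoff contact distance, Angstrom.
#' @return integer contact count.
#' @export
count_contacts <- function(frame, cutoff = 12) {
  xyz <- coords(frame)
  core <- frame$core_rows
  if (!length(core)) stop("structure has no non-tail histone beads")
  ph <- frame$phosphate_rows
  if (!length(ph)) return(0L)
  P <- xyz[ph, , drop = FALSE]
  C <- xyz[core, , drop = FALSE]
  n <- 0L
  c2 <- cutoff^2
  for (k in seq_len(nrow(P))) {
    d2 <- (C[, 1] - P[k, 1])^2 + (C[, 2] - P[k, 2])^2 + (C[, 3] - P[k, 3])^2
    if (min(d2) <= c2) n <- n + 1L
  }
  n
}

#' Salt-titration curve of histone-DNA contacts
#'
#' Per salt condition, the mean and standard error over frames (after an
#' equilibration burn-in) of the phosphate contact count: the observable
#' whose sigmoidal drop with increasing ionic strength signals DNA
#' unwrapping from the core.
#'
#' @param trajectories named list of \code{cg_trajectory}, one per salt
#'   condition; names (or the \code{salt} argument) give the
#'   concentrations.
#' @param salt numeric vector of salt concentrations (mol/L); defaults to
#'   \code{as.numeric(names(trajectories))}.
#' @param cutoff contact distance, Angstrom.
#' @param burn_in_frames frames discarded from the start of each
#'   trajectory.
#' @return data.frame with columns \code{salt, mean_contacts, se, n_frames}
#'   (\code{se} is NA for single-frame conditions).
#' @export
titration_curve <- function(trajectories, salt = NULL, cutoff = 12,
                            burn_in_frames = 0) {
  if (!length(trajectories)) stop("empty trajectory ensemble")
  if (is.null(salt)) salt <- as.numeric(names(trajectories))
  stopifnot(length(salt) == length(trajectories))
  out <- lapply(seq_along(trajectories), function(k) {
    tr <- trajectories[[k]]
    idx <- seq_len(n_frames(tr))
    idx <- idx[idx > burn_in_frames]
    if (!length(idx)) stop("burn-in discards all frames of condition ", k)
    counts <- vapply(idx, function(i) count_contacts(frame_structure(tr, i),
                                                     cutoff), 0L)
    data.frame(salt = salt[k], mean_contacts = mean(counts),
               se = if (length(counts) > 1)
                 stats::sd(counts) / sqrt(length(counts)) else NA_real_,
               n_frames = length(counts))
  })
  do.call(rbind, out)
}
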