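# Domain types for coarse-grained nucleosome structures and trajectories.
#
# A cg_structure holds a bead table (one row per bead) plus derived indices:
# the base-pair maps of the two DNA strands, the histone-core bead set and
# the symmetric residue pairs used to define the nucleosome symmetry axis.

#' Construct a coarse-grained structure
#'
#' A coarse-grained nucleosome structure: protein chains carry one CA bead
#' per residue, DNA chains carry phosphate (P), sugar (S) and base (B) beads
#' per nucleotide. Base-pair indices are 0-based at the first base pair of
#' strand 1; strand 2 is assumed antiparallel with equal length.
#'
#' @param beads data.frame with columns \code{chain} (character),
#'   \code{resid} (integer, 1-based within chain), \code{kind} (one of
#'   CA/P/S/B), \code{x,y,z} (Angstrom), and optionally \code{charge}
#'   (elementary charges), \code{radius} (Angstrom) and \code{tail}
#'   (logical, protein flexible-tail flag).
#' @param strand1,strand2 chain identifiers of the two DNA strands. If
#'   \code{NULL}, DNA chains are taken in order of appearance.
#' @param symmetric_pairs data.frame with columns \code{chain_a, resid_a,
#'   chain_b, resid_b} pairing residues across the two copies of each
#'   histone. If \code{NULL}, no pairs are stored.
#' @param hb_pairs optional data.frame (\code{donor_chain, donor_resid,
#'   p_chain, p_resid}) naming native hydrogen-bond donor/phosphate pairs.
#' @return an object of class \code{cg_structure}.
#' @export
cg_structure <- function(beads, strand1 = NULL, strand2 = NULL,
                         symmetric_pairs = NULL, hb_pairs = NULL) {
  stopifnot(is.data.frame(beads))
  need <- c("chain", "resid", "kind", "x", "y", "z")
  missing_cols <- setdiff(need, names(beads))
  if (length(missing_cols))
    stop("bead table lacks column(s): ", paste(missing_cols, collapse = ", "))
  if (!all(beads$kind %in% BEAD_KINDS))
    stop("bead kind must be one of ", paste(BEAD_KINDS, collapse = "/"))
  if (is.null(beads$charge)) beads$charge <- 0
  if (is.null(beads$radius)) beads$radius <- unname(DEFAULT_RADII[beads$kind])
  if (is.null(beads$tail)) beads$tail <- FALSE
  beads$charge[is.na(beads$charge)] <- 0
  beads$radius[is.na(beads$radius)] <- unname(DEFAULT_RADII[beads$kind[is.na(beads$radius)]])
  beads$tail[is.na(beads$tail)] <- FALSE
  if (any(beads$radius <= 0)) stop("bead radii must be positive")
  beads$chain <- as.character(beads$chain)

  # chains must be pure protein (CA) or pure DNA (P/S/B)
  chain_kinds <- split(beads$kind, beads$chain)
  is_dna_chain <- vapply(chain_kinds, function(k) all(k %in% c("P", "S", "B")), TRUE)
  is_prot_chain <- vapply(chain_kinds, function(k) all(k == "CA"), TRUE)
  bad <- names(chain_kinds)[!(is_dna_chain | is_prot_chain)]
  if (length(bad))
    stop("chain(s) ", paste(bad, collapse = ","),
         " mix protein and DNA bead kinds (topology error)")
  dna_chains <- names(chain_kinds)[is_dna_chain][
    order(match(names(chain_kinds)[is_dna_chain], unique(beads$chain)))]
  if (is.null(strand1) && length(dna_chains) >= 1) strand1 <- dna_chains[1]
  if (is.null(strand2) && length(dna_chains) >= 2) strand2 <- dna_chains[2]

  x <- structure(list(beads = beads,
                      strand1 = strand1, strand2 = strand2,
                      symmetric_pairs = symmetric_pairs,
                      hb_pairs = hb_pairs),
                 class = "cg_structure")
  x <- .index_structure(x)
  x
}

# Precompute strand bp maps and frequently used row-index vectors.
.index_structure <- function(x) {
  b <- x$beads
  resid_order <- function(chain) {
    r <- unique(b$resid[b$chain == chain])
    r
  }
  x$n_bp <- 0L
  x$bp1 <- x$bp2 <- NULL
  if (!is.null(x$strand1)) {
    r1 <- resid_order(x$strand1)
    x$bp1 <- data.frame(bp = seq_along(r1) - 1L, resid = r1)
    x$n_bp <- length(r1)
  }
  if (!is.null(x$strand2)) {
    r2 <- resid_order(x$strand2)
    if (x$n_bp && length(r2) != x$n_bp)
      stop("strand1 and strand2 have different base-pair counts (",
           x$n_bp, " vs ", length(r2), ")")
    # antiparallel: bp i of strand1 pairs with strand2 residue n-i
    x$bp2 <- data.frame(bp = rev(seq_along(r2)) - 1L, resid = r2)
  }
  x$protein_rows <- which(b$kind == "CA")
  x$core_rows <- which(b$kind == "CA" & !b$tail)
  x$phosphate_rows <- which(b$kind == "P")
  x
}

#' @export
print.cg_structure <- function(x, ...) {
  cat("cg_structure:", nrow(x$beads), "beads;",
      length(unique(x$beads$chain)), "chains;",
      x$n_bp, "bp per DNA strand\n")
  invisible(x)
}

#' Bead coordinates of a structure
#'
#' @param x a \code{cg_structure}.
#' @return numeric matrix (n beads x 3).
#' @export
coords <- function(x) {
  as.matrix(x$beads[, c("x", "y", "z")])
}

#' Replace bead coordinates
#'
#' @param x a \code{cg_structure}.
#' @param value numeric matrix (n beads x 3).
#' @export
`coords<-` <- function(x, value) {
  stopifnot(nrow(value) == nrow(x$beads), ncol(value) == 3)
  x$beads$x <- value[, 1]; x$beads$y <- value[, 2]; x$beads$z <- value[, 3]
  x
}

# row index of a single bead, NA if absent
bead_row <- function(x, chain, resid, kind) {
  w <- which(x$beads$chain == chain & x$beads$resid == resid & x$beads$kind == kind)
  if (length(w) == 0) NA_integer_ else w[1]
}

#' Bead rows belonging to one base pair
#'
#' Returns the row indices (into the bead table) of all beads of both
#' strands' nucleotides at base-pair index \code{bp} (0-based).
#'
#' @param x a \code{cg_structure}.
#' @param bp base-pair index (0-based).
#' @return integer vector of row indices.
#' @export
bp_rows <- function(x, bp) {
  if (bp < 0 || bp >= x$n_bp) stop("base pair index ", bp, " outside 0..", x$n_bp - 1)
  r1 <- x$bp1$resid[x$bp1$bp == bp]
  r2 <- if (!is.null(x$bp2)) x$bp2$resid[x$bp2$bp == bp] else integer()
  c(which(x$beads$chain == x$strand1 & x$beads$resid == r1),
    if (length(r2)) which(x$beads$chain == x$strand2 & x$beads$resid == r2))
}

# strand-1 phosphate rows ordered by bp; data.frame(bp, row)
strand1_phosphates <- function(x) {
  b <- x$beads
  idx <- which(b$chain == x$strand1 & b$kind == "P")
  bp <- x$bp1$bp[match(b$resid[idx], x$bp1$resid)]
  o <- order(bp)
  data.frame(bp = bp[o], row = idx[o])
}

#' Geometric center of the histone core
#'
#' Center of geometry of all non-tail protein (CA) beads.
#' @param x a \code{cg_structure}.
#' @return length-3 numeric vector.
#' @export
core_centroid <- function(x) {
  if (!length(x$core_rows)) stop("structure has no non-tail protein beads")
  colMeans(coords(x)[x$core_rows, , drop = FALSE])
}

#' Construct a coarse-grained trajectory
#'
#' @param topology a \code{cg_structure} providing bead identities.
#' @param frames list of coordinate matrices (n beads x 3), one per frame.
#' @param frame_stride MD steps between saved frames (bookkeeping only).
#' @return an object of class \code{cg_trajectory}.
#' @export
cg_trajectory <- function(topology, frames, frame_stride = 1) {
  stopifnot(inherits(topology, "cg_structure"), is.list(frames),
            frame_stride > 0)
  nb <- nrow(topology$beads)
  ok <- vapply(frames, function(f) nrow(f) == nb && ncol(f) == 3, TRUE)
  if (!all(ok)) stop("all frames must be (n beads x 3) matrices matching the topology")
  structure(list(topology = topology, frames = frames,
                 frame_stride = frame_stride),
            class = "cg_trajectory")
}

#' @export
print.cg_trajectory <- function(x, ...) {
  cat("cg_trajectory:", length(x$frames), "frames x",
      nrow(x$topology$beads), "beads (stride", x$frame_stride, "MD steps)\n")
  invisible(x)
}

#' Number of frames in a trajectory
#' @param x a \code{cg_trajectory}.
#' @return integer frame count.
#' @export
n_frames <- function(x) length(x$frames)

#' Extract one frame of a trajectory as a structure
#'
#' @param traj a \code{cg_trajectory}.
#' @param i frame number (1-based).
#' @return a \code{cg_structure} with that frame's coordinates.
#' @export
frame_structure <- function(traj, i) {
  if (i < 1 || i > length(traj$frames)) stop("frame ", i, " out of range")
  s <- traj$topology
  coords(s) <- traj$frames[[i]]
  s
}

## ---------------------------------------------------------------- file I/O

# The bead-TSV dialect: tab-separated, '#'-prefixed comments, header
# chain resid kind x y z charge radius tail; '.' marks a missing value.

#' Read a coarse-grained structure or trajectory from file
#'
#' Supports two dialects: a documented bead-TSV table (columns chain, resid,
#' kind, x, y, z, charge, radius, tail; tab-separated; '.' for missing
#' values) and (multi-model) PDB, in which bead kinds are taken from atom
#' names CA/P/S/B. A PDB with several MODEL records yields a
#' \code{cg_trajectory}; otherwise a \code{cg_structure} is returned.
#'
#' @param path file path.
#' @param dialect one of \code{"auto"}, \code{"tsv"}, \code{"pdb"}.
#' @return a \code{cg_structure} or \code{cg_trajectory}.
#' @export
read_structure <- function(path, dialect = c("auto", "tsv", "pdb")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  if (dialect == "auto") {
    dialect <- if (grepl("\\.pdb$", path, ignore.case = TRUE)) "pdb" else "tsv"
  }
  if (dialect == "tsv") .read_bead_tsv(path) else .read_cg_pdb(path)
}

.read_bead_tsv <- function(path) {
  d <- tryCatch(
    utils::read.delim(path, comment.char = "#", na.strings = ".",
                      stringsAsFactors = FALSE),
    error = function(e) stop("cannot parse bead TSV ", path, ": ",
                             conditionMessage(e)))
  need <- c("chain", "resid", "kind", "x", "y", "z")
  miss <- setdiff(need, names(d))
  if (length(miss))
    stop("bead TSV ", path, " lacks column(s): ", paste(miss, collapse = ", "))
  bad <- which(!is.finite(d$x) | !is.finite(d$y) | !is.finite(d$z))
  if (length(bad))
    stop("malformed coordinate in ", path, " at data line ", bad[1])
  if (!is.null(d$tail)) d$tail <- as.logical(d$tail)
  cg_structure(d)
}

.read_cg_pdb <- function(path) {
  pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
  atoms <- pdb$atom
  kind <- atoms$elety
  if (!all(kind %in% BEAD_KINDS))
    stop("PDB ", path, " contains atom names other than CA/P/S/B; ",
         "use coarse_grain() for all-atom input")
  beads <- data.frame(chain = atoms$chain, resid = atoms$resno, kind = kind,
                      x = atoms$x, y = atoms$y, z = atoms$z,
                      stringsAsFactors = FALSE)
  topo <- cg_structure(beads)
  nf <- nrow(pdb$xyz)
  if (is.null(nf) || nf <= 1) return(topo)
  frames <- lapply(seq_len(nf), function(i)
    matrix(pdb$xyz[i, ], ncol = 3, byrow = TRUE))
  cg_trajectory(topo, frames)
}

#' Write a coarse-grained structure or trajectory to file
#'
#' The bead-TSV dialect round-trips all bead attributes; PDB stores
#' coordinates to 3 decimals with bead kinds as atom names and one
#' MODEL/ENDMDL block per frame for trajectories.
#'
#' @param x a \code{cg_structure} or \code{cg_trajectory}.
#' @param path output file path.
#' @param dialect one of \code{"auto"}, \code{"tsv"}, \code{"pdb"}.
#' @return \code{path}, invisibly.
#' @export
write_structure <- function(x, path, dialect = c("auto", "tsv", "pdb")) {
  dialect <- match.arg(dialect)
  if (dialect == "auto") {
    dialect <- if (grepl("\\.pdb$", path, ignore.case = TRUE)) "pdb" else "tsv"
  }
  if (dialect == "tsv") {
    s <- if (inherits(x, "cg_trajectory")) x$topology else x
    d <- s$beads[, c("chain", "resid", "kind", "x", "y", "z",
                     "charge", "radius", "tail")]
    con <- file(path, "w")
    on.exit(close(con))
    writeLines("# nucleoslide bead table (x,y,z Angstrom; charge e; radius Angstrom)", con)
    utils::write.table(d, con, sep = "\t", quote = FALSE, row.names = FALSE,
                       na = ".")
  } else {
    .write_cg_pdb(x, path)
  }
  invisible(path)
}

.write_cg_pdb <- function(x, path) {
  if (inherits(x, "cg_trajectory")) {
    topo <- x$topology; frames <- x$frames
  } else {
    topo <- x; frames <- list(coords(x))
  }
  b <- topo$beads
  elem <- c(CA = "C", P = "P", S = "C", B = "C")[b$kind]
  resname <- ifelse(b$kind == "CA", "ALA", "DN")
  con <- file(path, "w")
  on.exit(close(con))
  multi <- length(frames) > 1
  for (m in seq_along(frames)) {
    xyz <- frames[[m]]
    if (multi) writeLines(sprintf("MODEL     %4d", m), con)
    lines <- sprintf(
      "ATOM  %5d %-4s %-3s %1s%4d    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
      seq_len(nrow(b)) %% 100000, b$kind, resname,
      substr(b$chain, 1, 1), b$resid %% 10000,
      xyz[, 1], xyz[, 2], xyz[, 3], elem)
    writeLines(lines, con)
    if (multi) writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}

## --------------------------------------------- all-atom -> CG mapping

NUC_RESIDS <- c("DA", "DT", "DG", "DC", "DU", "A", "T", "G", "C", "U")
PHOSPHATE_ATOMS <- c("P", "OP1", "OP2", "O1P", "O2P")

#' Coarse-grain an all-atom structure
#'
#' Maps an all-atom model (a \code{bio3d} \code{pdb} object or a path to a
#' PDB file) to the coarse-grained representation: each protein residue to a
#' single CA bead at its Calpha atom; each nucleotide to a P bead at the
#' phosphorus, an S bead at the centroid of the sugar-ring heavy atoms
#' (primed atom names) and a B bead at the centroid of the base heavy atoms.
#' 5'-terminal nucleotides without a phosphorus contribute no P bead.
#'
#' @param all_atom a \code{bio3d} \code{pdb} object, or a file path.
#' @return a \code{cg_structure}; residues lacking a Calpha are reported in
#'   attribute \code{"missing"}.
#' @export
coarse_grain <- function(all_atom) {
  if (is.character(all_atom))
    all_atom <- bio3d::read.pdb(all_atom, verbose = FALSE)
  a <- all_atom$atom
  a <- a[is.na(a$type) | a$type %in% c("ATOM", "HETATM"), ]
  a <- a[!grepl("^H", a$elety) & !(a$elesy %in% "H"), ]
  key <- paste(a$chain, a$resno, sep = "\r")
  missing <- character()
  rows <- list()
  for (k in unique(key)) {
    ai <- a[key == k, , drop = FALSE]
    chain <- ai$chain[1]; resno <- ai$resno[1]; resid_name <- ai$resid[1]
    if (resid_name %in% NUC_RESIDS) {
      pa <- ai[ai$elety == "P", , drop = FALSE]
      if (nrow(pa) == 1) {
        rows[[length(rows) + 1]] <- data.frame(
          chain = chain, resid = resno, kind = "P",
          x = pa$x, y = pa$y, z = pa$z)
      } else {
        message("nucleotide ", chain, ":", resno,
                " has no phosphorus (5' terminus); P bead omitted")
      }
      sugar <- ai[grepl("'", ai$elety) | grepl("\\*", ai$elety), , drop = FALSE]
      base <- ai[!grepl("'", ai$elety) & !grepl("\\*", ai$elety) &
                   !(ai$elety %in% PHOSPHATE_ATOMS), , drop = FALSE]
      if (nrow(sugar))
        rows[[length(rows) + 1]] <- data.frame(
          chain = chain, resid = resno, kind = "S",
          x = mean(sugar$x), y = mean(sugar$y), z = mean(sugar$z))
      if (nrow(base))
        rows[[length(rows) + 1]] <- data.frame(
          chain = chain, resid = resno, kind = "B",
          x = mean(base$x), y = mean(base$y), z = mean(base$z))
    } else {
      ca <- ai[ai$elety == "CA", , drop = FALSE]
      if (nrow(ca) == 1) {
        rows[[length(rows) + 1]] <- data.frame(
          chain = chain, resid = resno, kind = "CA",
          x = ca$x, y = ca$y, z = ca$z)
      } else {
        missing <- c(missing, paste0(chain, ":", resno))
      }
    }
  }
  beads <- do.call(rbind, rows)
  out <- cg_structure(beads)
  attr(out, "missing") <- missing
  out
}

## --------------------------------------------------- sequence constructs

#' Construct a DNA sequence record
#'
#' @param name construct name.
#' @param core core (wrapped) sequence, IUPAC DNA text, strand 1, 5'->3'.
#' @param linker5,linker3 linker sequences flanking the core.
#' @return an object of class \code{sequence_construct}.
#' @export
sequence_construct <- function(name, core, linker5 = "", linker3 = "") {
  core <- toupper(gsub("\\s", "", core))
  linker5 <- toupper(gsub("\\s", "", linker5))
  linker3 <- toupper(gsub("\\s", "", linker3))
  ok <- grepl("^[ACGTUNRYSWKM]*$", paste0(linker5, core, linker3))
  if (!ok) stop("sequence contains non-IUPAC characters")
  structure(list(name = name, core = core,
                 linker5 = linker5, linker3 = linker3),
            class = "sequence_construct")
}

#' @export
print.sequence_construct <- function(x, ...) {
  cat("sequence_construct '", x$name, "': ", nchar(x$core), " bp core + ",
      nchar(x$linker5), "/", nchar(x$linker3), " bp linkers = ",
      construct_length(x), " bp total\n", sep = "")
  invisible(x)
}

#' Total length of a sequence construct in base pairs
#' @param x a \code{sequence_construct}.
#' @return integer length.
#' @export
construct_length <- function(x) {
  nchar(x$core) + nchar(x$linker5) + nchar(x$linker3)
}

#' Full strand-1 sequence of a construct
#' @param x a \code{sequence_construct}.
#' @return character scalar (5'->3').
#' @export
construct_sequence <- function(x) paste0(x$linker5, x$core, x$linker3)

#' Reverse complement of a DNA sequence string
#'
#' @param seq character scalar, IUPAC DNA.
#' @return the reverse complement (5'->3' of the opposite strand).
#' @export
dna_complement <- function(seq) {
  comp <- chartr("ACGTUNRYSWKM", "TGCAANYRSWMK", toupper(seq))
  paste(rev(strsplit(comp, "")[[1]]), collapse = "")
}

#' Flank a nucleosome core sequence with polyCG linkers
#'
#' Builds a nucleosome DNA construct by adding polyCG linkers (alternating
#' C/G, phased so each linker starts on C) of the given length to both ends
#' of the core sequence. Nucleosome cores are normally 145 or 147 bp; other
#' lengths are accepted with a warning.
#'
#' @param core a \code{sequence_construct} (its core is used) or a character
#'   core sequence.
#' @param linker_length linker length in bp, added at each end.
#' @param name optional name for the result.
#' @return a \code{sequence_construct} of total length core + 2 x linker.
#' @examples
#' ct <- build_construct(strrep("CG", 74) |> substr(1, 147), 38)
#' construct_length(ct)  # 223
#' @export
build_construct <- function(core, linker_length, name = NULL) {
  if (inherits(core, "sequence_construct")) {
    if (is.null(name)) name <- core$name
    core <- core$core
  }
  if (linker_length < 0) stop("linker_length must be non-negative")
  nc <- nchar(core)
  if (!nc %in% c(145L, 147L))
    warning("core length ", nc, " bp is not a standard nucleosome core (145/147)")
  linker <- substr(strrep("CG", ceiling(linker_length / 2)), 1, linker_length)
  sequence_construct(if (is.null(name)) "construct" else name,
                     core, linker5 = linker, linker3 = linker)
}
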