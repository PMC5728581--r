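# Shared fixtures, built once per test run.

# default ideal nucleosome (147 wrapped bp, 38-bp linkers, 10 bp/turn)
ideal_spec <- superhelix_spec()
ideal <- build_ideal_nucleosome(ideal_spec)
ideal_hb <- extract_hbond_model(ideal)

# small bead table: two short "protein" chains and one 3-bp DNA duplex
toy_duplex <- function() {
  bp <- 0:2
  rise <- 3.4
  mk_strand <- function(chain, phase0, rev_order = FALSE) {
    rows <- lapply(bp, function(b) {
      a <- .rad_(phase0 + 36 * b)
      kinds <- c(if ((!rev_order && b > 0) || (rev_order && b < max(bp))) "P",
                 "S", "B")
      r <- c(P = 9.4, S = 7.4, B = 2.5)[kinds]
      data.frame(chain = chain, resid = b + 1L, kind = kinds,
                 x = r * cos(a), y = r * sin(a), z = rise * b,
                 charge = ifelse(kinds == "P", -1, 0), radius = 2.9,
                 tail = FALSE)
    })
    d <- do.call(rbind, rows)
    if (rev_order) d[order(-d$resid), ] else d
  }
  prot <- data.frame(chain = "A", resid = 1:3, kind = "CA",
                     x = c(0, 3.8, 7.6), y = -12, z = 0,
                     charge = c(0, 1, 0), radius = 3, tail = FALSE)
  cg_structure(rbind(prot, mk_strand("I", 0), mk_strand("J", 140, TRUE)))
}

.rad_ <- function(d) d * pi / 180

# apply a rigid motion (random rotation + translation) to a structure
rigid_move <- function(s, seed = 1) {
  set.seed(seed)
  M <- qr.Q(qr(matrix(rnorm(9), 3)))
  if (det(M) < 0) M[, 1] <- -M[, 1]
  shift <- rnorm(3, 0, 20)
  coords(s) <- sweep(coords(s) %*% M, 2, shift, "+")
  s
}

# straight ideal B-DNA: strand-1 phosphates on a helix about the z axis
straight_bdna <- function(n_bp = 41, radius = 9.4, twist = 10, rise = 3.4) {
  mk <- function(chain, phase0, rev_order = FALSE) {
    b <- 0:(n_bp - 1)
    rows <- lapply(b, function(k) {
      a <- .rad_(phase0 + 360 / twist * k)
      kinds <- c(if ((!rev_order && k > 0) || (rev_order && k < n_bp - 1)) "P",
                 "S", "B")
      r <- c(P = radius, S = 7.4, B = 2.5)[kinds]
      data.frame(chain = chain, resid = k + 1L, kind = kinds,
                 x = r * cos(a), y = r * sin(a), z = rise * k)
    })
    d <- do.call(rbind, rows)
    if (rev_order) d[order(-d$resid), ] else d
  }
  cg_structure(rbind(mk("I", 0), mk("J", 140, TRUE)))
}
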