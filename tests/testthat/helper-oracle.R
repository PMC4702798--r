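# Independent brute-force interaction checker. Re-implements the seven
# geometric rules with plain double loops and its own linear algebra
# (covariance eigenvectors for ring planes instead of SVD), sharing only
# the atom-typing tables' content with the package.

.o_dist <- function(a, b) sqrt(sum((a - b)^2))

.o_angle <- function(a, b, c) {
  u <- (a - b) / .o_dist(a, b)
  v <- (c - b) / .o_dist(c, b)
  acos(max(-1, min(1, sum(u * v)))) * 180 / pi
}

.o_plane_normal <- function(xyz) {
  ctr <- colMeans(xyz)
  cc <- crossprod(sweep(xyz, 2, ctr))
  ev <- eigen(cc, symmetric = TRUE)
  ev$vectors[, 3]
}

.o_donor_tbl <- list(
  SER = c(OG = "CB"), THR = c(OG1 = "CB"), TYR = c(OH = "CZ"),
  TRP = c(NE1 = "CD1"), LYS = c(NZ = "CE"), ASN = c(ND2 = "CG"),
  GLN = c(NE2 = "CD"), ARG = c(NE = "CD", NH1 = "CZ", NH2 = "CZ"),
  HIS = c(ND1 = "CG", NE2 = "CD2"))
.o_acc_tbl <- list(
  ASP = c("OD1", "OD2"), GLU = c("OE1", "OE2"), ASN = "OD1", GLN = "OE1",
  SER = "OG", THR = "OG1", TYR = "OH", HIS = c("ND1", "NE2"))
.o_pos_tbl <- list(LYS = "NZ", ARG = c("NH1", "NH2", "NE"))
.o_neg_tbl <- list(ASP = c("OD1", "OD2"), GLU = c("OE1", "OE2"))
.o_ring_tbl <- list(
  PHE = c("CG", "CD1", "CE1", "CZ", "CE2", "CD2"),
  TYR = c("CG", "CD1", "CE1", "CZ", "CE2", "CD2"),
  HIS = c("CG", "ND1", "CE1", "NE2", "CD2"),
  TRP = c("CD2", "CE2", "CZ2", "CH2", "CZ3", "CE3"))
.o_polar_c <- list(ASP = "CG", GLU = "CD", ASN = "CG", GLN = "CD",
                   ARG = "CZ")

.o_get <- function(res, nm) {
  r <- res[res$elety == nm, c("x", "y", "z")]
  if (nrow(r) == 0) NULL else as.numeric(r[1, ])
}

# 7-bit block for one residue vs one curated ligand, brute force
oracle_block <- function(res, lig, cfg = ifp_config()) {
  bits <- integer(7)
  if (nrow(res) == 0 || nrow(lig$atoms) == 0) return(bits)
  resn <- res$resid[1]
  lxyz <- as.matrix(lig$atoms[, c("x", "y", "z")])

  # 1 hydrophobic
  side <- setdiff(res$elety, c("N", "CA", "C", "O"))
  apol <- side[(substr(side, 1, 1) %in% c("C", "S")) &
                 !side %in% (.o_polar_c[[resn]] %||% character(0))]
  for (an in apol) {
    p <- .o_get(res, an)
    for (k in which(lig$atoms$apolar)) {
      if (.o_dist(p, lxyz[k, ]) <= cfg$hydrophobic_dist) bits[1] <- 1L
    }
  }

  # 2/3 aromatic
  rnames <- .o_ring_tbl[[resn]]
  if (!is.null(rnames) && all(rnames %in% res$elety)) {
    rring <- do.call(rbind, lapply(rnames, .o_get, res = res))
    rc <- colMeans(rring); rn <- .o_plane_normal(rring)
    for (ring in lig$aromatic_rings) {
      lxy <- lxyz[ring, , drop = FALSE]
      lc <- colMeans(lxy); ln <- .o_plane_normal(lxy)
      d <- .o_dist(rc, lc)
      ang <- acos(min(1, abs(sum(rn * ln)))) * 180 / pi
      if (d <= cfg$f2f_dist && ang <= cfg$f2f_angle) bits[2] <- 1L
      if (d <= cfg$e2f_dist && ang >= cfg$e2f_angle[1] &&
          ang <= cfg$e2f_angle[2]) bits[3] <- 1L
    }
  }

  # 4 protein donor -> ligand acceptor
  donors <- list()
  if (!is.null(.o_get(res, "N")) && !is.null(.o_get(res, "CA"))) {
    donors[[1]] <- list(d = .o_get(res, "N"), a = list(.o_get(res, "CA")))
  }
  for (nm in names(.o_donor_tbl[[resn]] %||% character(0))) {
    ant <- .o_donor_tbl[[resn]][[nm]]
    if (!is.null(.o_get(res, nm)) && !is.null(.o_get(res, ant))) {
      donors[[length(donors) + 1]] <- list(d = .o_get(res, nm),
                                           a = list(.o_get(res, ant)))
    }
  }
  for (don in donors) {
    ante <- colMeans(do.call(rbind, don$a))
    for (k in which(lig$atoms$acceptor)) {
      if (.o_dist(don$d, lxyz[k, ]) <= cfg$hbond_dist &&
          .o_angle(ante, don$d, lxyz[k, ]) >= cfg$hbond_angle) bits[4] <- 1L
    }
  }

  # 5 ligand donor -> protein acceptor
  accs <- c(if (!is.null(.o_get(res, "O"))) "O",
            intersect(.o_acc_tbl[[resn]] %||% character(0), res$elety))
  for (an in accs) {
    pa <- .o_get(res, an)
    for (k in which(lig$atoms$donor)) {
      nb <- c(lig$bonds$j[lig$bonds$i == k], lig$bonds$i[lig$bonds$j == k])
      if (.o_dist(lxyz[k, ], pa) > cfg$hbond_dist) next
      if (length(nb) == 0) { bits[5] <- 1L; next }
      ante <- colMeans(lxyz[nb, , drop = FALSE])
      if (.o_angle(ante, lxyz[k, ], pa) >= cfg$hbond_angle) bits[5] <- 1L
    }
  }

  # 6/7 ionic
  for (an in intersect(.o_pos_tbl[[resn]] %||% character(0), res$elety)) {
    p <- .o_get(res, an)
    for (k in which(lig$atoms$charge < 0)) {
      if (.o_dist(p, lxyz[k, ]) <= cfg$ionic_dist) bits[6] <- 1L
    }
  }
  for (an in intersect(.o_neg_tbl[[resn]] %||% character(0), res$elety)) {
    p <- .o_get(res, an)
    for (k in which(lig$atoms$charge > 0)) {
      if (.o_dist(p, lxyz[k, ]) <= cfg$ionic_dist) bits[7] <- 1L
    }
  }
  bits
}

`%||%` <- function(a, b) if (is.null(a)) b else a

oracle_ifp <- function(pocket, lig) {
  bits <- integer(595)
  for (i in 1:85) {
    if (pocket$slots$gap[i]) next
    res <- pocket$atoms[pocket$atoms$slot == i, , drop = FALSE]
    bits[(i - 1) * 7 + 1:7] <- oracle_block(res, lig)
  }
  bits
}

# independent Monte-Carlo surface-area integrator (for the ASA oracle)
mc_sasa <- function(xyz, elements, subset, probe = 1.4, n = 40000,
                    seed = 1) {
  set.seed(seed)
  vdw <- c(C = 1.70, N = 1.55, O = 1.52, S = 1.80, H = 1.20)
  r <- unname(vdw[elements]) + probe
  r[is.na(r)] <- 1.70 + probe
  total <- 0
  for (k in subset) {
    u <- matrix(rnorm(3 * n), ncol = 3)
    u <- u / sqrt(rowSums(u^2))
    pts <- sweep(u * r[k], 2, xyz[k, ], "+")
    free <- rep(TRUE, n)
    for (j in seq_len(nrow(xyz))) {
      if (j == k) next
      dj <- sqrt(colSums((t(pts) - xyz[j, ])^2))
      free <- free & dj >= r[j]
    }
    total <- total + 4 * pi * r[k]^2 * mean(free)
  }
  total
}
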