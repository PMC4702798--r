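#' @importFrom rlang .data
#' @importFrom tibble tibble as_tibble
NULL

# ---------------------------------------------------------------------------
# The master pocket definition: 85 binding-site slots grouped into kinase
# regions, a consensus pocket sequence, and a master structural frame (3D
# coordinate template) used for superposition, conformational descriptors,
# subpocket probes and the synthetic fixture generator.
#
# Region names follow the standard kinase nomenclature: the N-lobe beta
# strands (I-V), the Gly-rich loop (g.l), the alphaC helix (aC), the
# back-loop (b.l), the gatekeeper (GK, slot 45), hinge, linker, the C-lobe
# helices (aD, aE), the catalytic loop (c.l), the xDFG motif (slots 80-82
# with D81/F82) and the activation-loop start (a.l).
# ---------------------------------------------------------------------------

region_defs <- function() {
  tibble(
    region = c("I", "g.l", "II", "III", "aC", "b.l", "IV", "V", "GK",
               "hinge", "linker", "aD", "aE", "VI", "c.l", "VII", "VIII",
               "xDFG", "a.l"),
    from = c(1, 4, 10, 14, 20, 31, 38, 42, 45, 46, 49, 53, 60, 65, 68,
             76, 79, 80, 83),
    to   = c(3, 9, 13, 19, 30, 37, 41, 44, 45, 48, 52, 59, 64, 67, 75,
             78, 79, 82, 85)
  )
}

#' Pocket region table
#'
#' One row per binding-site slot (1..85) giving the kinase region each slot
#' belongs to and its column in the bundled master profile.
#'
#' @return A tibble with columns `index`, `region`, `master_column`.
#' @export
#' @examples
#' kp_regions()
kp_regions <- function() {
  defs <- region_defs()
  purrr::map_dfr(seq_len(nrow(defs)), function(i) {
    tibble(index = seq(defs$from[i], defs$to[i]), region = defs$region[i])
  }) |>
    dplyr::arrange(.data$index) |>
    dplyr::mutate(master_column = .data$index)
}

#' Consensus master pocket sequence
#'
#' The 85-residue consensus sequence of the bundled master profile, one
#' letter per pocket slot. Key conserved positions: the Gly-rich loop motif
#' (slots 4-9), the beta-3 lysine (slot 17), the alphaC glutamate (slot 24),
#' the threonine gatekeeper (slot 45), the catalytic HRD (slots 68-70) and
#' the xDFG motif (slots 80-82).
#'
#' @return A single 85-character string.
#' @export
master_pocket_sequence <- function() {
  paste0(
    "KVL",         # I
    "GQGSFG",      # g.l
    "TVYK",        # II
    "AILKVA",      # III
    "LRAMEVLREAL", # aC (E at 24)
    "NPLIVVT",     # b.l (V at 36)
    "ELMD",        # IV
    "LIA",         # V
    "T",           # GK (45)
    "EYM",         # hinge
    "GSLD",        # linker
    "LTRFLES",     # aD
    "ILGAV",       # aE
    "KIL",         # VI
    "HRDLAARN",    # c.l (HRD at 68-70)
    "VLV",         # VII
    "A",           # VIII
    "ADF",         # xDFG (D81, F82)
    "GLA"          # a.l
  )
}

#' Render a pocket-slot label
#'
#' Labels follow the `[one-letter aa].[region].[slot]` scheme, e.g. the
#' xDFG aspartate is `D.xDFG.81`, the alphaC glutamate `E.aC.24`, a
#' threonine gatekeeper `T.GK.45`.
#'
#' @param aa One-letter amino-acid code(s).
#' @param index Pocket slot index/indices in 1..85.
#' @param regions Region table as returned by [kp_regions()].
#' @return Character vector of labels.
#' @export
#' @examples
#' pocket_label("D", 81)
pocket_label <- function(aa, index, regions = kp_regions()) {
  if (any(index < 1 | index > 85)) {
    stop("pocket slot index must be in 1..85", call. = FALSE)
  }
  paste(aa, regions$region[match(index, regions$index)], index, sep = ".")
}

# slots used as superposition anchors: hinge + catalytic loop + xDFG motif
anchor_slots <- function() c(46:48, 68:75, 80:82)

aa3 <- c(A = "ALA", R = "ARG", N = "ASN", D = "ASP", C = "CYS", Q = "GLN",
         E = "GLU", G = "GLY", H = "HIS", I = "ILE", L = "LEU", K = "LYS",
         M = "MET", F = "PHE", P = "PRO", S = "SER", T = "THR", W = "TRP",
         Y = "TYR", V = "VAL")
aa1 <- stats::setNames(names(aa3), aa3)

# ---------------------------------------------------------------------------
# Canonical CA trace. Hand-placed polyline per region: geometric, not
# physical (see the methods vignette). The frame axes are fixed: y is the
# DFG-flip axis used by the yD/yF descriptors, the hinge sits at the +x
# front, the alphaC helix at the -x back, the Gly-rich loop at +z.
# ---------------------------------------------------------------------------

master_ca_trace <- function(alpha_c_shift = 0) {
  seg <- function(start, dir, n, spacing) {
    u <- unitv(dir)
    t(vapply(seq_len(n) - 1, function(i) start + i * spacing * u,
             numeric(3)))
  }
  ca <- matrix(NA_real_, 85, 3)
  ca[1:3, ]   <- seg(c(2, -3, 12), c(1, 0, 0), 3, 3.8)
  ca[4:9, ]   <- rbind(c(8, 0, 8.5), c(5, 1, 9.5), c(2, 1.5, 10),
                       c(-1.5, 1.5, 10), c(-5, 1, 9.5), c(-8, 0, 8.5))
  ca[10:13, ] <- seg(c(-10, -2, 10), c(1, 0, 0.05), 4, 3.8)
  ca[14:19, ] <- seg(c(5, -1, 7), c(-1, 0, 0), 6, 3.8)
  ca[20:30, ] <- cbind(rep(-9.5 - alpha_c_shift, 11),
                       0.5 + (24 - (20:30)) * 1.5, rep(2.5, 11))
  ca[31:37, ] <- seg(c(-13, -5, 4.5), c(1, 0.3, 0), 7, 3.8)
  ca[38:41, ] <- seg(c(-11.5, -6, 7), c(1, -0.1, 0), 4, 3.8)
  ca[42:44, ] <- rbind(c(5, 3, 6.5), c(4.3, 1.8, 3.3), c(3.6, 0.8, 0.2))
  ca[45, ]    <- c(3.2, 0, -2.8)
  ca[46:48, ] <- rbind(c(6, 0, -3.5), c(8.5, 0.5, -1.5), c(9.5, 1.5, -4.5))
  ca[49:52, ] <- rbind(c(8.8, 2.5, -7), c(6, 3, -8.5), c(2.8, 3, -9),
                       c(-0.5, 2.5, -9.5))
  ca[53:59, ] <- seg(c(1, 5.5, -11), c(-1, 0, 0), 7, 1.5)
  ca[60:64, ] <- seg(c(-10, 4, -12), c(0, -1, 0), 5, 1.5)
  ca[65:67, ] <- rbind(c(-8, -4, -11), c(-5, -4.5, -10.5), c(-1.8, -4, -10))
  ca[68:75, ] <- rbind(c(4, -2, -7), c(1.6, -3, -7.5), c(-0.9, -3.8, -8),
                       c(-3.4, -3, -8.3), c(-5.8, -2, -8), c(-7.5, 0, -7.5),
                       c(-8.5, 2, -7), c(-9, 4, -6.5))
  ca[76:78, ] <- rbind(c(-11, 2, -4.5), c(-11.5, -1, -3.5), c(-11, -4, -3))
  ca[79, ]    <- c(-9.5, -3, -4.5)
  ca[80:82, ] <- rbind(c(-8, -1, -4), c(-5.6, -0.3, -2.8), c(-4, 1, -1))
  ca[83:85, ] <- rbind(c(-1.5, 2.5, -2.5), c(1, 3.5, -3.5), c(3.5, 4.5, -4))
  ca
}

# hexagonal aromatic ring grown from CB along `dir`; returns named matrix
ring_atoms <- function(cb, dir, normal_hint = c(0, 0, 1), tyr_oh = FALSE) {
  dir <- unitv(dir)
  nh <- normal_hint - sum(normal_hint * dir) * dir
  if (vnorm(nh) < 1e-6) nh <- c(1, 0, 0) - dir[1] * dir
  normal <- unitv(pracma_cross(dir, unitv(nh)))
  cg <- cb + 1.4 * dir
  rc <- cb + 2.79 * dir
  e1 <- unitv(cg - rc)
  e2 <- pracma_cross(normal, e1)
  k <- 0:5
  verts <- t(vapply(k, function(kk) {
    th <- kk * pi / 3
    rc + 1.39 * (cos(th) * e1 + sin(th) * e2)
  }, numeric(3)))
  rownames(verts) <- c("CG", "CD1", "CE1", "CZ", "CE2", "CD2")
  if (tyr_oh) {
    verts <- rbind(verts, OH = rc - 2.75 * e1)
  }
  verts
}

# ---------------------------------------------------------------------------
# Full master frame: backbone N/CA/C/O for all 85 slots, CB for non-Gly,
# and full side chains for the functionally loaded residues (K17, E24, T45,
# Y47, D70, D81, F82). The DFG side-chain directions and the alphaC position
# are parameters so conformational states can be generated.
# ---------------------------------------------------------------------------

#' Build the master structural frame
#'
#' Returns the atom table of the master pocket template: backbone atoms for
#' every slot, C-beta for non-glycine slots, and full side chains for the
#' conserved functional residues. Conformational parameters move the DFG
#' side chains (via the y-offsets of the Cgamma positions), translate the
#' alphaC helix away from the pocket, and lift the Gly-rich loop.
#'
#' @param dfg `"in"`, `"out"` or `"outlike"`; preset DFG side-chain
#'   directions (`in`: yD = +1.4, yF = -1.3; `out`: yD = -1.4, yF = +1.3;
#'   `outlike`: yD = +1.4, yF = +1.3).
#' @param alpha_c_shift Outward translation of the alphaC helix in Angstrom
#'   (0 = alphaC-in geometry).
#' @param gloop_lift Displacement of the Gly-rich loop along the canonical
#'   G-loop/catalytic-loop axis, Angstrom.
#' @param yD,yF Optional explicit y-offsets of Cgamma - Calpha for D81/F82,
#'   overriding the `dfg` preset.
#' @return A tibble with columns `slot`, `resno`, `resid`, `elety`,
#'   `element`, `x`, `y`, `z`, `backbone`.
#' @export
kp_master_frame <- function(dfg = c("in", "out", "outlike"),
                            alpha_c_shift = 0, gloop_lift = 0,
                            yD = NULL, yF = NULL) {
  dfg <- match.arg(dfg)
  preset <- switch(dfg,
    "in"      = c(yD = 1.4, yF = -1.3),
    "out"     = c(yD = -1.4, yF = 1.3),
    "outlike" = c(yD = 1.4, yF = 1.3)
  )
  if (is.null(yD)) yD <- preset[["yD"]]
  if (is.null(yF)) yF <- preset[["yF"]]

  ca <- master_ca_trace(alpha_c_shift = alpha_c_shift)
  if (gloop_lift != 0) {
    axis <- unitv(colMeans(ca[4:9, ]) - colMeans(ca[68:75, ]))
    ca[4:9, ] <- sweep(ca[4:9, ], 2, gloop_lift * axis, "+")
  }
  seqv <- strsplit(master_pocket_sequence(), "")[[1]]
  center <- colMeans(ca[c(5, 36, 45, 47, 70, 81, 82), ])

  rows <- vector("list", 85)
  for (i in 1:85) {
    # local chain direction and a perpendicular for carbonyl/CB placement
    prev <- if (i > 1) ca[i - 1, ] else ca[i, ] - (ca[i + 1, ] - ca[i, ])
    nxt <- if (i < 85) ca[i + 1, ] else ca[i, ] + (ca[i, ] - ca[i - 1, ])
    d <- unitv(nxt - prev)
    p <- c(0, 0, 1) - d[3] * d
    if (vnorm(p) < 1e-6) p <- c(1, 0, 0) - d[1] * d
    p <- unitv(p)
    at <- rbind(
      N = ca[i, ] - 1.45 * d,
      CA = ca[i, ],
      C = ca[i, ] + 1.50 * d,
      O = ca[i, ] + 1.50 * d + 1.23 * p
    )
    if (seqv[i] != "G") {
      u <- unitv(center - ca[i, ])
      # keep CB off the backbone axis
      u <- unitv(u - 0.5 * sum(u * d) * d)
      at <- rbind(at, CB = ca[i, ] + 1.53 * u)
      cb <- at["CB", ]
      if (i == 17) { # beta-3 lysine reaching into the pocket
        at <- rbind(at,
                    CG = cb + 1.3 * u, CD = cb + 2.6 * u,
                    CE = cb + 3.9 * u, NZ = cb + 5.0 * u)
      } else if (i == 24) { # alphaC glutamate toward the DFG motif
        v <- unitv(ca[82, ] - ca[i, ])
        at <- rbind(at,
                    CG = cb + 1.3 * v, CD = cb + 2.5 * v,
                    OE1 = cb + 2.5 * v + 1.1 * p,
                    OE2 = cb + 3.5 * v)
      } else if (i == 45) { # threonine gatekeeper
        at <- rbind(at, OG1 = cb + c(0.5, -0.9, 1.0),
                    CG2 = cb + c(-0.6, 1.1, 0.9))
      } else if (i == 47) { # hinge tyrosine, ring facing the pocket
        at <- rbind(at, ring_atoms(cb, u, tyr_oh = TRUE))
      } else if (i == 70) { # catalytic-loop aspartate
        at <- rbind(at, CG = cb + 1.4 * u,
                    OD1 = cb + 1.4 * u + 1.1 * p,
                    OD2 = cb + 2.4 * u)
      } else if (i == 81) { # xDFG aspartate: yD descriptor lives here.
        # In DFG-out geometries (yD < 0) the aspartate swings out of the
        # back pocket into the open cleft and becomes solvent exposed.
        off <- c(0.3, yD, 0.6) + if (yD < 0) c(2.3, 0, 0.4) else c(0, 0, 0)
        cg <- ca[i, ] + off
        w <- unitv(off)
        at["CB", ] <- ca[i, ] + 0.76 * w + 0.4 * p
        at <- rbind(at, CG = cg,
                    OD1 = cg + 0.9 * w + 0.8 * p,
                    OD2 = cg + 1.2 * w - 0.5 * p)
      } else if (i == 82) { # xDFG phenylalanine: yF descriptor + ring
        off <- c(-0.4, yF, -0.5)
        w <- unitv(off)
        at["CB", ] <- ca[i, ] + 1.0 * w
        rng <- ring_atoms(ca[i, ] + 1.0 * w, w, normal_hint = c(1, 0, 0))
        # force the Cgamma y-offset to the requested descriptor value
        rng["CG", ] <- ca[i, ] + off
        at <- rbind(at, rng)
      }
    }
    rows[[i]] <- tibble(
      slot = i, resno = 100L + i, resid = unname(aa3[seqv[i]]),
      elety = rownames(at),
      element = substr(rownames(at), 1, 1),
      x = at[, 1], y = at[, 2], z = at[, 3],
      backbone = rownames(at) %in% c("N", "CA", "C", "O")
    )
  }
  dplyr::bind_rows(rows)
}

# cached canonical frame (DFG-in, alphaC-in); used as the superposition target
master_env <- new.env(parent = emptyenv())

#' Canonical master frame (cached)
#'
#' The DFG-in, alphaC-in master frame used as the fixed superposition target
#' and the coordinate system for subpocket probes and water clusters.
#' @return Atom tibble as from [kp_master_frame()].
#' @export
master_frame <- function() {
  if (is.null(master_env$frame)) master_env$frame <- kp_master_frame()
  master_env$frame
}

# reference heavy-atom names per slot, taken from the canonical frame;
# defines completeness for missing-atom detection
master_reference_atoms <- function() {
  if (is.null(master_env$ref_atoms)) {
    fr <- master_frame()
    master_env$ref_atoms <- split(fr$elety, fr$slot)
  }
  master_env$ref_atoms
}

# centroid of the pocket-lining residues; used to aim side chains and probes
pocket_center <- function() {
  ca <- master_ca_trace()
  colMeans(ca[c(5, 36, 45, 47, 70, 81, 82), ])
}
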