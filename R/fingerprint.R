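# ---------------------------------------------------------------------------
# Kinase-ligand interaction fingerprints: 7 interaction types per pocket
# slot, 85 slots, 595 bits. Bit order within a residue block (protein
# perspective first): hydrophobic, aromatic face-to-face, aromatic
# edge-to-face, H-bond donor (protein) -> acceptor (ligand), H-bond
# acceptor (protein) <- donor (ligand), ionic positive (protein) ->
# negative (ligand), ionic negative (protein) -> positive (ligand).
# ---------------------------------------------------------------------------

IFP_TYPES <- c("hydrophobic", "aromatic_f2f", "aromatic_e2f",
               "hbond_donor", "hbond_acceptor", "ionic_pos", "ionic_neg")

#' Default interaction-detection thresholds
#'
#' Geometric cutoffs for the seven interaction types, following the
#' conventions of structure-based interaction fingerprinting: hydrophobic
#' apolar-pair distance 4.5 A; aromatic face-to-face centroid 4.0 A with
#' inter-plane angle <= 30 degrees; edge-to-face centroid 5.0 A with angle
#' 60-90 degrees; H-bond heavy-atom distance 3.5 A with idealized donor
#' angle >= 120 degrees; ionic opposite-charge distance 4.5 A.
#'
#' @return Named list of thresholds.
#' @export
ifp_config <- function() {
  list(hydrophobic_dist = 4.5,
       f2f_dist = 4.0, f2f_angle = 30,
       e2f_dist = 5.0, e2f_angle = c(60, 90),
       hbond_dist = 3.5, hbond_angle = 120,
       ionic_dist = 4.5)
}

# --- protein-side atom typing (by residue and atom name) -------------------

PROTEIN_DONORS <- list(
  SER = c(OG = "CB"), THR = c(OG1 = "CB"), TYR = c(OH = "CZ"),
  TRP = c(NE1 = "CD1"), LYS = c(NZ = "CE"),
  ASN = c(ND2 = "CG"), GLN = c(NE2 = "CD"),
  ARG = c(NE = "CD", NH1 = "CZ", NH2 = "CZ"),
  HIS = c(ND1 = "CG", NE2 = "CD2")
)

PROTEIN_ACCEPTORS <- list(
  ASP = c("OD1", "OD2"), GLU = c("OE1", "OE2"), ASN = "OD1", GLN = "OE1",
  SER = "OG", THR = "OG1", TYR = "OH", HIS = c("ND1", "NE2")
)

PROTEIN_POSITIVE <- list(LYS = "NZ", ARG = c("NH1", "NH2", "NE"))
PROTEIN_NEGATIVE <- list(ASP = c("OD1", "OD2"), GLU = c("OE1", "OE2"))

PROTEIN_RINGS <- list(
  PHE = c("CG", "CD1", "CE1", "CZ", "CE2", "CD2"),
  TYR = c("CG", "CD1", "CE1", "CZ", "CE2", "CD2"),
  HIS = c("CG", "ND1", "CE1", "NE2", "CD2"),
  TRP = c("CD2", "CE2", "CZ2", "CH2", "CZ3", "CE3")
)

# side-chain carbons that are NOT apolar (carbonyl/guanidinium carbons)
POLAR_SIDECHAIN_C <- list(ASP = "CG", GLU = "CD", ASN = "CG", GLN = "CD",
                          ARG = "CZ")

residue_apolar_atoms <- function(res) {
  side <- res$elety[!res$elety %in% c("N", "CA", "C", "O")]
  el <- substr(side, 1, 1)
  excl <- POLAR_SIDECHAIN_C[[res$resid[1]]] %||% character(0)
  side[(el == "C" | el == "S") & !side %in% excl]
}

atom_xyz <- function(res, names) {
  out <- as.matrix(res[match(names, res$elety), c("x", "y", "z")])
  out[stats::complete.cases(out), , drop = FALSE]
}

# donors with antecedent positions for the idealized-hydrogen angle test
residue_donors <- function(res) {
  out <- list()
  if ("N" %in% res$elety && "CA" %in% res$elety) {
    out[[length(out) + 1]] <- list(
      d = as.numeric(res[res$elety == "N", c("x", "y", "z")]),
      ante = atom_xyz(res, "CA"))
  }
  sc <- PROTEIN_DONORS[[res$resid[1]]]
  for (nm in names(sc)) {
    if (nm %in% res$elety && sc[[nm]] %in% res$elety) {
      out[[length(out) + 1]] <- list(
        d = as.numeric(res[res$elety == nm, c("x", "y", "z")]),
        ante = atom_xyz(res, sc[[nm]]))
    }
  }
  out
}

residue_acceptors <- function(res) {
  nms <- c(if ("O" %in% res$elety) "O",
           intersect(PROTEIN_ACCEPTORS[[res$resid[1]]] %||% character(0),
                     res$elety))
  atom_xyz(res, nms)
}

residue_charged <- function(res, sign) {
  tab <- if (sign > 0) PROTEIN_POSITIVE else PROTEIN_NEGATIVE
  atom_xyz(res, intersect(tab[[res$resid[1]]] %||% character(0), res$elety))
}

residue_rings <- function(res) {
  nms <- PROTEIN_RINGS[[res$resid[1]]]
  if (is.null(nms)) return(list())
  xyz <- atom_xyz(res, nms)
  if (nrow(xyz) < 5) return(list())
  list(xyz)
}

# --- ligand-side typing (from the curated record) --------------------------

ligand_donors <- function(lig) {
  idx <- which(lig$atoms$donor)
  xyz <- ligand_xyz(lig)
  lapply(idx, function(k) {
    nb <- neighbours_of(lig$bonds, k)
    list(d = xyz[k, ],
         ante = xyz[nb, , drop = FALSE])
  })
}

ligand_ring_xyz <- function(lig) {
  xyz <- ligand_xyz(lig)
  lapply(lig$aromatic_rings, function(r) xyz[r, , drop = FALSE])
}

ring_geometry <- function(xyz) {
  pf <- plane_fit(xyz)
  list(centroid = pf$centroid, normal = pf$normal)
}

hbond_geom_ok <- function(donor, antecedents, acceptor, cfg) {
  if (vnorm(donor - acceptor) > cfg$hbond_dist) return(FALSE)
  if (nrow(antecedents) == 0) return(TRUE) # e.g. water: no heavy antecedent
  ante_mean <- colMeans(antecedents)
  vec_angle(ante_mean, donor, acceptor) >= cfg$hbond_angle
}

#' Detect the 7-bit interaction block for one residue
#'
#' Applies the geometric rules in [ifp_config()] between one pocket residue
#' and a curated ligand.
#'
#' @param res Atom tibble of one residue (`elety`, `resid`, `x`, `y`, `z`).
#' @param lig A `kp_ligand` with coordinates in the same frame.
#' @param cfg Threshold list from [ifp_config()].
#' @return Integer vector of 7 bits, named by `IFP_TYPES`.
#' @export
detect_interactions <- function(res, lig, cfg = ifp_config()) {
  bits <- stats::setNames(integer(7), IFP_TYPES)
  if (nrow(res) == 0 || nrow(lig$atoms) == 0) return(bits)
  lxyz <- ligand_xyz(lig)

  # hydrophobic: any apolar-apolar pair within cutoff
  rap <- atom_xyz(res, residue_apolar_atoms(res))
  lap <- lxyz[lig$atoms$apolar, , drop = FALSE]
  if (nrow(rap) > 0 && nrow(lap) > 0 &&
      min(pdist(rap, lap)) <= cfg$hydrophobic_dist) {
    bits["hydrophobic"] <- 1L
  }

  # aromatic: ring-centroid distance + inter-plane angle
  rr <- residue_rings(res)
  lr <- ligand_ring_xyz(lig)
  for (a in rr) for (b in lr) {
    ga <- ring_geometry(a); gb <- ring_geometry(b)
    d <- vnorm(ga$centroid - gb$centroid)
    ang <- axis_angle(ga$normal, gb$normal)
    if (d <= cfg$f2f_dist && ang <= cfg$f2f_angle) bits["aromatic_f2f"] <- 1L
    if (d <= cfg$e2f_dist && ang >= cfg$e2f_angle[1] &&
        ang <= cfg$e2f_angle[2]) bits["aromatic_e2f"] <- 1L
  }

  # H-bonds, idealized-H donor angle from heavy-atom antecedents
  lacc <- lxyz[lig$atoms$acceptor, , drop = FALSE]
  for (don in residue_donors(res)) {
    for (k in seq_len(nrow(lacc))) {
      if (hbond_geom_ok(don$d, don$ante, lacc[k, ], cfg)) {
        bits["hbond_donor"] <- 1L
      }
    }
  }
  racc <- residue_acceptors(res)
  for (don in ligand_donors(lig)) {
    for (k in seq_len(nrow(racc))) {
      if (hbond_geom_ok(don$d, don$ante, racc[k, ], cfg)) {
        bits["hbond_acceptor"] <- 1L
      }
    }
  }

  # ionic: opposite formal-charge centres
  lneg <- lxyz[lig$atoms$charge < 0, , drop = FALSE]
  lpos <- lxyz[lig$atoms$charge > 0, , drop = FALSE]
  rpos <- residue_charged(res, +1)
  rneg <- residue_charged(res, -1)
  if (nrow(rpos) > 0 && nrow(lneg) > 0 &&
      min(pdist(rpos, lneg)) <= cfg$ionic_dist) bits["ionic_pos"] <- 1L
  if (nrow(rneg) > 0 && nrow(lpos) > 0 &&
      min(pdist(rneg, lpos)) <= cfg$ionic_dist) bits["ionic_neg"] <- 1L
  bits
}

new_ifp <- function(bits, apo = FALSE) {
  stopifnot(length(bits) == 595)
  structure(as.integer(bits), apo = apo, class = "kp_ifp")
}

#' Compute the 595-bit interaction fingerprint
#'
#' Concatenates the 7-bit interaction blocks of the 85 pocket slots in slot
#' order. GAP slots (missing residues) contribute seven zeroes, so the
#' fingerprint always has length 595 and remains comparable across
#' structures. An apo structure (no ligand) yields the all-zero fingerprint
#' flagged `apo`.
#'
#' @param pocket A `kp_pocket`.
#' @param lig A `kp_ligand` in the same frame, or `NULL` for apo.
#' @param cfg Thresholds from [ifp_config()].
#' @return A `kp_ifp`: integer bit vector of length 595 with an `apo`
#'   attribute.
#' @export
compute_ifp <- function(pocket, lig, cfg = ifp_config()) {
  if (is.null(lig)) return(new_ifp(integer(595), apo = TRUE))
  bits <- integer(595)
  for (i in 1:85) {
    if (pocket$slots$gap[i]) next
    res <- pocket$atoms[pocket$atoms$slot == i, , drop = FALSE]
    bits[(i - 1) * 7 + 1:7] <- detect_interactions(res, lig, cfg)
  }
  new_ifp(bits)
}

#' @export
print.kp_ifp <- function(x, ...) {
  cat(sprintf("<kp_ifp> %d/595 bits set%s\n", sum(x),
              if (isTRUE(attr(x, "apo"))) " [apo]" else ""))
  invisible(x)
}

#' @export
tidy.kp_ifp <- function(x, ...) {
  tibble(slot = rep(1:85, each = 7), type = rep(IFP_TYPES, 85),
         bit = as.integer(x))
}

#' Heat-map view of an interaction fingerprint
#'
#' @param object A `kp_ifp`.
#' @param ... Ignored.
#' @return A ggplot object (85 slots x 7 interaction types).
#' @export
autoplot.kp_ifp <- function(object, ...) {
  df <- tidy.kp_ifp(object)
  ggplot2::ggplot(df, ggplot2::aes(
    x = .data$slot, y = factor(.data$type, levels = rev(IFP_TYPES)),
    fill = factor(.data$bit))) +
    ggplot2::geom_tile(colour = "grey90", linewidth = 0.1) +
    ggplot2::scale_fill_manual(values = c(`0` = "white", `1` = "grey20"),
                               guide = "none") +
    ggplot2::labs(x = "pocket slot", y = NULL) +
    ggplot2::theme_minimal()
}

#' Tanimoto similarity of two interaction fingerprints
#'
#' `|a AND b| / |a OR b|` over set bits; defined as 1 when both
#' fingerprints are all-zero.
#'
#' @param a,b `kp_ifp` objects (or 595-bit vectors).
#' @return Similarity in `[0, 1]`.
#' @export
ifp_similarity <- function(a, b) {
  a <- as.integer(a); b <- as.integer(b)
  if (length(a) != length(b)) stop("fingerprint length mismatch", call. = FALSE)
  u <- sum(a | b)
  if (u == 0) return(1)
  sum(a & b) / u
}

#' Build an interaction-pattern constraint set
#'
#' @param present,absent Constraints as `"slot:type"` strings (e.g.
#'   `"81:hbond_acceptor"`) or two-column data frames (`slot`, `type`).
#' @return A `kp_pattern`.
#' @export
kp_pattern <- function(present = character(0), absent = character(0)) {
  parse1 <- function(x) {
    if (is.data.frame(x)) return(tibble(slot = as.integer(x$slot),
                                        type = as.character(x$type)))
    if (length(x) == 0) return(tibble(slot = integer(0), type = character(0)))
    parts <- stringr::str_split_fixed(x, ":", 2)
    tibble(slot = as.integer(parts[, 1]), type = parts[, 2])
  }
  pat <- dplyr::bind_rows(
    dplyr::mutate(parse1(present), required = "present"),
    dplyr::mutate(parse1(absent), required = "absent")
  )
  if (nrow(pat) > 0) {
    stopifnot(all(pat$slot >= 1 & pat$slot <= 85),
              all(pat$type %in% IFP_TYPES))
  }
  structure(pat, class = c("kp_pattern", class(pat)))
}

ifp_bit_index <- function(slot, type) {
  (slot - 1L) * 7L + match(type, IFP_TYPES)
}

#' Match a fingerprint against an interaction pattern
#'
#' @param fp A `kp_ifp`.
#' @param pattern A `kp_pattern`.
#' @return `TRUE` iff every `present` constraint bit is 1 and every
#'   `absent` constraint bit is 0. The empty pattern matches everything.
#' @export
match_pattern <- function(fp, pattern) {
  if (nrow(pattern) == 0) return(TRUE)
  idx <- ifp_bit_index(pattern$slot, pattern$type)
  bits <- as.integer(fp)[idx]
  all(bits[pattern$required == "present"] == 1L) &&
    all(bits[pattern$required == "absent"] == 0L)
}

#' Serialize a fingerprint to hexadecimal
#'
#' 595 bits are padded to 600 (five trailing zero bits) and written as 150
#' hex digits; [ifp_from_hex()] inverts this.
#'
#' @param fp A `kp_ifp`.
#' @return Single hex string.
#' @export
ifp_to_hex <- function(fp) {
  bits <- c(as.integer(fp), integer(5))
  nib <- matrix(bits, nrow = 4)
  vals <- as.integer(8 * nib[1, ] + 4 * nib[2, ] + 2 * nib[3, ] + nib[4, ])
  paste(strsplit("0123456789abcdef", "")[[1]][vals + 1], collapse = "")
}

#' @rdname ifp_to_hex
#' @param hex Hex string from [ifp_to_hex()].
#' @export
ifp_from_hex <- function(hex) {
  vals <- strtoi(strsplit(hex, "")[[1]], base = 16L)
  bits <- as.integer(vapply(vals, function(v) {
    c(bitwAnd(v, 8L) > 0, bitwAnd(v, 4L) > 0, bitwAnd(v, 2L) > 0,
      bitwAnd(v, 1L) > 0)
  }, logical(4)))
  new_ifp(bits[1:595])
}
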