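# ---------------------------------------------------------------------------
# Synthetic fixture generator: kinase-like pocket structures and complexes
# built from the master frame with known ground truth (designed interaction
# bits, conformation classes, gaps, mutations, subpocket occupancy, water
# cluster membership). Fixtures are geometric, not physical: ligand groups
# are placed analytically to satisfy - or stay clear of - each interaction
# rule, and every designed-contact manifest is verified at build time.
# ---------------------------------------------------------------------------

#' Specify a synthetic kinase complex
#'
#' @param seed Integer seed; the whole build is deterministic given the spec.
#' @param kinase_id Identifier written on outputs.
#' @param dfg `"in"`, `"out"` or `"outlike"`; the generated DFG side-chain
#'   geometry (class means yD/yF = (+1.4, -1.3), (-1.4, +1.3), (+1.4, +1.3)
#'   with per-fixture jitter `conf_jitter`).
#' @param alpha_c `"in"`, `"outlike"`, `"out"` or a numeric outward shift in
#'   Angstrom (class shifts drawn from U(-0.5, 0.5), U(1.5, 2.5), U(4, 7)).
#' @param gloop_lift G-rich loop displacement along the G-loop/catalytic
#'   loop axis, Angstrom.
#' @param contacts List of designed ligand contacts, each
#'   `list(slot =, type =)` with `type` one of the seven interaction types.
#' @param gaps Slots to delete entirely (GAP).
#' @param truncations Named list `slot -> atom names` to drop (missing
#'   atoms).
#' @param mutations Named character vector `slot -> one-letter aa`.
#' @param insertions List of `list(after_slot =, aa =)` extra residues.
#' @param noise Gaussian coordinate noise sd, Angstrom (protein atoms).
#' @param occupy Subpocket labels the ligand should occupy: one
#'   interaction-inert marker atom (fluorine, which participates in none of
#'   the seven interaction rules) is placed at each label's canonical
#'   centre, so the ligand is flagged for those (sub)pockets.
#' @param waters Character vector of water-cluster labels (I1..I11, O1, O2)
#'   or `"off"` for an off-cluster water; placed with <= 0.5 A jitter.
#' @param resno_offset First residue number minus one.
#' @param conf_jitter SD of the DFG side-chain descriptor jitter.
#' @return A `kp_fixture_spec`.
#' @export
fixture_spec <- function(seed = 1, kinase_id = sprintf("SYN%04d", seed),
                         dfg = "in", alpha_c = "in", gloop_lift = 0,
                         contacts = list(), occupy = character(0),
                         gaps = integer(0),
                         truncations = list(), mutations = character(0),
                         insertions = list(), noise = 0,
                         waters = character(0), resno_offset = 100L,
                         conf_jitter = 0.15) {
  stopifnot(dfg %in% c("in", "out", "outlike"),
            is.numeric(alpha_c) || alpha_c %in% c("in", "outlike", "out"),
            noise >= 0, all(occupy %in% subpocket_labels()$label))
  for (ct in contacts) {
    stopifnot(ct$slot %in% 1:85, ct$type %in% IFP_TYPES)
  }
  structure(list(seed = seed, kinase_id = kinase_id, dfg = dfg,
                 alpha_c = alpha_c, gloop_lift = gloop_lift,
                 contacts = contacts, occupy = occupy,
                 gaps = as.integer(gaps),
                 truncations = truncations, mutations = mutations,
                 insertions = insertions, noise = noise, waters = waters,
                 resno_offset = as.integer(resno_offset),
                 conf_jitter = conf_jitter),
            class = "kp_fixture_spec")
}

# choose the placement direction for a contact group: candidate unit
# vectors (optionally restricted to a cone around the allowed approach,
# angle at `origin` w.r.t. `ante` >= min_angle) are scored by the minimum
# clearance of the group's atoms - computed by `layout(u)` - to the rest of
# the protein; the most open direction wins
best_direction <- function(origin, protein_xyz, layout, ante = NULL,
                           min_angle = 140, n_cand = 200) {
  cand <- sphere_points(n_cand)
  if (!is.null(ante)) {
    keep <- vapply(seq_len(nrow(cand)), function(i) {
      vec_angle(ante, origin, origin + cand[i, ]) >= min_angle
    }, logical(1))
    cand <- cand[keep, , drop = FALSE]
  }
  score <- vapply(seq_len(nrow(cand)), function(i) {
    min(min_dist(layout(cand[i, ]), protein_xyz))
  }, numeric(1))
  cand[which.max(score), ]
}

# --- designed-contact group builders --------------------------------------
# each returns list(atoms = tibble(name, element, x, y, z),
#                   bonds = tibble(i, j, order), implied = extra bit types)

lig_atom <- function(name, element, p) {
  tibble(name = name, element = element, x = p[1], y = p[2], z = p[3])
}

# Contact groups use polar-only scaffolds wherever the designed bit allows
# it (carbonyl, amide, carboxylate, ammonium, and a triazine-like C3N3 ring
# for aromatic stacking) so no incidental hydrophobic contacts arise; the
# lone apolar carbon of a hydrophobic contact is placed at the most open
# direction around its target.
build_contact <- function(slot, type, frame_atoms, counter) {
  res <- frame_atoms[frame_atoms$slot == slot, ]
  other <- as.matrix(frame_atoms[frame_atoms$slot != slot,
                                 c("x", "y", "z")])
  nm <- function(base) paste0(base, counter)
  if (type == "hydrophobic") {
    cb <- as.numeric(res[res$elety == "CB", c("x", "y", "z")])
    u <- best_direction(cb, other, function(u) matrix(cb + 4.0 * u, 1))
    atoms <- lig_atom(nm("C1"), "C", cb + 4.0 * u)
    list(atoms = atoms,
         bonds = tibble(i = integer(0), j = integer(0), order = character(0)),
         implied = character(0))
  } else if (type %in% c("aromatic_f2f", "aromatic_e2f")) {
    ring_nm <- c("CG", "CD1", "CE1", "CZ", "CE2", "CD2")
    rxyz <- as.matrix(res[match(ring_nm, res$elety), c("x", "y", "z")])
    if (any(is.na(rxyz))) stop("slot ", slot, " has no aromatic ring")
    geo <- ring_geometry(rxyz)
    n <- geo$normal
    # aim the ring stack toward open space
    if (min_dist(matrix(geo$centroid + 4 * n, 1), other) <
        min_dist(matrix(geo$centroid - 4 * n, 1), other)) n <- -n
    if (type == "aromatic_f2f") {
      rc <- geo$centroid + 3.6 * n
      e1 <- unitv(rxyz[1, ] - geo$centroid)
      e2 <- pracma_cross(n, e1)
    } else {
      rc <- geo$centroid + 4.7 * n
      # perpendicular ring: its normal lies in the residue ring plane
      e1 <- n
      aux <- unitv(rxyz[1, ] - geo$centroid)
      e2 <- pracma_cross(pracma_cross(n, aux), e1)
    }
    verts <- t(vapply(0:5, function(k) {
      th <- k * pi / 3
      rc + 1.39 * (cos(th) * e1 + sin(th) * e2)
    }, numeric(3)))
    # alternating C/N (triazine-like): ring carbons have N neighbours and
    # stay out of the hydrophobic rule
    el <- rep(c("C", "N"), 3)
    atoms <- purrr::map_dfr(1:6, function(k) {
      lig_atom(nm(paste0(ifelse(el[k] == "C", "CR", "NR"), k)), el[k],
               verts[k, ])
    })
    bonds <- tibble(i = 1:6, j = c(2:6, 1L), order = "ar")
    list(atoms = atoms, bonds = bonds, implied = character(0))
  } else if (type == "hbond_donor") {
    # protein backbone N donates to a ligand carbonyl oxygen
    dN <- as.numeric(res[res$elety == "N", c("x", "y", "z")])
    ca <- as.numeric(res[res$elety == "CA", c("x", "y", "z")])
    u <- best_direction(dN, other, function(u) {
      rbind(dN + 2.9 * u, dN + 4.13 * u)
    }, ante = ca)
    atoms <- dplyr::bind_rows(lig_atom(nm("O"), "O", dN + 2.9 * u),
                              lig_atom(nm("C"), "C", dN + 4.13 * u))
    bonds <- tibble(i = 1L, j = 2L, order = "2")
    list(atoms = atoms, bonds = bonds, implied = character(0))
  } else if (type == "hbond_acceptor") {
    # ligand amide N-H donates to the protein backbone carbonyl oxygen
    aO <- as.numeric(res[res$elety == "O", c("x", "y", "z")])
    cC <- as.numeric(res[res$elety == "C", c("x", "y", "z")])
    w0 <- unitv(pracma_cross(c(0, 0, 1), aO - cC))
    layout <- function(u) {
      w <- unitv(pracma_cross(u, w0))
      rbind(aO + 2.9 * u, aO + 4.37 * u, aO + 4.97 * u + 1.1 * w)
    }
    u <- best_direction(aO, other, layout, ante = cC, min_angle = 120)
    pos <- layout(u)
    atoms <- dplyr::bind_rows(lig_atom(nm("N"), "N", pos[1, ]),
                              lig_atom(nm("C"), "C", pos[2, ]),
                              lig_atom(nm("O2"), "O", pos[3, ]))
    bonds <- tibble(i = c(1L, 2L), j = c(2L, 3L), order = c("1", "2"))
    list(atoms = atoms, bonds = bonds, implied = character(0))
  } else if (type == "ionic_pos") {
    # ligand carboxylate faces a protein positive centre (beta-3 lysine NZ)
    nz <- as.numeric(res[res$elety == "NZ", c("x", "y", "z")])
    ce <- as.numeric(res[res$elety == "CE", c("x", "y", "z")])
    layout <- function(u) {
      w <- unitv(pracma_cross(u, if (abs(u[3]) < 0.9) c(0, 0, 1) else
        c(1, 0, 0)))
      pC <- nz + 4.9 * u
      rbind(pC - 1.25 * unitv(u + 0.45 * w), pC,
            pC - 1.25 * unitv(u - 0.45 * w))
    }
    u <- best_direction(nz, other, layout, ante = ce, min_angle = 120)
    pos <- layout(u)
    atoms <- dplyr::bind_rows(lig_atom(nm("OC1"), "O", pos[1, ]),
                              lig_atom(nm("CC"), "C", pos[2, ]),
                              lig_atom(nm("OC2"), "O", pos[3, ]))
    bonds <- tibble(i = c(1L, 3L), j = c(2L, 2L), order = c("1", "1"))
    list(atoms = atoms, bonds = bonds, implied = character(0))
  } else if (type == "ionic_neg") {
    # ligand ammonium nitrogen faces a protein carboxylate
    neg <- res[res$elety %in% c("OD1", "OD2", "OE1", "OE2"), ]
    if (nrow(neg) == 0) stop("slot ", slot, " has no negative centre")
    od <- as.numeric(neg[1, c("x", "y", "z")])
    cg <- as.numeric(res[res$elety %in% c("CG", "CD"), c("x", "y", "z")][1, ])
    layout <- function(u) rbind(od + 4.0 * u, od + 5.47 * u)
    u <- best_direction(od, other, layout, ante = cg, min_angle = 110)
    atoms <- dplyr::bind_rows(lig_atom(nm("N"), "N", od + 4.0 * u),
                              lig_atom(nm("C"), "C", od + 5.47 * u))
    bonds <- tibble(i = 1L, j = 2L, order = "1")
    list(atoms = atoms, bonds = bonds, implied = character(0))
  } else {
    stop("unknown contact type ", type)
  }
}

mutate_slot <- function(atoms, slot, aa) {
  res3 <- aa3[[aa]]
  keep <- atoms$slot != slot |
    atoms$elety %in% c("N", "CA", "C", "O", if (aa != "G") "CB")
  atoms <- atoms[keep, ]
  atoms$resid[atoms$slot == slot] <- res3
  atoms
}

#' Generate a synthetic kinase complex
#'
#' Builds the protein from the master frame with the spec's conformation,
#' gaps, mutations, truncations and noise; places ligand groups that
#' satisfy each designed contact (verified at build time against the
#' interaction rules — contradictory or colliding designs fail); adds
#' waters at the requested cluster sites. Output is deterministic given the
#' spec.
#'
#' @param spec A `kp_fixture_spec`.
#' @param dir If non-`NULL`, write PDB/MOL2 files and a JSON manifest here.
#' @param validate Verify designed contacts against the interaction rules
#'   (default `TRUE` when contacts are designed and `noise == 0`).
#' @return A `kp_fixture`: list with `monomer` (`kp_monomer`),
#'   `ligand_atoms`/`ligand_bonds` (or `NULL`), `waters` (matrix), and
#'   `manifest` (ground truth).
#' @export
generate_complex <- function(spec, dir = NULL,
                             validate = length(spec$contacts) > 0 &&
                               spec$noise == 0) {
  set.seed(spec$seed)
  jit <- function(n) stats::rnorm(n, 0, spec$conf_jitter)
  yDyF <- switch(spec$dfg,
                 "in" = c(1.4, -1.3), "out" = c(-1.4, 1.3),
                 "outlike" = c(1.4, 1.3)) + jit(2)
  shift <- if (is.numeric(spec$alpha_c)) spec$alpha_c else
    switch(spec$alpha_c,
           "in" = stats::runif(1, -0.5, 0.5),
           "outlike" = stats::runif(1, 1.5, 2.5),
           "out" = stats::runif(1, 4, 7))
  frame <- kp_master_frame(dfg = spec$dfg, alpha_c_shift = shift,
                           gloop_lift = spec$gloop_lift,
                           yD = yDyF[1], yF = yDyF[2])

  atoms <- frame
  for (s in names(spec$mutations)) {
    atoms <- mutate_slot(atoms, as.integer(s), spec$mutations[[s]])
  }
  for (s in names(spec$truncations)) {
    sl <- as.integer(s)
    atoms <- atoms[!(atoms$slot == sl &
                       atoms$elety %in% spec$truncations[[s]]), ]
  }
  if (length(spec$gaps) > 0) atoms <- atoms[!atoms$slot %in% spec$gaps, ]

  # ligand built against the clean frame, before protein noise
  lig_atoms <- NULL
  lig_bonds <- NULL
  designed <- tibble(slot = integer(0), type = character(0))
  if (length(spec$contacts) > 0 || length(spec$occupy) > 0) {
    parts <- list()
    bonds <- tibble(i = integer(0), j = integer(0), order = character(0))
    off <- 0L
    for (ci in seq_along(spec$contacts)) {
      ct <- spec$contacts[[ci]]
      g <- build_contact(ct$slot, ct$type, atoms, ci)
      parts[[ci]] <- g$atoms
      bonds <- dplyr::bind_rows(bonds, dplyr::mutate(
        g$bonds, i = .data$i + off, j = .data$j + off))
      if (ci > 1) { # topological link between consecutive groups (C-C
        # where possible so apolar typing is preserved)
        prev_c <- which(parts[[ci - 1]]$element == "C")
        this_c <- which(g$atoms$element == "C")
        i_prev <- off - nrow(parts[[ci - 1]]) +
          (if (length(prev_c) > 0) prev_c[length(prev_c)] else 1L)
        j_this <- off + (if (length(this_c) > 0) this_c[1] else 1L)
        bonds <- dplyr::bind_rows(bonds, tibble(
          i = as.integer(i_prev), j = as.integer(j_this), order = "1"))
      }
      designed <- dplyr::bind_rows(
        designed,
        tibble(slot = ct$slot, type = c(ct$type, g$implied)))
      off <- off + nrow(g$atoms)
    }
    lig_atoms <- dplyr::bind_rows(parts)
    lig_bonds <- bonds
    designed <- dplyr::distinct(designed)
    if (length(spec$occupy) > 0) {
      an <- subpocket_anchors()
      fo <- an[match(spec$occupy, an$label), ]
      f_atoms <- tibble(name = paste0("F", seq_len(nrow(fo))),
                        element = "F", x = fo$cx, y = fo$cy, z = fo$cz)
      n0 <- if (is.null(lig_atoms)) 0L else nrow(lig_atoms)
      anchor_at <- if (n0 > 0) {
        cs <- which(lig_atoms$element == "C")
        if (length(cs) > 0) cs[1] else 1L
      }
      f_bonds <- tibble(
        i = if (n0 > 0) rep(as.integer(anchor_at), nrow(fo)) else
          utils::head(n0 + seq_len(nrow(fo)), -1),
        j = if (n0 > 0) n0 + seq_len(nrow(fo)) else
          utils::tail(n0 + seq_len(nrow(fo)), -1),
        order = "1")
      if (n0 == 0 && nrow(fo) == 1) {
        f_bonds <- tibble(i = integer(0), j = integer(0),
                          order = character(0))
      }
      lig_atoms <- dplyr::bind_rows(lig_atoms, f_atoms)
      lig_bonds <- dplyr::bind_rows(lig_bonds, f_bonds)
    }
  }

  if (spec$noise > 0) {
    n <- nrow(atoms)
    atoms$x <- atoms$x + stats::rnorm(n, 0, spec$noise)
    atoms$y <- atoms$y + stats::rnorm(n, 0, spec$noise)
    atoms$z <- atoms$z + stats::rnorm(n, 0, spec$noise)
  }

  # residue list in sequence order, with optional insertions
  res_order <- tibble(slot = sort(unique(atoms$slot)))
  ins_rows <- purrr::map_dfr(spec$insertions, function(ins) {
    tibble(slot = ins$after_slot + seq_along(strsplit(ins$aa, "")[[1]]) / 10,
           ins_aa = strsplit(ins$aa, "")[[1]])
  })
  prot <- atoms
  if (nrow(ins_rows) > 0) {
    base <- master_ca_trace()
    ins_atoms <- purrr::map_dfr(seq_len(nrow(ins_rows)), function(k) {
      anchor <- base[floor(ins_rows$slot[k]), ] + c(0, 2.5, 2) * k
      tibble(slot = ins_rows$slot[k], resno = NA_integer_,
             resid = unname(aa3[ins_rows$ins_aa[k]]),
             elety = c("N", "CA", "C", "O"),
             element = c("N", "C", "C", "O"),
             x = anchor[1] + c(-1.2, 0, 1.2, 1.2),
             y = anchor[2] + c(0, 0, 0, 1.23),
             z = anchor[3], backbone = TRUE)
    })
    prot <- dplyr::bind_rows(atoms, ins_atoms)
  }
  prot <- dplyr::arrange(prot, .data$slot)
  resno_map <- tibble(slot = unique(prot$slot))
  resno_map$resno <- spec$resno_offset + seq_len(nrow(resno_map))
  prot$resno <- resno_map$resno[match(prot$slot, resno_map$slot)]

  # waters
  wmat <- matrix(numeric(0), 0, 3)
  if (length(spec$waters) > 0) {
    sites <- canonical_water_sites()
    wmat <- t(vapply(spec$waters, function(lb) {
      if (lb == "off") return(c(20, 20, 20) + stats::runif(3, -1, 1))
      s <- sites[sites$label == lb, ]
      jitter_dir <- unitv(stats::rnorm(3))
      c(s$x, s$y, s$z) + stats::runif(1, 0, 0.5) * jitter_dir
    }, numeric(3)))
  }

  monomer_atoms <- tibble(
    eleno = seq_len(nrow(prot)), elety = prot$elety, resid = prot$resid,
    chain = "A", resno = prot$resno, x = prot$x, y = prot$y, z = prot$z,
    o = 1, b = 0, elesy = prot$element, type = "ATOM"
  )
  het <- list()
  if (!is.null(lig_atoms)) {
    het[[1]] <- tibble(
      eleno = nrow(prot) + seq_len(nrow(lig_atoms)),
      elety = lig_atoms$name, resid = "LIG", chain = "A", resno = 900L,
      x = lig_atoms$x, y = lig_atoms$y, z = lig_atoms$z,
      o = 1, b = 0, elesy = lig_atoms$element, type = "HETATM")
  }
  if (nrow(wmat) > 0) {
    het[[length(het) + 1]] <- tibble(
      eleno = 5000L + seq_len(nrow(wmat)), elety = "O", resid = "HOH",
      chain = "A", resno = 950L + seq_len(nrow(wmat)),
      x = wmat[, 1], y = wmat[, 2], z = wmat[, 3],
      o = 1, b = 0, elesy = "O", type = "HETATM")
  }
  monomer <- new_monomer(spec$kinase_id, 1L, "A", monomer_atoms,
                         dplyr::bind_rows(het))

  manifest <- list(
    kinase_id = spec$kinase_id, dfg = paste0("DFG-", spec$dfg),
    alpha_c = if (is.numeric(spec$alpha_c)) NULL else
      paste0("aC-", spec$alpha_c),
    alpha_c_shift = shift,
    gaps = spec$gaps,
    mutations = spec$mutations,
    truncations = spec$truncations,
    expected_ifp = designed,
    subpockets = if (!is.null(lig_atoms)) {
      anchor_truth_labels(as.matrix(lig_atoms[, c("x", "y", "z")]))
    } else character(0),
    waters = setdiff(spec$waters, "off"),
    apo = is.null(lig_atoms)
  )

  fx <- structure(list(monomer = monomer, ligand_atoms = lig_atoms,
                       ligand_bonds = lig_bonds, waters = wmat,
                       manifest = manifest, spec = spec),
                  class = "kp_fixture")
  if (validate && !is.null(lig_atoms)) validate_fixture(fx)
  if (!is.null(dir)) write_fixture(fx, dir)
  fx
}

#' Curated ligand record of a fixture
#' @param fx A `kp_fixture`.
#' @return A `kp_ligand`, or `NULL` for apo fixtures.
#' @export
fixture_ligand <- function(fx) {
  if (is.null(fx$ligand_atoms)) return(NULL)
  g <- tibble(name = fx$ligand_atoms$name, element = fx$ligand_atoms$element,
              x = fx$ligand_atoms$x, y = fx$ligand_atoms$y,
              z = fx$ligand_atoms$z, resid = "LIG")
  attr(g, "kp_bonds") <- fx$ligand_bonds
  curate_ligand_topology(g)
}

# build-time verification: the computed fingerprint of the clean fixture
# must equal the designed bits exactly (no incidental contacts)
validate_fixture <- function(fx) {
  pocket <- extract_pocket(NULL, fx$monomer, kinase_id = fx$spec$kinase_id)
  fp <- compute_ifp(pocket, fixture_ligand(fx))
  got <- tidy.kp_ifp(fp) |> dplyr::filter(.data$bit == 1L)
  want <- fx$manifest$expected_ifp
  same <- setequal(paste(got$slot, got$type),
                   paste(want$slot, want$type))
  if (!same) {
    stop("fixture spec produces incidental or missing contacts; got [",
         paste(got$slot, got$type, sep = ":", collapse = ", "),
         "] designed [",
         paste(want$slot, want$type, sep = ":", collapse = ", "), "]",
         call. = FALSE)
  }
  invisible(TRUE)
}

#' Write a fixture to disk
#'
#' PDB for the complex, MOL2 for the ligand, JSON for the ground-truth
#' manifest. Deterministic byte output for a given spec.
#'
#' @param fx A `kp_fixture`.
#' @param dir Output directory.
#' @return Invisibly, the paths written.
#' @export
write_fixture <- function(fx, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  base <- file.path(dir, fx$spec$kinase_id)
  paths <- paste0(base, "_complex.pdb")
  write_atoms_pdb(fx$monomer$atoms, fx$monomer$hetero, paths)
  if (!is.null(fx$ligand_atoms)) {
    f <- paste0(base, "_ligand.mol2")
    write_mol2(dplyr::mutate(fx$ligand_atoms, resid = "LIG", resno = 1L),
               fx$ligand_bonds, f, name = "LIG")
    paths <- c(paths, f)
  }
  mf <- paste0(base, "_manifest.json")
  jsonlite::write_json(fx$manifest, mf, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(c(paths, mf))
}

# stratified class counts: sizes differ by at most one, later classes take
# the remainder (n = 100, k = 3 -> 33/33/34)
stratified_counts <- function(n, k) {
  base <- n %/% k
  extra <- n %% k
  base + c(rep(0, k - extra), rep(1, extra))
}

#' Generate a labelled conformational corpus
#'
#' Reproducible set of apo fixtures stratified over the three DFG classes
#' (and cycling over the three alphaC classes within each), for classifier
#' training/validation.
#'
#' @param n Number of fixtures (>= 10).
#' @param seed Corpus seed; fixture `i` uses `seed * 1000 + i`.
#' @param noise Coordinate noise sd per fixture, Angstrom.
#' @return List of `kp_fixture` objects; labels are in each manifest.
#' @export
generate_corpus <- function(n, seed = 1, noise = 0.1) {
  stopifnot(n >= 10)
  counts <- stratified_counts(n, 3)
  dfg_lab <- rep(c("in", "out", "outlike"), counts)
  ac_lab <- unlist(lapply(counts, function(k) {
    rep(c("in", "outlike", "out"), length.out = k)
  }))
  lapply(seq_len(n), function(i) {
    generate_complex(fixture_spec(
      seed = seed * 1000 + i,
      kinase_id = sprintf("SYN%d_%03d", seed, i),
      dfg = dfg_lab[i], alpha_c = ac_lab[i], noise = noise))
  })
}

#' Generate a synthetic subpocket training corpus
#'
#' Ligand-like atom clouds sampled inside the canonical (sub)pocket
#' envelopes of the master frame, labelled with every (sub)pocket they
#' touch (ground truth by construction).
#'
#' @param n Number of clouds.
#' @param seed Corpus seed.
#' @param atoms_range Atoms per cloud (uniform integer range).
#' @return List of examples `list(xyz, labels)` as consumed by
#'   [train_subpocket_model()].
#' @export
generate_subpocket_corpus <- function(n, seed = 1, atoms_range = c(8, 20)) {
  set.seed(seed)
  an <- subpocket_anchors()
  sub <- an[!is.na(subpocket_labels()$parent), ]
  lapply(seq_len(n), function(i) {
    # each cloud concentrates in one subpocket, with a tail into its
    # neighbourhood
    a <- sub[1 + (i - 1) %% nrow(sub), ]
    n_at <- sample(seq(atoms_range[1], atoms_range[2]), 1)
    ctr <- c(a$cx, a$cy, a$cz)
    pts <- matrix(stats::rnorm(3 * n_at, 0, a$radius / 2.2), ncol = 3)
    pts <- sweep(pts, 1, pmin(1, a$radius / sqrt(rowSums(pts^2))), "*")
    xyz <- sweep(pts, 2, ctr, "+")
    list(xyz = xyz, labels = anchor_truth_labels(xyz))
  })
}
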