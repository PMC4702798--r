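# ---------------------------------------------------------------------------
# Ligand chemical topology: read chemical-component-dictionary entries,
# curate atom/bond typing (dictionary-driven where possible, geometric
# perception otherwise), perceive rings and aromaticity, and apply
# rule-based protonation at physiological pH. The resulting kp_ligand
# record feeds interaction typing in the fingerprint module.
# ---------------------------------------------------------------------------

COVALENT_RADII <- c(H = 0.31, C = 0.76, N = 0.71, O = 0.66, S = 1.05,
                    P = 1.07, F = 0.57, CL = 1.02, BR = 1.20, I = 1.39,
                    B = 0.84, SE = 1.20)

cov_radius <- function(el) {
  r <- COVALENT_RADII[toupper(el)]
  r[is.na(r)] <- 1.5
  unname(r)
}

# --- minimal CIF loop reader (chem_comp_atom / chem_comp_bond only) --------
# The chemical component dictionary is distributed as CIF; no installed
# package parses its chem_comp tables, so a small reader lives here.

cif_tokens <- function(line) {
  scan(text = line, what = character(), quiet = TRUE,
       quote = "\"'", strip.white = TRUE)
}

parse_cif_loops <- function(lines, categories) {
  out <- list()
  i <- 1
  n <- length(lines)
  while (i <= n) {
    if (grepl("^\\s*loop_\\s*$", lines[i])) {
      j <- i + 1
      cols <- character(0)
      while (j <= n && grepl("^\\s*_", lines[j])) {
        cols <- c(cols, trimws(lines[j]))
        j <- j + 1
      }
      cat_name <- sub("^_([^.]+)\\..*$", "\\1", cols[1])
      rows <- list()
      while (j <= n && !grepl("^\\s*(loop_|_|#|data_)", lines[j]) &&
             nzchar(trimws(lines[j]))) {
        rows[[length(rows) + 1]] <- cif_tokens(lines[j])
        j <- j + 1
      }
      if (cat_name %in% categories && length(rows) > 0) {
        mat <- do.call(rbind, rows)
        colnames(mat) <- sub("^_[^.]+\\.", "", cols)
        df <- as_tibble(as.data.frame(mat, stringsAsFactors = FALSE))
        out[[cat_name]] <- dplyr::bind_rows(out[[cat_name]], df)
      }
      i <- j
    } else {
      i <- i + 1
    }
  }
  out
}

#' Read a chemical component dictionary
#'
#' Parses the `chem_comp_atom` and `chem_comp_bond` loops of a CIF
#' dictionary into per-component atom and bond tables.
#'
#' @param path Path to a CIF chemical component dictionary.
#' @return A `kp_ccd` object: named list of components, each with `atoms`
#'   (name, element, charge, aromatic) and `bonds` (atom_1, atom_2, order).
#' @export
read_ccd <- function(path) {
  lines <- readLines(path, warn = FALSE)
  loops <- parse_cif_loops(lines, c("chem_comp_atom", "chem_comp_bond"))
  at <- loops$chem_comp_atom
  bd <- loops$chem_comp_bond
  if (is.null(at)) stop("no chem_comp_atom loop in dictionary", call. = FALSE)
  comps <- unique(at$comp_id)
  out <- lapply(comps, function(cc) {
    a <- at[at$comp_id == cc, ]
    b <- if (!is.null(bd)) bd[bd$comp_id == cc, ] else NULL
    list(
      atoms = tibble(
        name = a$atom_id,
        element = toupper(a$type_symbol),
        charge = suppressWarnings(as.numeric(a$charge)) |>
          (\(x) ifelse(is.na(x), 0, x))(),
        aromatic = if ("pdbx_aromatic_flag" %in% names(a)) {
          a$pdbx_aromatic_flag == "Y"
        } else rep(FALSE, nrow(a))
      ),
      bonds = if (!is.null(b) && nrow(b) > 0) {
        tibble(
          atom_1 = b$atom_id_1, atom_2 = b$atom_id_2,
          order = dplyr::case_when(
            toupper(b$value_order) == "SING" ~ "1",
            toupper(b$value_order) == "DOUB" ~ "2",
            toupper(b$value_order) == "TRIP" ~ "3",
            toupper(b$value_order) == "AROM" ~ "ar",
            TRUE ~ "1"
          )
        )
      } else tibble(atom_1 = character(0), atom_2 = character(0),
                    order = character(0))
    )
  })
  names(out) <- comps
  structure(out, class = "kp_ccd")
}

# --- ring perception -------------------------------------------------------
# SSSR-style small rings: for every bond, the shortest cycle through it
# (bond removed, shortest alternative path kept). Unique rings of size <= 7.

find_rings <- function(n_atoms, bonds) {
  if (nrow(bonds) == 0) return(list())
  g <- igraph::graph_from_data_frame(
    data.frame(from = bonds$i, to = bonds$j), directed = FALSE,
    vertices = data.frame(name = seq_len(n_atoms)))
  rings <- list()
  for (k in seq_len(nrow(bonds))) {
    g2 <- igraph::delete_edges(g, k)
    sp <- suppressWarnings(igraph::shortest_paths(
      g2, from = as.character(bonds$i[k]), to = as.character(bonds$j[k])))
    path <- sp$vpath[[1]]
    if (length(path) >= 2 && length(path) <= 6) {
      ring <- sort(as.integer(igraph::as_ids(path)))
      key <- paste(ring, collapse = "-")
      rings[[key]] <- as.integer(igraph::as_ids(path))
    }
  }
  unname(rings)
}

ring_is_planar <- function(xyz, tol = 0.15) {
  if (nrow(xyz) < 4) return(TRUE)
  pf <- plane_fit(xyz)
  dev <- abs(sweep(xyz, 2, pf$centroid) %*% pf$normal)
  max(dev) <= tol
}

# --- curation --------------------------------------------------------------

perceive_bonds <- function(atoms) {
  xyz <- as.matrix(atoms[, c("x", "y", "z")])
  n <- nrow(atoms)
  if (n < 2) return(tibble(i = integer(0), j = integer(0), order = character(0)))
  d <- pdist(xyz, xyz)
  r <- cov_radius(atoms$element)
  lim <- outer(r, r, "+") * 1.25
  hits <- which(d < lim & upper.tri(d), arr.ind = TRUE)
  tibble(i = hits[, 1], j = hits[, 2], order = "1",
         length = d[hits])
}

bond_degree <- function(n, bonds) {
  tabulate(c(bonds$i, bonds$j), nbins = n)
}

neighbours_of <- function(bonds, k) {
  c(bonds$j[bonds$i == k], bonds$i[bonds$j == k])
}

#' Curate the chemical topology of a hetero group
#'
#' Builds a ligand record with curated bond orders, formal charges,
#' aromaticity and hydrogen-bond capability. When the component code has a
#' dictionary entry, bond orders and charges are taken from it (matched by
#' atom name); otherwise they are perceived from geometry (covalent-radius
#' bonds, short C-O pairs as carbonyls, planar 5/6-rings as aromatic).
#' Protonation states are then assigned by rule at physiological pH:
#' carboxylates and terminal phosphate oxygens negative, aliphatic amines
#' and amidine/guanidine nitrogens positive.
#'
#' @param group Atom tibble of one hetero group (from [hetero_groups()]) or
#'   an existing `kp_ligand` (curation is idempotent).
#' @param dictionary Optional `kp_ccd` from [read_ccd()].
#' @return A `kp_ligand`: list with `component_id`, `atoms` (name, element,
#'   x, y, z, charge, aromatic, n_h, donor, acceptor, apolar), `bonds`
#'   (i, j, order), `rings`, `protonation_applied`, `curated`.
#' @export
curate_ligand_topology <- function(group, dictionary = NULL) {
  if (inherits(group, "kp_ligand")) {
    atoms <- group$atoms[, c("name", "element", "x", "y", "z")]
    file_bonds <- group$bonds
    comp <- group$component_id
  } else if (!is.null(attr(group, "kp_bonds")) || is.data.frame(group)) {
    comp <- if ("resid" %in% names(group)) group$resid[1] else "LIG"
    atoms <- tibble(
      name = if ("name" %in% names(group)) group$name else group$elety,
      element = if ("element" %in% names(group)) toupper(group$element)
                else atom_elements(group),
      x = group$x, y = group$y, z = group$z
    )
    file_bonds <- attr(group, "kp_bonds")
  } else {
    stop("unsupported ligand input", call. = FALSE)
  }
  atoms <- atoms[atoms$element != "H", , drop = FALSE]
  n <- nrow(atoms)
  if (n < 1) stop("hetero group has no heavy atoms", call. = FALSE)

  curated <- FALSE
  dict_entry <- NULL
  if (!is.null(dictionary) && comp %in% names(dictionary)) {
    dict_entry <- dictionary[[comp]]
  }

  if (!is.null(dict_entry)) {
    dheavy <- dict_entry$atoms[dict_entry$atoms$element != "H", ]
    if (all(atoms$name %in% dheavy$name)) {
      m <- match(atoms$name, dheavy$name)
      charge <- dheavy$charge[m]
      arom_flag <- dheavy$aromatic[m]
      db <- dict_entry$bonds
      bi <- match(db$atom_1, atoms$name)
      bj <- match(db$atom_2, atoms$name)
      keep <- !is.na(bi) & !is.na(bj)
      bonds <- tibble(i = bi[keep], j = bj[keep], order = db$order[keep])
      # was anything in the file wrong? compare against naive perception
      geo <- perceive_bonds(atoms)
      curated <- !identical(
        sort(paste(pmin(bonds$i, bonds$j), pmax(bonds$i, bonds$j))),
        sort(paste(pmin(geo$i, geo$j), pmax(geo$i, geo$j)))) ||
        any(bonds$order != "1") || any(charge != 0)
    } else {
      warning("atom names do not match dictionary entry for ", comp,
              "; falling back to geometric perception", call. = FALSE)
      dict_entry <- NULL
    }
  }

  if (is.null(dict_entry)) {
    if (!is.null(file_bonds) && nrow(file_bonds) > 0) {
      bonds <- tibble(i = as.integer(file_bonds$i),
                      j = as.integer(file_bonds$j),
                      order = as.character(file_bonds$order))
    } else {
      bonds <- perceive_bonds(atoms)[, c("i", "j", "order")]
      curated <- TRUE
    }
    charge <- rep(0, n)
    arom_flag <- rep(FALSE, n)
    xyz <- as.matrix(atoms[, c("x", "y", "z")])
    # short C=O perception
    for (k in seq_len(nrow(bonds))) {
      els <- atoms$element[c(bonds$i[k], bonds$j[k])]
      if (setequal(els, c("C", "O")) && bonds$order[k] == "1") {
        d <- vnorm(xyz[bonds$i[k], ] - xyz[bonds$j[k], ])
        odeg <- bond_degree(n, bonds)[c(bonds$i[k], bonds$j[k])[els == "O"]]
        if (d < 1.28 && odeg == 1) {
          bonds$order[k] <- "2"
          curated <- TRUE
        }
      }
    }
    # aromatic perception on planar small rings of C/N/S/O
    rings <- find_rings(n, bonds)
    for (ring in rings) {
      if (!length(ring) %in% c(5L, 6L)) next
      if (!all(atoms$element[ring] %in% c("C", "N", "S", "O"))) next
      in_ring <- bonds$i %in% ring & bonds$j %in% ring
      mean_len <- mean(sqrt(rowSums(
        (xyz[bonds$i[in_ring], , drop = FALSE] -
           xyz[bonds$j[in_ring], , drop = FALSE])^2)))
      if (ring_is_planar(xyz[ring, , drop = FALSE]) && mean_len <= 1.46) {
        if (any(bonds$order[in_ring] != "ar")) curated <- TRUE
        bonds$order[in_ring] <- "ar"
        arom_flag[ring] <- TRUE
      }
    }
  }

  arom_flag <- arom_flag |
    seq_len(n) %in% unique(c(bonds$i[bonds$order == "ar"],
                             bonds$j[bonds$order == "ar"]))

  # ---- protonation rules at pH 7.4 ----------------------------------------
  deg <- bond_degree(n, bonds)
  for (k in which(atoms$element == "C")) {
    nb <- neighbours_of(bonds, k)
    os <- nb[atoms$element[nb] == "O" & deg[nb] == 1]
    if (length(os) == 2) {
      # carboxylate: one C=O, the other O deprotonated
      bk <- which((bonds$i == k & bonds$j %in% os) |
                    (bonds$j == k & bonds$i %in% os))
      if (!any(bonds$order[bk] == "2")) {
        bonds$order[bk[1]] <- "2"
        curated <- TRUE
      }
      dbl_o <- setdiff(c(bonds$i[bk], bonds$j[bk])[
        bonds$order[bk] == "2"], k)[1]
      anion <- setdiff(os, dbl_o)
      if (length(anion) >= 1 && any(charge[anion] != -1)) {
        charge[anion] <- -1
        curated <- TRUE
      }
    }
    # amidine / guanidine: protonated at the sp2 nitrogen
    ns <- nb[atoms$element[nb] == "N" & !arom_flag[nb]]
    if (length(ns) >= 2) {
      bk <- which((bonds$i == k & bonds$j %in% ns) |
                    (bonds$j == k & bonds$i %in% ns))
      dbl <- bk[bonds$order[bk] == "2"]
      if (length(dbl) >= 1) {
        nplus <- setdiff(c(bonds$i[dbl[1]], bonds$j[dbl[1]]), k)
        if (charge[nplus] != 1) { charge[nplus] <- 1; curated <- TRUE }
      }
    }
  }
  for (k in which(atoms$element == "N")) {
    nb <- neighbours_of(bonds, k)
    bk <- which(bonds$i == k | bonds$j == k)
    all_single <- all(bonds$order[bk] == "1")
    amide <- any(vapply(nb[atoms$element[nb] == "C"], function(cc) {
      cb <- which((bonds$i == cc | bonds$j == cc) & bonds$order == "2")
      any(atoms$element[setdiff(c(bonds$i[cb], bonds$j[cb]), cc)] == "O")
    }, logical(1)))
    if (all_single && !arom_flag[k] && !amide && deg[k] <= 3 &&
        all(atoms$element[nb] == "C") && length(nb) >= 1) {
      if (charge[k] != 1) { charge[k] <- 1; curated <- TRUE }
    }
  }
  for (k in which(atoms$element == "P")) {
    nb <- neighbours_of(bonds, k)
    term_o <- nb[atoms$element[nb] == "O" & deg[nb] == 1]
    if (length(term_o) >= 2) {
      anions <- utils::head(sort(term_o), 2)
      if (any(charge[anions] != -1)) { charge[anions] <- -1; curated <- TRUE }
    }
  }

  # ---- derived typing ------------------------------------------------------
  ord_num <- ifelse(bonds$order == "ar", 1.5,
                    suppressWarnings(as.numeric(bonds$order)))
  bsum <- vapply(seq_len(n), function(k) {
    sum(ord_num[bonds$i == k | bonds$j == k])
  }, numeric(1))
  target <- dplyr::case_when(
    atoms$element == "C" ~ 4, atoms$element == "N" ~ 3 + pmax(charge, 0),
    atoms$element == "O" ~ 2 + pmin(charge, 0),
    atoms$element == "S" ~ 2, atoms$element == "P" ~ 5,
    TRUE ~ 1
  )
  n_h <- pmax(0, round(target - bsum))
  nb_el <- function(k) atoms$element[neighbours_of(bonds, k)]
  donor <- (atoms$element %in% c("N", "O")) & n_h >= 1 & charge >= 0 |
    (atoms$element == "N" & charge > 0)
  acceptor <- (atoms$element == "O") |
    (atoms$element == "N" & n_h == 0 & charge <= 0)
  apolar <- (atoms$element == "C" &
               vapply(seq_len(n), function(k) !any(nb_el(k) %in% c("N", "O")),
                      logical(1))) |
    (atoms$element == "S" & charge == 0)

  rings <- find_rings(n, bonds)
  arom_rings <- Filter(function(r) all(arom_flag[r]) &&
                         length(r) %in% c(5L, 6L), rings)

  structure(list(
    component_id = comp,
    atoms = dplyr::bind_cols(atoms, tibble(
      charge = charge, aromatic = arom_flag, n_h = n_h,
      donor = donor, acceptor = acceptor, apolar = apolar)),
    bonds = bonds[, c("i", "j", "order")],
    rings = rings, aromatic_rings = arom_rings,
    protonation_applied = TRUE, curated = curated
  ), class = "kp_ligand")
}

#' @export
print.kp_ligand <- function(x, ...) {
  cat(sprintf("<kp_ligand> %s: %d heavy atoms, %d bonds, %d rings (%d aromatic)%s\n",
              x$component_id, nrow(x$atoms), nrow(x$bonds), length(x$rings),
              length(x$aromatic_rings),
              if (x$curated) " [topology corrected]" else ""))
  invisible(x)
}

#' @export
tidy.kp_ligand <- function(x, ...) x$atoms

ligand_xyz <- function(lig) as.matrix(lig$atoms[, c("x", "y", "z")])

# rigidly transform a ligand record
transform_ligand <- function(lig, rotation, translation) {
  xyz <- apply_rigid(ligand_xyz(lig), rotation, translation)
  lig$atoms$x <- xyz[, 1]; lig$atoms$y <- xyz[, 2]; lig$atoms$z <- xyz[, 3]
  lig
}

#' Ligand physicochemical descriptors
#'
#' Molecular weight (implicit hydrogens included), a Crippen-type
#' atomic-contribution logP estimate, H-bond donor/acceptor counts,
#' rotatable bonds and heavy-atom count.
#'
#' @param lig A `kp_ligand`.
#' @return One-row tibble with `mw`, `logp`, `hbd`, `hba`, `rotatable`,
#'   `heavy_atoms`.
#' @export
ligand_descriptors <- function(lig) {
  masses <- c(C = 12.011, N = 14.007, O = 15.999, S = 32.06, P = 30.974,
              F = 18.998, CL = 35.45, BR = 79.904, I = 126.904, B = 10.81)
  m <- masses[lig$atoms$element]
  m[is.na(m)] <- 40
  mw <- sum(m) + 1.008 * sum(lig$atoms$n_h)
  # atomic contributions, Crippen-style coarse classes
  contrib <- dplyr::case_when(
    lig$atoms$element == "C" & lig$atoms$aromatic ~ 0.29,
    lig$atoms$element == "C" & lig$atoms$apolar ~ 0.14,
    lig$atoms$element == "C" ~ -0.03,
    lig$atoms$element == "N" & lig$atoms$charge > 0 ~ -1.0,
    lig$atoms$element == "N" ~ -0.60,
    lig$atoms$element == "O" & lig$atoms$charge < 0 ~ -1.2,
    lig$atoms$element == "O" ~ -0.40,
    lig$atoms$element == "S" ~ 0.25,
    lig$atoms$element %in% c("CL", "BR", "I") ~ 0.65,
    lig$atoms$element == "F" ~ 0.20,
    TRUE ~ 0
  )
  deg <- bond_degree(nrow(lig$atoms), lig$bonds)
  in_ring <- seq_len(nrow(lig$atoms)) %in% unlist(lig$rings)
  rot <- sum(vapply(seq_len(nrow(lig$bonds)), function(k) {
    i <- lig$bonds$i[k]; j <- lig$bonds$j[k]
    lig$bonds$order[k] == "1" && deg[i] > 1 && deg[j] > 1 &&
      !(i %in% unlist(lig$rings) && j %in% unlist(lig$rings) &&
          any(vapply(lig$rings, function(r) all(c(i, j) %in% r), logical(1))))
  }, logical(1)))
  tibble(mw = mw, logp = sum(contrib), hbd = sum(lig$atoms$donor),
         hba = sum(lig$atoms$acceptor), rotatable = rot,
         heavy_atoms = nrow(lig$atoms))
}
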