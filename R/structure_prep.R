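# ---------------------------------------------------------------------------
# Structure preparation: read PDB/mmCIF entries, split them into single
# model/single chain monomers, resolve alternate locations, and classify
# hetero groups into waters / ions / cofactors / organometallics / ligands.
# ---------------------------------------------------------------------------

WATER_CODES <- c("HOH", "DOD", "WAT")
METALS <- c("LI", "NA", "K", "RB", "CS", "MG", "CA", "SR", "BA", "MN",
            "FE", "CO", "NI", "CU", "ZN", "CD", "HG", "AL", "PT", "PD",
            "RU", "W", "MO", "V")
HALIDES <- c("F", "CL", "BR", "I")

#' Default cofactor component codes
#'
#' Nucleotide and redox cofactors routed to the `cofactors` entity category
#' rather than being treated as ligands. Configurable: pass your own vector
#' to [classify_entities()].
#' @return Character vector of chemical component codes.
#' @export
default_cofactors <- function() {
  c("ATP", "ADP", "AMP", "ANP", "AGS", "ACP", "ADN", "GTP", "GDP", "GNP",
    "NAD", "NAP", "NDP", "FAD", "FMN", "SAM", "SAH", "COA", "TPP", "PLP")
}

#' Filter homology-search hits
#'
#' Applies the entry-selection rule used when collecting kinase structures:
#' a hit is accepted iff its sequence identity is at least 70 percent and
#' its e-value is at most 0.001 (both boundaries inclusive).
#'
#' @param hits Data frame with numeric columns `identity` (percent, 0-100)
#'   and `e_value`.
#' @param min_identity,max_evalue Acceptance thresholds.
#' @return Integer vector of accepted row indices.
#' @export
#' @examples
#' filter_homolog_hits(data.frame(identity = c(70, 69.9), e_value = c(1e-3, 1e-50)))
filter_homolog_hits <- function(hits, min_identity = 70, max_evalue = 0.001) {
  stopifnot(is.data.frame(hits), all(c("identity", "e_value") %in% names(hits)))
  if (any(hits$e_value < 0)) stop("negative e-value", call. = FALSE)
  if (any(hits$identity < 0 | hits$identity > 100)) {
    stop("identity must be a percentage in [0, 100]", call. = FALSE)
  }
  which(hits$identity >= min_identity & hits$e_value <= max_evalue)
}

new_monomer <- function(source_id, model_index, chain_id, atoms, hetero) {
  structure(
    list(source_id = source_id, model_index = as.integer(model_index),
         chain_id = chain_id, atoms = atoms, hetero = hetero),
    class = "kp_monomer"
  )
}

#' @export
print.kp_monomer <- function(x, ...) {
  cat(sprintf(
    "<kp_monomer> %s model %d chain %s: %d protein atoms (%d residues), %d hetero groups\n",
    x$source_id, x$model_index, x$chain_id, nrow(x$atoms),
    dplyr::n_distinct(x$atoms$resno), length(hetero_groups(x))))
  invisible(x)
}

#' Hetero groups of a monomer
#'
#' @param monomer A `kp_monomer`.
#' @return Named list of atom tibbles, one per hetero residue group, named
#'   `"<resid>_<resno>"`.
#' @export
hetero_groups <- function(monomer) {
  het <- monomer$hetero
  if (is.null(het) || nrow(het) == 0) return(list())
  key <- paste(het$resid, het$resno, sep = "_")
  split(het, factor(key, levels = unique(key)))
}

# keep the highest-occupancy alt-loc per (resno, atom name); ties resolved
# alphabetically by alt-loc code
resolve_altlocs <- function(atoms) {
  atoms |>
    dplyr::mutate(alt = dplyr::coalesce(.data$alt, ""),
                  o = dplyr::coalesce(.data$o, 1)) |>
    dplyr::group_by(.data$resno, .data$resid, .data$elety) |>
    dplyr::arrange(dplyr::desc(.data$o), .data$alt, .by_group = TRUE) |>
    dplyr::slice(1) |>
    dplyr::ungroup() |>
    dplyr::arrange(.data$eleno)
}

read_structure_file <- function(path) {
  ext <- tolower(tools::file_ext(path))
  parsed <- tryCatch({
    if (ext %in% c("cif", "mmcif")) {
      bio3d::read.cif(path, rm.alt = FALSE)
    } else {
      bio3d::read.pdb(path, multi = TRUE, rm.alt = FALSE)
    }
  }, error = function(e) {
    stop("could not parse structure file '", path, "': ", conditionMessage(e),
         call. = FALSE)
  })
  parsed
}

#' Split a structure entry into monomers
#'
#' Reads a PDB or mmCIF file and produces one monomer per (model, chain)
#' pair. Hetero groups stay attached to the chain they are assigned to in
#' the file; alternate locations are resolved by keeping the
#' highest-occupancy conformer (ties: alphabetically first alt-loc code).
#'
#' @param path Path to a PDB (`.pdb`) or mmCIF (`.cif`) file.
#' @param source_id Entry identifier; defaults to the file base name.
#' @return List of `kp_monomer` objects.
#' @export
split_entry <- function(path, source_id = NULL) {
  pdb <- read_structure_file(path)
  if (is.null(source_id)) {
    source_id <- toupper(tools::file_path_sans_ext(basename(path)))
  }
  atom <- as_tibble(pdb$atom)
  atom$eleno <- as.integer(atom$eleno)
  atom$resno <- as.integer(atom$resno)
  n_models <- max(1L, nrow(pdb$xyz))
  is_protein <- atom$type == "ATOM" & atom$resid %in% names(aa1)
  if (!any(is_protein)) stop("no protein chains in entry", call. = FALSE)
  chains <- unique(atom$chain[is_protein])

  out <- list()
  for (m in seq_len(n_models)) {
    xyz <- matrix(pdb$xyz[m, ], ncol = 3, byrow = TRUE)
    atm <- atom
    atm$x <- xyz[, 1]; atm$y <- xyz[, 2]; atm$z <- xyz[, 3]
    if (any(!is.finite(xyz))) stop("non-finite coordinates", call. = FALSE)
    for (ch in chains) {
      sel <- atm$chain == ch | is.na(atm$chain) & length(chains) == 1L
      sub <- atm[sel & !is.na(sel), ]
      prot <- resolve_altlocs(sub[sub$type == "ATOM" &
                                    sub$resid %in% names(aa1), ])
      het <- resolve_altlocs(sub[sub$type == "HETATM", ])
      if (nrow(prot) == 0) next
      out[[length(out) + 1]] <- new_monomer(
        source_id, m, ch,
        dplyr::select(prot, dplyr::any_of(c(
          "eleno", "elety", "resid", "chain", "resno", "x", "y", "z",
          "o", "b", "elesy", "type"))),
        dplyr::select(het, dplyr::any_of(c(
          "eleno", "elety", "resid", "chain", "resno", "x", "y", "z",
          "o", "b", "elesy", "type")))
      )
    }
  }
  if (length(out) == 0) stop("no protein chains in entry", call. = FALSE)
  out
}

# element of a hetero atom: prefer the element symbol column, fall back to
# the first alphabetic character of the atom name
atom_elements <- function(atoms) {
  el <- toupper(atoms$elesy %||% rep(NA_character_, nrow(atoms)))
  miss <- is.na(el) | el == ""
  nm <- toupper(gsub("[^A-Za-z].*$", "", atoms$elety[miss]))
  two <- nm %in% c(METALS, "BR", "CL")
  el[miss] <- ifelse(two, nm, substr(nm, 1, 1))
  el
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Classify the entities of a monomer
#'
#' Partitions every hetero group into exactly one category by a fixed rule
#' order: water (HOH/DOD/WAT), ion (single-atom metal or halide), cofactor
#' (component code on `cofactors`), organometallic (contains both a metal
#' and carbon), else ligand. Ligands with at least one heavy atom within
#' `contact_distance` of a heavy atom of any front-cleft, gate-area or
#' back-cleft pocket residue are orthosteric (the best-contacting group when
#' several qualify); remaining ligands are allosteric.
#'
#' @param monomer A `kp_monomer`.
#' @param pocket A `kp_pocket` from [extract_pocket()], used for the
#'   orthosteric contact test. May be `NULL`, in which case every ligand is
#'   reported allosteric.
#' @param cofactors Character vector of cofactor component codes.
#' @param contact_distance Heavy-atom contact cutoff in Angstrom.
#' @return A `kp_entities` list with elements `protein`, `orthosteric_ligand`
#'   (atom tibble or `NULL`), `allosteric_ligands`, `waters`, `ions`,
#'   `cofactors`, `organometallics`, and a summary tibble `manifest`.
#' @export
classify_entities <- function(monomer, pocket = NULL,
                              cofactors = default_cofactors(),
                              contact_distance = 4.0) {
  groups <- hetero_groups(monomer)
  cats <- character(length(groups))
  for (i in seq_along(groups)) {
    g <- groups[[i]]
    el <- atom_elements(g)
    heavy <- el != "H"
    code <- g$resid[1]
    cats[i] <- if (code %in% WATER_CODES) {
      "water"
    } else if (sum(heavy) == 1 && el[heavy] %in% c(METALS, HALIDES)) {
      "ion"
    } else if (code %in% cofactors) {
      "cofactor"
    } else if (any(el %in% METALS) && any(el == "C")) {
      "organometallic"
    } else {
      "ligand"
    }
  }

  lig_idx <- which(cats == "ligand")
  ortho <- NULL
  ortho_key <- NA_character_
  if (length(lig_idx) > 0 && !is.null(pocket)) {
    pocket_xyz <- pocket_region_xyz(pocket)
    n_contacts <- vapply(lig_idx, function(i) {
      g <- groups[[i]]
      heavy <- atom_elements(g) != "H"
      if (nrow(pocket_xyz) == 0 || !any(heavy)) return(0L)
      d <- min_dist(as.matrix(g[heavy, c("x", "y", "z")]), pocket_xyz)
      sum(d <= contact_distance)
    }, integer(1))
    if (any(n_contacts > 0)) {
      best <- lig_idx[which.max(n_contacts)]
      ortho <- groups[[best]]
      ortho_key <- names(groups)[best]
    }
  }

  allo <- groups[setdiff(lig_idx, match(ortho_key, names(groups)))]
  manifest <- tibble(
    group = names(groups) %||% character(0),
    component = vapply(groups, function(g) g$resid[1], character(1)),
    category = dplyr::if_else(names(groups) %in% ortho_key,
                              "orthosteric_ligand",
                              dplyr::if_else(cats == "ligand" &
                                               names(groups) %in% names(allo),
                                             "allosteric_ligand", cats)),
    n_atoms = vapply(groups, nrow, integer(1))
  )
  structure(list(
    protein = monomer$atoms,
    orthosteric_ligand = ortho,
    allosteric_ligands = unname(allo),
    waters = unname(groups[cats == "water"]),
    ions = unname(groups[cats == "ion"]),
    cofactors = unname(groups[cats == "cofactor"]),
    organometallics = unname(groups[cats == "organometallic"]),
    manifest = manifest
  ), class = "kp_entities")
}

# heavy-atom coordinates of pocket residues lining the three major regions
pocket_region_xyz <- function(pocket,
                              majors = c("front_cleft", "gate_area",
                                         "back_cleft")) {
  map <- major_region_map()
  regs <- map$region[map$major %in% majors]
  slots <- kp_regions()$index[kp_regions()$region %in% regs]
  at <- pocket$atoms
  el <- atom_elements(at)
  keep <- at$slot %in% slots & el != "H"
  as.matrix(at[keep & !is.na(keep), c("x", "y", "z")])
}

# which kinase regions line which major pocket; configurable by rebuild
major_region_map <- function() {
  tibble(
    region = c("I", "g.l", "II", "hinge", "linker", "aD",
               "V", "GK", "VIII", "xDFG", "c.l",
               "III", "aC", "b.l", "IV"),
    major = c(rep("front_cleft", 6), rep("gate_area", 5),
              rep("back_cleft", 4))
  )
}

#' @export
print.kp_entities <- function(x, ...) {
  cat("<kp_entities>\n")
  print(x$manifest)
  invisible(x)
}

#' Write a monomer to disk
#'
#' Writes the protein as PDB, each hetero group (and the pocket, if given)
#' as MOL2, plus an entity manifest CSV.
#'
#' @param monomer A `kp_monomer`.
#' @param dir Output directory (created if needed).
#' @param entities Optional `kp_entities` for the manifest.
#' @return Invisibly, the paths written.
#' @export
write_monomer <- function(monomer, dir, entities = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  prot_file <- file.path(dir, sprintf("%s_%d%s_protein.pdb",
                                      monomer$source_id,
                                      monomer$model_index, monomer$chain_id))
  write_atoms_pdb(monomer$atoms, monomer$hetero, prot_file,
                  chain = monomer$chain_id)
  paths <- c(paths, prot_file)
  for (nm in names(hetero_groups(monomer))) {
    g <- hetero_groups(monomer)[[nm]]
    f <- file.path(dir, sprintf("%s_%d%s_%s.mol2", monomer$source_id,
                                monomer$model_index, monomer$chain_id, nm))
    write_mol2(atoms_to_mol2_tbl(g), bonds = NULL, file = f, name = nm)
    paths <- c(paths, f)
  }
  if (!is.null(entities)) {
    f <- file.path(dir, "entities.csv")
    readr::write_csv(entities$manifest, f)
    paths <- c(paths, f)
  }
  invisible(paths)
}

write_atoms_pdb <- function(atoms, hetero, file, chain = "A") {
  all_at <- dplyr::bind_rows(
    dplyr::mutate(atoms, type = "ATOM"),
    if (!is.null(hetero) && nrow(hetero) > 0) {
      dplyr::mutate(hetero, type = "HETATM")
    }
  )
  xyz <- as.numeric(t(as.matrix(all_at[, c("x", "y", "z")])))
  bio3d::write.pdb(
    file = file, xyz = xyz,
    type = all_at$type,
    resno = all_at$resno, resid = all_at$resid,
    eleno = seq_len(nrow(all_at)), elety = all_at$elety,
    chain = if ("chain" %in% names(all_at)) {
      dplyr::coalesce(all_at$chain, chain)
    } else rep(chain, nrow(all_at)),
    o = rep(1, nrow(all_at)), b = rep(0, nrow(all_at))
  )
}

atoms_to_mol2_tbl <- function(g) {
  tibble(
    name = g$elety, element = atom_elements(g),
    x = g$x, y = g$y, z = g$z,
    charge = 0, aromatic = FALSE,
    resid = g$resid, resno = g$resno
  )
}

# minimal TRIPOS MOL2 writer for ligand/pocket/probe point sets
sybyl_type <- function(element, aromatic = FALSE) {
  dplyr::case_when(
    element == "C" & aromatic ~ "C.ar",
    element == "C" ~ "C.3",
    element == "N" & aromatic ~ "N.ar",
    element == "N" ~ "N.3",
    element == "O" ~ "O.3",
    element == "S" ~ "S.3",
    element == "P" ~ "P.3",
    element == "H" ~ "H",
    TRUE ~ element
  )
}

write_mol2 <- function(atoms, bonds = NULL, file, name = "MOL") {
  n_b <- if (is.null(bonds)) 0L else nrow(bonds)
  lines <- c(
    "@<TRIPOS>MOLECULE", name,
    sprintf("%d %d 1 0 0", nrow(atoms), n_b),
    "SMALL", "USER_CHARGES", "", "@<TRIPOS>ATOM"
  )
  resid <- if ("resid" %in% names(atoms)) atoms$resid else rep(name, nrow(atoms))
  resno <- if ("resno" %in% names(atoms)) atoms$resno else rep(1L, nrow(atoms))
  charge <- if ("charge" %in% names(atoms)) atoms$charge else rep(0, nrow(atoms))
  arom <- if ("aromatic" %in% names(atoms)) atoms$aromatic else rep(FALSE, nrow(atoms))
  lines <- c(lines, sprintf(
    "%7d %-8s %9.4f %9.4f %9.4f %-7s %5d %-8s %9.4f",
    seq_len(nrow(atoms)), atoms$name, atoms$x, atoms$y, atoms$z,
    sybyl_type(atoms$element, arom), resno, resid, charge))
  if (n_b > 0) {
    ord <- as.character(bonds$order)
    lines <- c(lines, "@<TRIPOS>BOND",
               sprintf("%6d %5d %5d %4s", seq_len(n_b),
                       bonds$i, bonds$j, ord))
  }
  writeLines(lines, file)
  invisible(file)
}

read_mol2_atoms <- function(file) {
  m <- suppressWarnings(bio3d::read.mol2(file))
  at <- as_tibble(m$atom)
  tibble(
    name = at$elena, element = toupper(sub("\\..*$", "", at$elety)),
    x = as.numeric(at$x), y = as.numeric(at$y), z = as.numeric(at$z),
    charge = as.numeric(at$charge),
    aromatic = grepl("\\.ar$", at$elety),
    resid = at$resid, resno = as.integer(at$resno)
  )
}

read_mol2_bonds <- function(file) {
  m <- suppressWarnings(bio3d::read.mol2(file))
  if (is.null(m$bond) || nrow(m$bond) == 0) {
    return(tibble(i = integer(0), j = integer(0), order = character(0)))
  }
  b <- as_tibble(m$bond)
  tibble(i = as.integer(b$origin), j = as.integer(b$target),
         order = as.character(b$type))
}
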