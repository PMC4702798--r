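# ---------------------------------------------------------------------------
# End-to-end annotation: one processed monomer becomes an AnnotationRecord,
# the searchable unit holding the pocket alignment, fingerprint,
# conformation classes, subpocket flags, water assignments, quality score
# and ligand descriptors.
# ---------------------------------------------------------------------------

#' Annotate a monomer end-to-end
#'
#' Runs the full pipeline: pocket extraction, superposition onto the master
#' frame, entity classification, ligand curation, interaction
#' fingerprinting, conformation classification, subpocket and water-cluster
#' assignment, and the quality score.
#'
#' @param monomer A `kp_monomer`.
#' @param ligand Optional pre-curated `kp_ligand` (e.g. from
#'   [fixture_ligand()] or a MOL2 file); if `NULL` the orthosteric hetero
#'   group is curated with `dictionary`.
#' @param dictionary Optional `kp_ccd`.
#' @param metadata Named list merged into the record identifiers (e.g.
#'   `kinase`, `family`, `group`, `species`, `resolution`).
#' @param subpocket_model Optional `kp_subpocket_model`.
#' @param water_clusters A `kp_water_clusters`.
#' @param dfg_tree DFG model.
#' @return A `kp_record`.
#' @export
annotate_structure <- function(monomer, ligand = NULL, dictionary = NULL,
                               metadata = list(),
                               subpocket_model = NULL,
                               water_clusters = load_water_clusters(),
                               dfg_tree = load_dfg_tree()) {
  pocket <- extract_pocket(NULL, monomer)
  sp <- superpose(pocket)
  pocket_m <- pocket
  pocket_m$atoms <- transform_atoms(pocket$atoms, sp)
  entities <- classify_entities(monomer, pocket)

  if (is.null(ligand) && !is.null(entities$orthosteric_ligand)) {
    ligand <- curate_ligand_topology(entities$orthosteric_ligand, dictionary)
  }
  lig_m <- if (!is.null(ligand)) {
    transform_ligand(ligand, sp$rotation, sp$translation)
  }

  ifp <- compute_ifp(pocket_m, lig_m)
  conf <- annotate_conformation(pocket_m, tree = dfg_tree)
  sub <- if (!is.null(subpocket_model) && !is.null(lig_m)) {
    assign_subpockets(lig_m, subpocket_model)
  }
  wat <- {
    wgroups <- entities$waters
    if (length(wgroups) > 0) {
      wxyz <- do.call(rbind, lapply(wgroups, function(g) {
        as.matrix(g[atom_elements(g) == "O", c("x", "y", "z")])
      }))
      assign_water_clusters(apply_rigid(wxyz, sp$rotation, sp$translation),
                            water_clusters, pocket = pocket_m, lig = lig_m)
    }
  }
  quality <- compute_quality_score(
    sp$rmsd_anchor, sp$rmsd_pocket,
    n_missing_residues = sum(pocket$slots$gap),
    n_missing_atoms = sum(lengths(pocket$slots$missing_atoms)))

  structure(list(
    ids = utils::modifyList(
      list(entry_id = paste0(monomer$source_id, "_", monomer$model_index,
                             monomer$chain_id),
           kinase = monomer$source_id, family = NA_character_,
           group = NA_character_, species = NA_character_,
           resolution = NA_real_),
      metadata),
    pocket = pocket_m, superposition = sp, entities = entities,
    ligand = lig_m, ifp = ifp, conformation = conf,
    subpockets = sub, waters = wat, quality = quality,
    ligand_descriptors = if (!is.null(lig_m)) ligand_descriptors(lig_m)
  ), class = "kp_record")
}

#' @export
print.kp_record <- function(x, ...) {
  cat(sprintf("<kp_record> %s: %s/%s, quality %.1f, %d IFP bits%s\n",
              x$ids$entry_id, x$conformation$dfg, x$conformation$alpha_c,
              x$quality$score, sum(x$ifp),
              if (is.null(x$ligand)) " [apo]" else ""))
  invisible(x)
}

#' One-row tabular view of a record
#'
#' @param x A `kp_record`.
#' @param ... Ignored.
#' @return One-row tibble with identifiers, conformation classes, quality,
#'   RMSDs, gap/mutation counts, ligand descriptors, flagged subpockets and
#'   occupied water clusters (semicolon-joined), and the fingerprint as hex.
#' @export
tidy.kp_record <- function(x, ...) {
  base <- tibble(
    entry_id = x$ids$entry_id, kinase = x$ids$kinase,
    family = x$ids$family, group = x$ids$group, species = x$ids$species,
    resolution = x$ids$resolution,
    dfg = x$conformation$dfg, alpha_c = x$conformation$alpha_c,
    gloop_angle = x$conformation$gloop[["angle"]],
    gloop_distance = x$conformation$gloop[["distance"]],
    gloop_rotation = x$conformation$gloop[["rotation"]],
    quality = x$quality$score,
    rmsd_anchor = x$superposition$rmsd_anchor,
    rmsd_pocket = x$superposition$rmsd_pocket,
    n_gaps = sum(x$pocket$slots$gap),
    n_missing_atoms = sum(lengths(x$pocket$slots[["missing_atoms"]] %||%
                                    list())),
    apo = is.null(x$ligand),
    subpockets = if (is.null(x$subpockets)) "" else
      paste(x$subpockets$label[x$subpockets$flag], collapse = ";"),
    water_clusters = if (is.null(x$waters) || nrow(x$waters) == 0) "" else
      paste(sort(unique(x$waters$cluster)), collapse = ";"),
    ifp_hex = ifp_to_hex(x$ifp)
  )
  if (!is.null(x$ligand_descriptors)) {
    base <- dplyr::bind_cols(base, x$ligand_descriptors)
  }
  base
}

#' @export
glance.kp_record <- function(x, ...) {
  tibble(entry_id = x$ids$entry_id, quality = x$quality$score,
         dfg = x$conformation$dfg, alpha_c = x$conformation$alpha_c,
         n_ifp_bits = sum(x$ifp))
}

#' Write an annotation record to a collection directory
#'
#' Serialises the searchable content of a record as JSON (pocket sequence,
#' conformation, quality, fingerprint hex, subpocket flags, water
#' assignments, ligand descriptors) plus a MOL2 of the superposed ligand.
#' [read_record_json()] restores a query-ready record; the full ligand
#' graph is not restored, so chemical-similarity clauses are unavailable on
#' reloaded records.
#'
#' @param record A `kp_record`.
#' @param dir Collection directory.
#' @return Invisibly, the JSON path.
#' @export
write_record_json <- function(record, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  base <- file.path(dir, record$ids$entry_id)
  obj <- list(
    ids = record$ids,
    pocket_aa = paste(record$pocket$slots$aa, collapse = ""),
    gaps = which(record$pocket$slots$gap),
    dfg = record$conformation$dfg,
    alpha_c = record$conformation$alpha_c,
    gloop = as.list(record$conformation$gloop),
    quality = record$quality$score,
    rmsd_anchor = record$superposition$rmsd_anchor,
    rmsd_pocket = record$superposition$rmsd_pocket,
    ifp_hex = ifp_to_hex(record$ifp),
    apo = is.null(record$ligand),
    subpockets = if (!is.null(record$subpockets)) {
      record$subpockets$label[record$subpockets$flag]
    } else character(0),
    waters = if (!is.null(record$waters)) record$waters$cluster else
      character(0),
    ligand_descriptors = record$ligand_descriptors
  )
  jsonlite::write_json(obj, paste0(base, ".json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  if (!is.null(record$ligand)) {
    write_mol2(record$ligand$atoms |>
                 dplyr::mutate(resid = record$ligand$component_id),
               record$ligand$bonds, paste0(base, "_ligand.mol2"),
               name = record$ligand$component_id)
  }
  invisible(paste0(base, ".json"))
}

#' @rdname write_record_json
#' @param path Path to a record JSON file.
#' @export
read_record_json <- function(path) {
  obj <- jsonlite::fromJSON(path)
  labs <- subpocket_labels()
  aa <- strsplit(obj$pocket_aa, "")[[1]]
  id_fields <- c("entry_id", "kinase", "family", "group", "species")
  ids <- lapply(id_fields, function(f) obj$ids[[f]] %||% NA_character_)
  names(ids) <- id_fields
  ids$resolution <- obj$ids$resolution %||% NA_real_
  structure(list(
    ids = ids,
    pocket = list(slots = tibble(index = 1:85, aa = aa,
                                 gap = 1:85 %in% obj$gaps)),
    conformation = list(dfg = obj$dfg, alpha_c = obj$alpha_c,
                        gloop = unlist(obj$gloop)),
    superposition = list(rmsd_anchor = obj$rmsd_anchor,
                         rmsd_pocket = obj$rmsd_pocket),
    quality = list(score = obj$quality),
    ifp = ifp_from_hex(obj$ifp_hex),
    subpockets = tibble(label = labs$label, parent = labs$parent,
                        flag = labs$label %in% unlist(obj$subpockets)),
    waters = if (length(obj$waters) > 0) {
      tibble(cluster = unlist(obj$waters))
    },
    ligand = NULL,
    ligand_descriptors = if (!is.null(obj$ligand_descriptors)) {
      as_tibble(obj$ligand_descriptors)
    }
  ), class = "kp_record")
}

#' Build a record collection
#'
#' @param records List of `kp_record` objects.
#' @return A `kp_collection` (list with a tabular cache).
#' @export
kp_collection <- function(records) {
  stopifnot(all(vapply(records, inherits, logical(1), "kp_record")))
  names(records) <- vapply(records, function(r) r$ids$entry_id, character(1))
  structure(records, class = "kp_collection")
}

#' @export
print.kp_collection <- function(x, ...) {
  cat(sprintf("<kp_collection> %d records\n", length(x)))
  invisible(x)
}

#' @export
tidy.kp_collection <- function(x, ...) {
  purrr::map_dfr(x, tidy.kp_record)
}

#' Quality-score overview plot for a collection
#'
#' @param object A `kp_collection`.
#' @param ... Ignored.
#' @return A ggplot histogram of quality scores coloured by DFG class.
#' @export
autoplot.kp_collection <- function(object, ...) {
  df <- tidy.kp_collection(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$quality, fill = .data$dfg)) +
    ggplot2::geom_histogram(binwidth = 0.5, boundary = 0) +
    ggplot2::labs(x = "quality score (0-10)", y = "structures",
                  fill = "DFG") +
    ggplot2::theme_minimal()
}
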