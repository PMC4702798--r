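# ---------------------------------------------------------------------------
# Probe-grid subpocket model: a 0.5 A grid is laid over the envelope of
# superposed training ligands; each probe is scored by the ratio of close
# contacts (< 1.0 A) with ligands annotated for a (sub)pocket versus
# ligands not annotated for it, and the highest-ranked probes per label are
# retained as the model. A new ligand is flagged for a (sub)pocket when any
# heavy atom touches any retained probe of that label. Conserved pocket
# waters are assigned to the nearest of 13 cluster centroids.
# ---------------------------------------------------------------------------

#' Subpocket label table
#'
#' The 3 major pockets and 12 subpockets with their parent region.
#' @return Tibble with columns `label`, `parent` (`NA` for majors).
#' @export
subpocket_labels <- function() {
  tibble(
    label = c("front_cleft", "gate_area", "back_cleft",
              "FP-I", "FP-II",
              "BP-I-A", "BP-I-B", "BP-II-in", "BP-II-A-in", "BP-II-B-in",
              "BP-II-out", "BP-II-B", "BP-III", "BP-IV", "BP-V"),
    parent = c(NA, NA, NA,
               "front_cleft", "front_cleft",
               "gate_area", "gate_area",
               "back_cleft", "back_cleft", "back_cleft", "back_cleft",
               "back_cleft", "back_cleft", "back_cleft", "back_cleft")
  )
}

# canonical centres (master frame) used by the synthetic corpus generator;
# majors are wide envelopes (front cleft at the hinge, gate area at the
# gatekeeper, back cleft behind it), subpockets local lobes spaced so that
# each is resolvable at the model's probe contact radius
subpocket_anchors <- function() {
  tibble(
    label = subpocket_labels()$label,
    cx = c(6, 1.5, -5.5,   7, 6,   0, 0,
           -5.5, -5.5, -5.5, -5.5, -8.5, -8.5, -8.5, -8.5),
    cy = c(0, 0.5, 0,   -1, 1,   -1, 1,
           5.2, -5.2, 0, 0, 3, -3, 3, -3),
    cz = c(0, 0, 0,   -2, 4,   3, -3,
           0, 0, 5.2, -5.2, 3, 3, -3, -3),
    radius = c(4.5, 2.5, 4.5,  1.8, 1.8,  1.5, 1.5,
               1.2, 1.2, 1.2, 1.2, 1.2, 1.2, 1.2, 1.2)
  )
}

# ground-truth label set of an atom cloud: inside any anchor sphere, plus
# the hierarchy closure (a subpocket implies its parent major region)
anchor_truth_labels <- function(xyz) {
  an <- subpocket_anchors()
  hit <- vapply(seq_len(nrow(an)), function(i) {
    any(sqrt(colSums((t(xyz) - c(an$cx[i], an$cy[i], an$cz[i]))^2)) <=
          an$radius[i])
  }, logical(1))
  labs <- an$label[hit]
  parents <- subpocket_labels()
  union(labs, stats::na.omit(parents$parent[parents$label %in% labs]))
}

#' Train the probe-grid subpocket model
#'
#' @param training List of training examples, each a list with `xyz` (heavy
#'   atoms in the master frame, n x 3) and `labels` (character vector of
#'   (sub)pocket labels the ligand is annotated for).
#' @param grid_spacing Probe grid spacing, Angstrom.
#' @param contact_radius Close-contact cutoff, Angstrom.
#' @param ratio_threshold Minimum positive:negative contact ratio for a
#'   probe to be retained.
#' @param top_k Maximum retained probes per label.
#' @param grid_origin Grid anchor point; defaults to the master-frame hinge
#'   centroid so training is reproducible.
#' @return A `kp_subpocket_model`: list of per-label probe matrices plus
#'   the parameters.
#' @export
train_subpocket_model <- function(training, grid_spacing = 0.5,
                                  contact_radius = 1.0,
                                  ratio_threshold = 3, top_k = 200,
                                  grid_origin = NULL) {
  stopifnot(length(training) > 0)
  if (is.null(grid_origin)) {
    fr <- master_frame()
    hs <- fr[fr$slot %in% 46:48, c("x", "y", "z")]
    grid_origin <- colMeans(as.matrix(hs))
  }
  all_xyz <- do.call(rbind, lapply(training, `[[`, "xyz"))
  lo <- apply(all_xyz, 2, min) - contact_radius
  hi <- apply(all_xyz, 2, max) + contact_radius
  # snap the grid to the origin so probe positions are reproducible
  ax <- lapply(1:3, function(d) {
    seq(grid_origin[d] + grid_spacing *
          floor((lo[d] - grid_origin[d]) / grid_spacing),
        hi[d], by = grid_spacing)
  })
  grid <- as.matrix(expand.grid(x = ax[[1]], y = ax[[2]], z = ax[[3]]))
  # only keep probes near any training atom (the ligand envelope)
  near <- min_dist(grid, all_xyz) <= contact_radius
  grid <- grid[near, , drop = FALSE]

  labels <- subpocket_labels()$label
  example_labels <- lapply(training, `[[`, "labels")
  probes <- list()
  for (lab in labels) {
    pos <- which(vapply(example_labels, function(l) lab %in% l, logical(1)))
    neg <- setdiff(seq_along(training), pos)
    if (length(pos) == 0) {
      warning("no positive examples for label ", lab, "; skipped",
              call. = FALSE)
      next
    }
    pos_xyz <- do.call(rbind, lapply(training[pos], `[[`, "xyz"))
    neg_xyz <- if (length(neg) > 0) {
      do.call(rbind, lapply(training[neg], `[[`, "xyz"))
    } else matrix(numeric(0), 0, 3)
    pos_n <- rowSums(pdist(grid, pos_xyz) < contact_radius)
    neg_n <- if (nrow(neg_xyz) > 0) {
      rowSums(pdist(grid, neg_xyz) < contact_radius)
    } else rep(0L, nrow(grid))
    ratio <- pos_n / pmax(neg_n, 0.5) # zero-negative probes score 2x pos_n
    keep <- which(pos_n > 0 & ratio >= ratio_threshold)
    if (length(keep) == 0) next
    keep <- keep[order(-ratio[keep], -pos_n[keep])]
    keep <- utils::head(keep, top_k)
    probes[[lab]] <- grid[keep, , drop = FALSE]
  }
  structure(list(probes = probes, grid_spacing = grid_spacing,
                 contact_radius = contact_radius,
                 ratio_threshold = ratio_threshold, top_k = top_k),
            class = "kp_subpocket_model")
}

#' @export
print.kp_subpocket_model <- function(x, ...) {
  cat(sprintf("<kp_subpocket_model> %d labels, %d probes (%.1f A grid)\n",
              length(x$probes), sum(vapply(x$probes, nrow, integer(1))),
              x$grid_spacing))
  invisible(x)
}

#' Assign subpocket flags to a ligand
#'
#' A (sub)pocket flag is set iff any ligand heavy atom lies within the
#' model's contact radius of any retained probe of that label. The
#' hierarchy constraint is enforced afterwards: a flagged subpocket implies
#' its parent major region.
#'
#' @param xyz Ligand heavy-atom coordinates in the master frame (n x 3), or
#'   a `kp_ligand`.
#' @param model A `kp_subpocket_model`.
#' @return Tibble with columns `label`, `parent`, `flag`.
#' @export
assign_subpockets <- function(xyz, model) {
  if (inherits(xyz, "kp_ligand")) xyz <- ligand_xyz(xyz)
  if (length(model$probes) == 0) stop("empty subpocket model", call. = FALSE)
  labs <- subpocket_labels()
  flag <- vapply(labs$label, function(lab) {
    p <- model$probes[[lab]]
    !is.null(p) && nrow(p) > 0 &&
      min(pdist(matrix(xyz, ncol = 3), p)) <= model$contact_radius
  }, logical(1))
  names(flag) <- labs$label
  # hierarchy: subpocket => parent major
  for (i in which(!is.na(labs$parent))) {
    if (flag[labs$label[i]]) flag[labs$parent[i]] <- TRUE
  }
  tibble(label = labs$label, parent = labs$parent, flag = unname(flag))
}

#' Write / read a subpocket model (MOL2 probe points + JSON metadata)
#'
#' @param model A `kp_subpocket_model`.
#' @param dir Output directory.
#' @return Invisibly the directory (write) or the model (read).
#' @export
write_subpocket_model <- function(model, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (lab in names(model$probes)) {
    p <- model$probes[[lab]]
    write_mol2(tibble(name = paste0("P", seq_len(nrow(p))), element = "C",
                      x = p[, 1], y = p[, 2], z = p[, 3]),
               file = file.path(dir, paste0(gsub("[^A-Za-z0-9-]", "_", lab),
                                            ".mol2")), name = lab)
  }
  jsonlite::write_json(
    list(labels = names(model$probes), grid_spacing = model$grid_spacing,
         contact_radius = model$contact_radius,
         ratio_threshold = model$ratio_threshold, top_k = model$top_k,
         provenance = "trained on a synthetic subpocket corpus"),
    file.path(dir, "model.json"), auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}

#' @rdname write_subpocket_model
#' @export
read_subpocket_model <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "model.json"))
  probes <- list()
  for (lab in unlist(meta$labels)) {
    f <- file.path(dir, paste0(gsub("[^A-Za-z0-9-]", "_", lab), ".mol2"))
    at <- read_mol2_atoms(f)
    probes[[lab]] <- as.matrix(at[, c("x", "y", "z")])
  }
  structure(list(probes = probes, grid_spacing = meta$grid_spacing,
                 contact_radius = meta$contact_radius,
                 ratio_threshold = meta$ratio_threshold, top_k = meta$top_k),
            class = "kp_subpocket_model")
}

# --- conserved water clusters ---------------------------------------------

#' Load the bundled water-cluster centroids
#'
#' 13 conserved pocket water clusters (I1-I11 plus the two DFG-out-specific
#' clusters O1 and O2) as centroids in the master frame, derived by
#' average-linkage clustering of superposed pocket waters.
#'
#' @param path CSV file; defaults to the bundled, versioned centroid table.
#' @return A `kp_water_clusters`: tibble with `label`, `x`, `y`, `z`,
#'   `dfg_out_specific`, plus an `assignment_radius` attribute (1.5 A).
#' @export
load_water_clusters <- function(path = system.file(
  "extdata", "water_clusters.csv", package = "kinpocket")) {
  tbl <- readr::read_csv(path, show_col_types = FALSE)
  structure(tbl, assignment_radius = 1.5,
            class = c("kp_water_clusters", class(tbl)))
}

#' Derive water-cluster centroids from superposed waters
#'
#' Average-linkage hierarchical clustering of water oxygen positions in the
#' master frame, cut into `k` clusters. Labels are assigned deterministically
#' by matching each centroid to the nearest canonical position (I1-I11, O1,
#' O2).
#'
#' @param xyz Water oxygen coordinates in the master frame (n x 3).
#' @param k Number of clusters.
#' @return Tibble `label`, `x`, `y`, `z`, `dfg_out_specific`, `n_members`.
#' @export
derive_water_clusters <- function(xyz, k = 13) {
  hc <- stats::hclust(stats::dist(xyz), method = "average")
  grp <- stats::cutree(hc, k = k)
  cents <- t(vapply(seq_len(k), function(g) {
    colMeans(xyz[grp == g, , drop = FALSE])
  }, numeric(3)))
  canon <- canonical_water_sites()
  # match centroids to canonical sites greedily by distance
  d <- pdist(cents, as.matrix(canon[, c("x", "y", "z")]))
  lab <- character(k)
  used <- integer(0)
  for (step in seq_len(k)) {
    idx <- which(d == min(d), arr.ind = TRUE)[1, ]
    lab[idx[1]] <- canon$label[idx[2]]
    d[idx[1], ] <- Inf
    d[, idx[2]] <- Inf
    used <- c(used, idx[2])
  }
  counts <- as.integer(table(factor(grp, levels = seq_len(k))))
  tibble(label = lab, x = cents[, 1], y = cents[, 2], z = cents[, 3],
         dfg_out_specific = grepl("^O", lab), n_members = counts) |>
    dplyr::arrange(match(.data$label, canon$label))
}

# canonical conserved water sites used by the fixture generator (master
# frame); the shipped centroid file is re-derived from clustered waters
canonical_water_sites <- function() {
  tibble(
    label = c(paste0("I", 1:11), "O1", "O2"),
    x = c(6, 7, 4, -1, -3, 0, -2, 2, -7, -6, 5, -6, -8),
    y = c(1, -1, 2, -1, -1.5, 2, -3, -3, -2, 3, 4, 2.5, 1),
    z = c(4, -2, -4, -4.5, -3, 5, 5, 2, 1, -5, -1, 1.5, -1.5)
  )
}

#' Assign pocket waters to conserved clusters
#'
#' Each water is assigned to the nearest centroid within the assignment
#' radius (ties broken toward the lowest label index); waters outside every
#' cluster are dropped. For each kept water the H-bond pattern with the
#' ligand and the protein is evaluated with the fingerprint module's H-bond
#' rule (water has no heavy-atom antecedent, so the distance criterion
#' governs).
#'
#' @param waters Water oxygen coordinates in the master frame (n x 3 matrix
#'   or tibble with x, y, z).
#' @param clusters A `kp_water_clusters` (or compatible tibble).
#' @param pocket Optional `kp_pocket` in the master frame for protein
#'   H-bonds.
#' @param lig Optional `kp_ligand` in the master frame for ligand H-bonds.
#' @param radius Assignment radius; defaults to the cluster set's.
#' @return Tibble `water`, `x`, `y`, `z`, `cluster`, `hbond_ligand`,
#'   `hbond_protein`.
#' @export
assign_water_clusters <- function(waters, clusters = load_water_clusters(),
                                  pocket = NULL, lig = NULL, radius = NULL) {
  if (is.data.frame(waters)) waters <- as.matrix(waters[, c("x", "y", "z")])
  waters <- matrix(as.numeric(waters), ncol = 3)
  if (is.null(radius)) radius <- attr(clusters, "assignment_radius") %||% 1.5
  if (nrow(waters) == 0) {
    return(tibble(water = integer(0), x = numeric(0), y = numeric(0),
                  z = numeric(0), cluster = character(0),
                  hbond_ligand = logical(0), hbond_protein = logical(0)))
  }
  cxyz <- as.matrix(clusters[, c("x", "y", "z")])
  d <- pdist(waters, cxyz)
  cfg <- ifp_config()
  out <- purrr::map_dfr(seq_len(nrow(waters)), function(i) {
    j <- which(d[i, ] <= radius)
    if (length(j) == 0) return(NULL)
    j <- j[order(d[i, j], j)][1] # nearest; ties -> lowest label index
    w <- waters[i, ]
    hb_lig <- FALSE
    if (!is.null(lig)) {
      lxyz <- ligand_xyz(lig)
      partners <- lxyz[lig$atoms$donor | lig$atoms$acceptor, , drop = FALSE]
      hb_lig <- nrow(partners) > 0 &&
        min(pdist(matrix(w, 1), partners)) <= cfg$hbond_dist
    }
    hb_prot <- FALSE
    if (!is.null(pocket)) {
      at <- pocket$atoms
      polar <- at[substr(at$elety, 1, 1) %in% c("N", "O"), c("x", "y", "z")]
      hb_prot <- nrow(polar) > 0 &&
        min(pdist(matrix(w, 1), as.matrix(polar))) <= cfg$hbond_dist
    }
    tibble(water = i, x = w[1], y = w[2], z = w[3],
           cluster = clusters$label[j],
           hbond_ligand = hb_lig, hbond_protein = hb_prot)
  })
  out
}
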