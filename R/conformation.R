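# ---------------------------------------------------------------------------
# Conformation annotation: solvent-accessible surface area of pocket
# residues (Shrake-Rupley), the DFG side-chain direction descriptors
# (y-components of Cgamma - Calpha for D81 and F82 in the master frame),
# the DFG decision-tree classifier, alphaC-helix distance classes, and the
# Gly-rich loop geometry descriptors.
# ---------------------------------------------------------------------------

VDW_RADII <- c(C = 1.70, N = 1.55, O = 1.52, S = 1.80, P = 1.80, H = 1.20,
               F = 1.47, CL = 1.75, BR = 1.85, I = 1.98)

vdw_radius <- function(el) {
  r <- VDW_RADII[toupper(el)]
  r[is.na(r)] <- 1.70
  unname(r)
}

#' Shrake-Rupley accessible surface area
#'
#' Numerical SASA of a subset of atoms in the context of a full structure:
#' each atom's extended sphere (van der Waals radius + probe) is sampled
#' with a deterministic Fibonacci point set and points buried inside any
#' neighbouring extended sphere are discarded.
#'
#' @param xyz n x 3 coordinate matrix of the full structure.
#' @param elements Length-n element symbols.
#' @param subset Indices of the atoms whose area is summed.
#' @param probe Probe radius in Angstrom.
#' @param n_points Sphere points per atom.
#' @return Total accessible area of the subset, Angstrom^2.
#' @export
shrake_rupley <- function(xyz, elements, subset = seq_len(nrow(xyz)),
                          probe = 1.4, n_points = 960) {
  xyz <- as.matrix(xyz)
  r <- vdw_radius(elements) + probe
  sp <- sphere_points(n_points)
  total <- 0
  for (k in subset) {
    rk <- r[k]
    d <- sqrt(colSums((t(xyz) - xyz[k, ])^2))
    nb <- which(d < rk + r & d > 1e-9)
    pts <- sweep(sp * rk, 2, xyz[k, ], "+")
    exposed <- rep(TRUE, n_points)
    for (j in nb) {
      if (!any(exposed)) break
      dj <- sqrt(colSums((t(pts[exposed, , drop = FALSE]) - xyz[j, ])^2))
      keep <- dj >= r[j]
      exposed[exposed] <- keep
    }
    total <- total + 4 * pi * rk^2 * mean(exposed)
  }
  total
}

#' ASA of one pocket residue
#'
#' @param pocket A `kp_pocket`.
#' @param index Slot index 1..85 (must be mapped).
#' @param probe,n_points See [shrake_rupley()].
#' @return Area in Angstrom^2.
#' @export
accessible_surface_area <- function(pocket, index, probe = 1.4,
                                    n_points = 960) {
  if (pocket$slots$gap[index]) {
    stop("undefined descriptor: slot ", index, " is a GAP", call. = FALSE)
  }
  at <- pocket$atoms
  shrake_rupley(as.matrix(at[, c("x", "y", "z")]),
                substr(at$elety, 1, 1),
                subset = which(at$slot == index),
                probe = probe, n_points = n_points)
}

slot_atom <- function(pocket, index, name) {
  at <- pocket$atoms
  row <- at[at$slot == index & at$elety == name, c("x", "y", "z")]
  if (nrow(row) == 0) return(NULL)
  as.numeric(row[1, ])
}

#' DFG side-chain direction descriptors
#'
#' The y-components of (Cgamma - Calpha) for the xDFG aspartate (slot 81)
#' and phenylalanine (slot 82), evaluated after superposition onto the
#' master frame (the frame fixes the axis convention).
#'
#' @param pocket A `kp_pocket` whose coordinates are already in the master
#'   frame (e.g. transformed with [transform_atoms()]).
#' @return Named numeric vector `c(yD, yF)`.
#' @export
dfg_vectors <- function(pocket) {
  out <- c(yD = NA_real_, yF = NA_real_)
  for (nm in c("yD", "yF")) {
    idx <- if (nm == "yD") 81L else 82L
    ca <- slot_atom(pocket, idx, "CA")
    cg <- slot_atom(pocket, idx, "CG")
    if (is.null(ca) || is.null(cg)) {
      stop("undefined descriptor: missing CA/CG at slot ", idx, call. = FALSE)
    }
    out[nm] <- cg[2] - ca[2]
  }
  out
}

#' Conformational descriptor set of a superposed pocket
#'
#' @param pocket A `kp_pocket` in the master frame.
#' @param n_points Sphere points for the ASA term.
#' @return One-row tibble with `asa_D81`, `yD`, `yF`, `d_F82_E24`.
#' @export
conformation_descriptors <- function(pocket, n_points = 240) {
  v <- dfg_vectors(pocket)
  ca82 <- slot_atom(pocket, 82, "CA")
  ca24 <- slot_atom(pocket, 24, "CA")
  tibble(
    asa_D81 = accessible_surface_area(pocket, 81, n_points = n_points),
    yD = v[["yD"]], yF = v[["yF"]],
    d_F82_E24 = if (is.null(ca82) || is.null(ca24)) NA_real_ else
      vnorm(ca82 - ca24)
  )
}

# --- DFG decision tree -----------------------------------------------------

#' Load the frozen DFG decision tree
#'
#' The default model shipped with the package; a JSON tree over the three
#' descriptors `asa_D81`, `yD`, `yF` with class leaves. Classification is
#' reproducible from the model file alone.
#'
#' @param path JSON model file; defaults to the bundled model.
#' @return A `kp_dfg_tree` (nested list).
#' @export
load_dfg_tree <- function(path = system.file("extdata", "dfg_tree.json",
                                             package = "kinpocket")) {
  structure(jsonlite::read_json(path), class = "kp_dfg_tree")
}

apply_tree_node <- function(node, x) {
  if (!is.null(node$class)) return(node$class)
  if (x[[node$feature]] < node$threshold) {
    apply_tree_node(node$left, x)
  } else {
    apply_tree_node(node$right, x)
  }
}

#' Classify the DFG conformation
#'
#' Applies the decision tree over `(asa_D81, yD, yF)`. Undefined
#' descriptors give class `"unknown"`.
#'
#' @param descriptors One-row data frame (or named list) with `asa_D81`,
#'   `yD`, `yF`.
#' @param tree A `kp_dfg_tree`; defaults to the bundled frozen model.
#' @return One of `"DFG-in"`, `"DFG-out"`, `"DFG-outlike"`, `"unknown"`.
#' @export
classify_dfg <- function(descriptors, tree = load_dfg_tree()) {
  x <- as.list(descriptors)
  if (any(vapply(x[c("asa_D81", "yD", "yF")], function(v)
    is.null(v) || is.na(v), logical(1)))) {
    return("unknown")
  }
  node <- if (!is.null(tree$root)) tree$root else tree
  apply_tree_node(node, x)
}

rpart_to_tree <- function(fit) {
  fr <- fit$frame
  node_ids <- as.integer(rownames(fr))
  splits <- fit$splits
  # rpart lists primary splits in frame order for non-leaf nodes
  split_rows <- which(fr$var != "<leaf>")
  split_idx <- integer(nrow(fr))
  cum <- 0
  for (ri in split_rows) {
    split_idx[ri] <- cum + 1
    cum <- cum + fr$ncompete[ri] + fr$nsurrogate[ri] + 1
  }
  build <- function(id) {
    ri <- match(id, node_ids)
    if (fr$var[ri] == "<leaf>") {
      return(list(class = attr(fit, "ylevels")[fr$yval[ri]]))
    }
    srow <- splits[split_idx[ri], ]
    thr <- unname(srow["index"])
    feat <- as.character(fr$var[ri])
    left <- build(2L * id)
    right <- build(2L * id + 1L)
    if (srow["ncat"] < 0) { # left branch is "< threshold"
      list(feature = feat, threshold = thr, left = left, right = right)
    } else {
      list(feature = feat, threshold = thr, left = right, right = left)
    }
  }
  list(root = build(1L))
}

#' Train the DFG decision tree
#'
#' CART (depth <= 3) over the three descriptors with labelled examples;
#' returns the model as the same JSON-serialisable structure used by the
#' frozen model file, plus the fitted rpart object.
#'
#' @param data Data frame with `asa_D81`, `yD`, `yF` and a `dfg` label
#'   column (`DFG-in` / `DFG-out` / `DFG-outlike`).
#' @param maxdepth Tree depth cap.
#' @return List with `tree` (a `kp_dfg_tree`) and `fit` (rpart).
#' @export
train_dfg_tree <- function(data, maxdepth = 3) {
  fit <- rpart::rpart(
    factor(dfg) ~ asa_D81 + yD + yF, data = data, method = "class",
    control = rpart::rpart.control(maxdepth = maxdepth, minsplit = 5,
                                   cp = 0.001, xval = 0))
  tree <- structure(rpart_to_tree(fit), class = "kp_dfg_tree")
  list(tree = tree, fit = fit)
}

#' Cross-validated accuracy of the DFG classifier
#'
#' k-fold cross-validation of the training harness: in each fold a fresh
#' tree is trained on the remaining folds and evaluated on the held-out
#' fold.
#'
#' @param data As in [train_dfg_tree()].
#' @param k Number of folds.
#' @param seed Fold-assignment seed.
#' @return Overall accuracy in `[0, 1]`.
#' @export
dfg_cv_accuracy <- function(data, k = 10, seed = 1) {
  set.seed(seed)
  fold <- sample(rep(seq_len(k), length.out = nrow(data)))
  correct <- 0L
  for (f in seq_len(k)) {
    tr <- train_dfg_tree(data[fold != f, ])
    pred <- vapply(which(fold == f), function(i) {
      classify_dfg(data[i, ], tr$tree)
    }, character(1))
    correct <- correct + sum(pred == data$dfg[fold == f])
  }
  correct / nrow(data)
}

#' Save a DFG tree model to JSON
#' @param tree A `kp_dfg_tree`.
#' @param path Output path.
#' @export
write_dfg_tree <- function(tree, path) {
  jsonlite::write_json(unclass(tree), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

# --- alphaC classes --------------------------------------------------------

#' Classify the alphaC-helix position
#'
#' Thresholds on the distance between the Calpha atoms of the xDFG
#' phenylalanine (slot 82) and the alphaC glutamate (slot 24):
#' `d <= t1` alphaC-in, `t1 < d <= t2` alphaC-outlike, `d > t2` alphaC-out.
#'
#' @param pocket A `kp_pocket` (any rigid frame; the distance is internal).
#' @param t1,t2 Class boundaries in Angstrom (defaults fitted on the
#'   synthetic conformational corpus).
#' @return One of `"aC-in"`, `"aC-outlike"`, `"aC-out"`, `"unknown"`.
#' @export
classify_alpha_c <- function(pocket, t1 = 7.2, t2 = 9.3) {
  ca82 <- slot_atom(pocket, 82, "CA")
  ca24 <- slot_atom(pocket, 24, "CA")
  if (is.null(ca82) || is.null(ca24)) return("unknown")
  d <- vnorm(ca82 - ca24)
  if (d <= t1) "aC-in" else if (d <= t2) "aC-outlike" else "aC-out"
}

# --- G-rich loop descriptors ----------------------------------------------

region_backbone_xyz <- function(pocket, region) {
  slots <- kp_regions()$index[kp_regions()$region == region]
  at <- pocket$atoms
  at <- at[at$slot %in% slots & at$elety %in% c("N", "CA", "C", "O"), ]
  if (nrow(at) == 0) return(NULL)
  as.matrix(at[, c("x", "y", "z")])
}

#' Gly-rich loop geometry descriptors
#'
#' Three descriptors of the G-rich loop relative to the hinge and catalytic
#' loop: the planar angle at the hinge centroid between the G-loop and
#' catalytic-loop centroids; the centroid distance between the G-loop and
#' the catalytic loop; and the rotation of the G-loop principal axis
#' against the catalytic-loop principal axis about the centroid-centroid
#' axis. Centroids and axes are computed over backbone atoms.
#'
#' @param pocket A `kp_pocket`.
#' @return Named numeric vector `c(angle, distance, rotation)` (degrees,
#'   Angstrom, degrees).
#' @export
gloop_descriptors <- function(pocket) {
  g <- region_backbone_xyz(pocket, "g.l")
  h <- region_backbone_xyz(pocket, "hinge")
  c_ <- region_backbone_xyz(pocket, "c.l")
  if (is.null(g) || is.null(h) || is.null(c_)) {
    stop("undefined descriptor: a required region is fully GAP", call. = FALSE)
  }
  gc <- colMeans(g); hc <- colMeans(h); cc <- colMeans(c_)
  c(angle = vec_angle(gc, hc, cc),
    distance = vnorm(gc - cc),
    rotation = projected_rotation(principal_axis(g), principal_axis(c_),
                                  gc - cc))
}

#' Full conformation annotation of a superposed pocket
#'
#' @param pocket A `kp_pocket` in the master frame.
#' @param tree DFG tree model.
#' @param n_points ASA sphere points.
#' @return A `kp_conformation`: list with `dfg`, `alpha_c`, `gloop` and the
#'   raw `descriptors` tibble.
#' @export
annotate_conformation <- function(pocket, tree = load_dfg_tree(),
                                  n_points = 240) {
  desc <- tryCatch(conformation_descriptors(pocket, n_points = n_points),
                   error = function(e) NULL)
  dfg <- if (is.null(desc)) "unknown" else classify_dfg(desc, tree)
  gl <- tryCatch(gloop_descriptors(pocket),
                 error = function(e) c(angle = NA_real_, distance = NA_real_,
                                       rotation = NA_real_))
  structure(list(dfg = dfg, alpha_c = classify_alpha_c(pocket),
                 gloop = gl, descriptors = desc),
            class = "kp_conformation")
}

#' @export
print.kp_conformation <- function(x, ...) {
  cat(sprintf("<kp_conformation> %s / %s; G-loop angle %.1f deg, dist %.1f A\n",
              x$dfg, x$alpha_c, x$gloop[["angle"]], x$gloop[["distance"]]))
  invisible(x)
}

#' @export
glance.kp_conformation <- function(x, ...) {
  tibble(dfg = x$dfg, alpha_c = x$alpha_c,
         gloop_angle = x$gloop[["angle"]],
         gloop_distance = x$gloop[["distance"]],
         gloop_rotation = x$gloop[["rotation"]]) |>
    dplyr::bind_cols(x$descriptors %||% tibble())
}
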