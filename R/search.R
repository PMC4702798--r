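# ---------------------------------------------------------------------------
# Query engine over annotated collections: pocket composition, conformation
# classes, subpocket and water-cluster flags, interaction patterns,
# fingerprint similarity, ligand similarity/dissimilarity and property
# filters, all ANDed. Plus the ligand chemical fingerprints (circular
# radius-2 and 166-bit structural keys) used by the similarity clauses.
# ---------------------------------------------------------------------------

# --- ligand chemical fingerprints -----------------------------------------

# deterministic string hash (polynomial rolling, 2^24 modulus: exact in
# double precision)
str_hash <- function(s) {
  h <- 0
  for (cc in utf8ToInt(s)) h <- (h * 31 + cc) %% 16777213
  h
}

#' Morgan-style circular fingerprint (radius 2)
#'
#' Hashed circular fingerprint over the ligand graph: the atom invariant
#' (element, degree, charge sign, aromaticity, implicit-H count) is
#' iteratively combined with sorted neighbour invariants for radii 0..2 and
#' each environment hash sets one of `n_bits` bits.
#'
#' @param lig A `kp_ligand`.
#' @param radius Environment radius.
#' @param n_bits Fingerprint length.
#' @return Logical vector of length `n_bits`.
#' @export
circular_fp <- function(lig, radius = 2, n_bits = 1024) {
  n <- nrow(lig$atoms)
  deg <- bond_degree(n, lig$bonds)
  inv <- sprintf("%s|%d|%d|%d|%d", lig$atoms$element, deg,
                 sign(lig$atoms$charge), as.integer(lig$atoms$aromatic),
                 lig$atoms$n_h)
  bits <- logical(n_bits)
  set_bits <- function(codes) {
    for (cd in codes) bits[(str_hash(cd) %% n_bits) + 1] <<- TRUE
  }
  set_bits(inv)
  for (r in seq_len(radius)) {
    inv <- vapply(seq_len(n), function(k) {
      nb <- neighbours_of(lig$bonds, k)
      ords <- vapply(nb, function(j) {
        b <- lig$bonds[(lig$bonds$i == k & lig$bonds$j == j) |
                         (lig$bonds$j == k & lig$bonds$i == j), ]
        b$order[1]
      }, character(1))
      paste(inv[k], paste(sort(paste(ords, inv[nb])), collapse = ","),
            sep = ">")
    }, character(1))
    set_bits(inv)
  }
  bits
}

# the 166 structural keys: thresholded counts of elements, rings, charges,
# H-bonding atoms, bond orders and simple two-atom fragments (MACCS-style
# coverage, package-defined key set)
structural_key_defs <- function() {
  feats <- c("C", "N", "O", "S", "P", "F", "CL", "BR", "I",
             "heavy", "rings", "aromatic_rings", "ring5", "ring6",
             "pos_charge", "neg_charge", "donors", "acceptors",
             "rotatable", "deg1", "deg2", "deg3", "deg4",
             "aromatic_atoms", "h_total", "double_bonds", "triple_bonds",
             "c_o_bonds", "c_n_bonds", "n_in_ring", "o_in_ring",
             "s_in_ring")
  defs <- tidyr::expand_grid(feature = feats, threshold = 1:5)
  extra <- tibble(feature = c("C", "C", "C", "heavy", "heavy", "heavy"),
                  threshold = c(8L, 12L, 16L, 10L, 20L, 30L))
  dplyr::bind_rows(defs, extra) # 32*5 + 6 = 166
}

structural_features <- function(lig) {
  n <- nrow(lig$atoms)
  deg <- bond_degree(n, lig$bonds)
  ring_atoms <- unique(unlist(lig$rings))
  el <- lig$atoms$element
  bond_el <- function(a, b) {
    sum((el[lig$bonds$i] == a & el[lig$bonds$j] == b) |
          (el[lig$bonds$i] == b & el[lig$bonds$j] == a))
  }
  c(C = sum(el == "C"), N = sum(el == "N"), O = sum(el == "O"),
    S = sum(el == "S"), P = sum(el == "P"), F = sum(el == "F"),
    CL = sum(el == "CL"), BR = sum(el == "BR"), I = sum(el == "I"),
    heavy = n, rings = length(lig$rings),
    aromatic_rings = length(lig$aromatic_rings),
    ring5 = sum(lengths(lig$rings) == 5),
    ring6 = sum(lengths(lig$rings) == 6),
    pos_charge = sum(lig$atoms$charge > 0),
    neg_charge = sum(lig$atoms$charge < 0),
    donors = sum(lig$atoms$donor), acceptors = sum(lig$atoms$acceptor),
    rotatable = ligand_descriptors(lig)$rotatable,
    deg1 = sum(deg == 1), deg2 = sum(deg == 2), deg3 = sum(deg == 3),
    deg4 = sum(deg >= 4),
    aromatic_atoms = sum(lig$atoms$aromatic),
    h_total = sum(lig$atoms$n_h),
    double_bonds = sum(lig$bonds$order == "2"),
    triple_bonds = sum(lig$bonds$order == "3"),
    c_o_bonds = bond_el("C", "O"), c_n_bonds = bond_el("C", "N"),
    n_in_ring = sum(el[ring_atoms] == "N"),
    o_in_ring = sum(el[ring_atoms] == "O"),
    s_in_ring = sum(el[ring_atoms] == "S"))
}

#' 166-bit structural-key fingerprint
#'
#' Explicit thresholded substructure/count keys (MACCS-style coverage with
#' a package-defined key set): elements, ring statistics, charges, H-bond
#' donors/acceptors, bond orders and simple fragments.
#'
#' @param lig A `kp_ligand`.
#' @return Logical vector of length 166.
#' @export
structural_fp <- function(lig) {
  f <- structural_features(lig)
  defs <- structural_key_defs()
  unname(f[defs$feature] >= defs$threshold)
}

#' Tanimoto similarity of two bit vectors
#' @param a,b Logical/0-1 vectors of equal length.
#' @return Similarity in `[0, 1]` (1 when both are empty).
#' @export
tanimoto <- function(a, b) {
  stopifnot(length(a) == length(b))
  u <- sum(a | b)
  if (u == 0) return(1)
  sum(a & b) / u
}

#' Ligand similarity
#' @param a,b `kp_ligand` objects.
#' @param kind `"circular"` (Morgan-style radius 2) or `"structural"`
#'   (166-key).
#' @return Tanimoto similarity.
#' @export
ligand_similarity <- function(a, b, kind = c("circular", "structural")) {
  kind <- match.arg(kind)
  if (kind == "circular") {
    tanimoto(circular_fp(a), circular_fp(b))
  } else {
    tanimoto(structural_fp(a), structural_fp(b))
  }
}

#' Tautomer-tolerant compound identity (approximate)
#'
#' Compares canonicalised composition: element counts, heavy-atom count,
#' ring-size multiset and the bond multiset with orders collapsed to
#' single/multiple. Tautomers (proton/bond-order shifts) compare equal;
#' the comparison is approximate, not a full graph isomorphism.
#'
#' @param a,b `kp_ligand` objects.
#' @return Logical.
#' @export
same_compound <- function(a, b) {
  key <- function(l) {
    el <- sort(table(l$atoms$element))
    multi <- sum(l$bonds$order %in% c("2", "3", "ar"))
    paste(paste(names(el), el, collapse = ","),
          nrow(l$bonds), paste(sort(lengths(l$rings)), collapse = "-"),
          sep = "|")
  }
  key(a) == key(b)
}

# --- property presets ------------------------------------------------------

#' Ligand property preset ranges
#'
#' Descriptor ranges for the four standard medicinal-chemistry presets.
#' `rule_of_five`: MW <= 500, logP <= 5, HBD <= 5, HBA <= 10.
#' `rule_of_three`: MW <= 300, logP <= 3, HBD <= 3, HBA <= 3,
#' rotatable <= 3. `fragment_like` and `lead_like` follow the usual
#' fragment/lead-oriented screening conventions; all ranges can be
#' overridden via `overrides`.
#'
#' @param preset One of `"rule_of_five"`, `"rule_of_three"`,
#'   `"fragment_like"`, `"lead_like"`.
#' @param overrides Named list `property -> c(min, max)` taking precedence.
#' @return Tibble with `property`, `min`, `max`.
#' @export
property_preset <- function(preset = c("rule_of_five", "rule_of_three",
                                       "fragment_like", "lead_like"),
                            overrides = list()) {
  preset <- match.arg(preset)
  base <- switch(preset,
    rule_of_five = list(mw = c(0, 500), logp = c(-Inf, 5), hbd = c(0, 5),
                        hba = c(0, 10)),
    rule_of_three = list(mw = c(0, 300), logp = c(-Inf, 3), hbd = c(0, 3),
                         hba = c(0, 3), rotatable = c(0, 3)),
    fragment_like = list(mw = c(0, 250), logp = c(-2, 3), hbd = c(0, 3),
                         hba = c(0, 3), rotatable = c(0, 3)),
    lead_like = list(mw = c(250, 350), logp = c(-Inf, 3.5),
                     rotatable = c(0, 7))
  )
  for (nm in names(overrides)) base[[nm]] <- overrides[[nm]]
  tibble(property = names(base),
         min = unname(vapply(base, `[`, numeric(1), 1)),
         max = unname(vapply(base, `[`, numeric(1), 2)))
}

# --- query construction ----------------------------------------------------

#' Build a collection query
#'
#' All supplied clauses are ANDed; the empty query matches every record.
#'
#' @param pocket Pocket-composition constraints: named vector
#'   `slot -> allowed amino acids` (e.g. `c("45" = "T")`; several letters
#'   allow any of them).
#' @param dfg,alpha_c Conformation class(es) to require.
#' @param subpocket,not_subpocket (Sub)pocket labels that must / must not
#'   be flagged.
#' @param water,not_water Water-cluster labels that must / must not be
#'   occupied.
#' @param pattern A `kp_pattern` interaction-pattern constraint.
#' @param ifp_ref,ifp_min Reference `kp_ifp` and minimum Tanimoto
#'   similarity.
#' @param ligand_ref Reference `kp_ligand` for chemical similarity.
#' @param ligand_kind `"circular"` or `"structural"`.
#' @param ligand_min,ligand_max Similarity bounds against `ligand_ref`.
#' @param preset Property preset name (see [property_preset()]).
#' @param ranges Manual property ranges, named list `property -> c(min,
#'   max)` (with a preset, acts as overrides).
#' @param quality_min,resolution_max Structure-property bounds.
#' @return A `kp_query`.
#' @export
kp_query <- function(pocket = NULL, dfg = NULL, alpha_c = NULL,
                     subpocket = NULL, not_subpocket = NULL,
                     water = NULL, not_water = NULL, pattern = NULL,
                     ifp_ref = NULL, ifp_min = NULL,
                     ligand_ref = NULL, ligand_kind = "circular",
                     ligand_min = NULL, ligand_max = NULL,
                     preset = NULL, ranges = NULL,
                     quality_min = NULL, resolution_max = NULL) {
  if (!is.null(ifp_min) && is.null(ifp_ref)) {
    stop("query error in clause 'ifp': ifp_min given without ifp_ref",
         call. = FALSE)
  }
  if ((!is.null(ligand_min) || !is.null(ligand_max)) && is.null(ligand_ref)) {
    stop("query error in clause 'ligand': bounds given without ligand_ref",
         call. = FALSE)
  }
  if (!is.null(pocket)) {
    slots <- suppressWarnings(as.integer(names(pocket)))
    if (any(is.na(slots)) || any(slots < 1 | slots > 85)) {
      stop("query error in clause 'pocket': names must be slots 1..85",
           call. = FALSE)
    }
  }
  if (!is.null(pattern) && !inherits(pattern, "kp_pattern")) {
    stop("query error in clause 'pattern': expected kp_pattern",
         call. = FALSE)
  }
  props <- if (!is.null(preset)) {
    property_preset(preset, overrides = ranges %||% list())
  } else if (!is.null(ranges)) {
    tibble(property = names(ranges),
           min = unname(vapply(ranges, `[`, numeric(1), 1)),
           max = unname(vapply(ranges, `[`, numeric(1), 2)))
  }
  structure(list(pocket = pocket, dfg = dfg, alpha_c = alpha_c,
                 subpocket = subpocket, not_subpocket = not_subpocket,
                 water = water, not_water = not_water, pattern = pattern,
                 ifp_ref = ifp_ref, ifp_min = ifp_min,
                 ligand_ref = ligand_ref, ligand_kind = ligand_kind,
                 ligand_min = ligand_min, ligand_max = ligand_max,
                 properties = props, quality_min = quality_min,
                 resolution_max = resolution_max),
            class = "kp_query")
}

record_matches <- function(r, q) {
  if (!is.null(q$pocket)) {
    for (s in names(q$pocket)) {
      aa <- r$pocket$slots$aa[as.integer(s)]
      if (!aa %in% strsplit(q$pocket[[s]], "")[[1]]) return(FALSE)
    }
  }
  if (!is.null(q$dfg) && !r$conformation$dfg %in% q$dfg) return(FALSE)
  if (!is.null(q$alpha_c) && !r$conformation$alpha_c %in% q$alpha_c) {
    return(FALSE)
  }
  if (!is.null(q$subpocket) || !is.null(q$not_subpocket)) {
    if (is.null(r$subpockets)) return(FALSE)
    flagged <- r$subpockets$label[r$subpockets$flag]
    if (!all(q$subpocket %in% flagged)) return(FALSE)
    if (any(q$not_subpocket %in% flagged)) return(FALSE)
  }
  if (!is.null(q$water) || !is.null(q$not_water)) {
    occ <- if (is.null(r$waters)) character(0) else unique(r$waters$cluster)
    if (!all(q$water %in% occ)) return(FALSE)
    if (any(q$not_water %in% occ)) return(FALSE)
  }
  if (!is.null(q$pattern) && !match_pattern(r$ifp, q$pattern)) return(FALSE)
  if (!is.null(q$ifp_ref) &&
      ifp_similarity(r$ifp, q$ifp_ref) < (q$ifp_min %||% 0)) return(FALSE)
  if (!is.null(q$ligand_ref)) {
    if (is.null(r$ligand)) return(FALSE)
    s <- ligand_similarity(r$ligand, q$ligand_ref, q$ligand_kind)
    if (!is.null(q$ligand_min) && s < q$ligand_min) return(FALSE)
    if (!is.null(q$ligand_max) && s > q$ligand_max) return(FALSE)
  }
  if (!is.null(q$properties)) {
    if (is.null(r$ligand_descriptors)) return(FALSE)
    d <- r$ligand_descriptors
    for (k in seq_len(nrow(q$properties))) {
      p <- q$properties$property[k]
      if (!p %in% names(d)) next
      v <- d[[p]]
      if (v < q$properties$min[k] || v > q$properties$max[k]) return(FALSE)
    }
  }
  if (!is.null(q$quality_min) && r$quality$score < q$quality_min) {
    return(FALSE)
  }
  if (!is.null(q$resolution_max) &&
      (is.na(r$ids$resolution) || r$ids$resolution > q$resolution_max)) {
    return(FALSE)
  }
  TRUE
}

#' Evaluate a query over a collection
#'
#' Returns the records satisfying every clause, ordered by descending
#' fingerprint similarity when an IFP-similarity clause is present,
#' otherwise by entry id (ties: entry id lexicographic). Pure function of
#' `(records, query)`.
#'
#' @param records A `kp_collection` (or list of `kp_record`).
#' @param q A `kp_query`.
#' @return Tibble: one row per matching record (as [tidy.kp_record()]) plus
#'   an `ifp_similarity` column when relevant.
#' @export
evaluate_query <- function(records, q) {
  hit <- vapply(records, record_matches, logical(1), q = q)
  matched <- records[hit]
  if (length(matched) == 0) {
    return(tibble(entry_id = character(0)))
  }
  out <- purrr::map_dfr(matched, tidy.kp_record)
  if (!is.null(q$ifp_ref)) {
    out$ifp_similarity <- vapply(matched, function(r) {
      ifp_similarity(r$ifp, q$ifp_ref)
    }, numeric(1))
    out <- dplyr::arrange(out, dplyr::desc(.data$ifp_similarity),
                          .data$entry_id)
  } else {
    out <- dplyr::arrange(out, .data$entry_id)
  }
  out
}

#' Export query results to CSV
#'
#' One row per record, stable column order, UTF-8, RFC-4180 quoting
#' (spreadsheet-compatible).
#'
#' @param results Result tibble from [evaluate_query()] (or any data
#'   frame).
#' @param file Output path.
#' @return Invisibly, `file`.
#' @export
export_results <- function(results, file) {
  stopifnot(ncol(results) > 0)
  readr::write_csv(results, file)
  invisible(file)
}
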