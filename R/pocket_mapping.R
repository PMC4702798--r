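# ---------------------------------------------------------------------------
# Pocket mapping: align a kinase catalytic-domain sequence to the master
# profile, identify the 85 pocket residues, apply the slot numbering, and
# report gaps, missing atoms and mutations.
# ---------------------------------------------------------------------------

#' Amino-acid sequence of a monomer
#'
#' One-letter sequence in residue-number order of the protein chain.
#' @param monomer A `kp_monomer`.
#' @return Character string.
#' @export
monomer_sequence <- function(monomer) {
  res <- monomer$atoms |>
    dplyr::distinct(.data$resno, .data$resid) |>
    dplyr::arrange(.data$resno)
  paste(aa1[res$resid], collapse = "")
}

#' Align a sequence to the master pocket profile
#'
#' Global-local alignment (global in the master profile, local in the query)
#' with BLOSUM62, gap open 11 / extend 1. Deterministic for fixed
#' parameters.
#'
#' @param sequence One-letter amino-acid string (>= 50 residues unless
#'   `min_length` is lowered).
#' @param master Master profile consensus; defaults to the bundled one.
#' @param score_floor Alignments scoring below this are rejected as not a
#'   kinase domain.
#' @param min_length Minimum query length.
#' @return A `kp_alignment`: list with `score`, `mapping` (tibble
#'   `master_column`, `query_pos` with `NA` for gapped columns), and the
#'   aligned strings.
#' @export
align_to_master <- function(sequence, master = master_pocket_sequence(),
                            score_floor = 60, min_length = 50) {
  if (nchar(sequence) < min_length) {
    stop("sequence too short to be a kinase catalytic domain", call. = FALSE)
  }
  data_env <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = data_env)
  pa <- Biostrings::pairwiseAlignment(
    pattern = master, subject = sequence,
    substitutionMatrix = data_env$BLOSUM62,
    gapOpening = 11, gapExtension = 1, type = "global-local")
  if (Biostrings::score(pa) < score_floor) {
    stop("alignment score below floor: not a kinase domain", call. = FALSE)
  }
  pat <- strsplit(as.character(Biostrings::alignedPattern(pa)), "")[[1]]
  sub <- strsplit(as.character(Biostrings::alignedSubject(pa)), "")[[1]]
  sub_start <- Biostrings::start(Biostrings::subject(pa))
  mcol <- 0L
  qpos <- sub_start - 1L
  map <- matrix(NA_integer_, nrow = nchar(master), ncol = 1)
  for (k in seq_along(pat)) {
    if (pat[k] != "-") mcol <- mcol + 1L
    if (sub[k] != "-") qpos <- qpos + 1L
    if (pat[k] != "-" && sub[k] != "-") map[mcol, 1] <- qpos
  }
  structure(list(
    score = Biostrings::score(pa),
    mapping = tibble(master_column = seq_len(nchar(master)),
                     query_pos = map[, 1]),
    aligned_master = paste(pat, collapse = ""),
    aligned_query = paste(sub, collapse = "")
  ), class = "kp_alignment")
}

#' @export
print.kp_alignment <- function(x, ...) {
  cat(sprintf("<kp_alignment> score %.1f, %d/%d master columns mapped\n",
              x$score, sum(!is.na(x$mapping$query_pos)),
              nrow(x$mapping)))
  invisible(x)
}

#' Extract the 85-slot pocket alignment of a monomer
#'
#' Maps each of the 85 master pocket columns to a structure residue (or GAP),
#' records unresolved side-chain atoms per slot, and attaches the pocket
#' atom coordinates. The mapping is by alignment column, so it is invariant
#' under renumbering of the structure's residues.
#'
#' @param alignment A `kp_alignment` from [align_to_master()], or `NULL` to
#'   align `monomer`'s sequence automatically.
#' @param monomer A `kp_monomer`.
#' @param kinase_id Identifier stored on the result.
#' @param max_gaps Maximum tolerated GAP slots (more than half the pocket
#'   missing is rejected as unresolved).
#' @return A `kp_pocket`: list with `kinase_id`, `slots` (85-row tibble:
#'   `index`, `region`, `label`, `master_aa`, `aa`, `resno`, `gap`,
#'   `missing_atoms` list-column) and `atoms` (pocket atoms with a `slot`
#'   column).
#' @export
extract_pocket <- function(alignment, monomer, kinase_id = monomer$source_id,
                           max_gaps = 42) {
  if (is.null(alignment)) alignment <- align_to_master(monomer_sequence(monomer))
  regions <- kp_regions()
  res <- monomer$atoms |>
    dplyr::distinct(.data$resno, .data$resid) |>
    dplyr::arrange(.data$resno)
  master_aa <- strsplit(master_pocket_sequence(), "")[[1]]
  ref_atoms <- master_reference_atoms()

  qpos <- alignment$mapping$query_pos[regions$master_column]
  resno <- ifelse(is.na(qpos), NA_integer_, res$resno[qpos])
  aa <- ifelse(is.na(qpos), "-", unname(aa1[res$resid[qpos]]))
  gap <- is.na(qpos)
  if (sum(gap) > max_gaps) {
    stop("pocket unresolved: more than ", max_gaps, " GAP slots",
         call. = FALSE)
  }

  atoms <- monomer$atoms |>
    dplyr::mutate(slot = match(.data$resno, .env$resno)) |>
    dplyr::filter(!is.na(.data$slot))

  missing_atoms <- lapply(1:85, function(i) {
    if (gap[i]) return(character(0))
    have <- atoms$elety[atoms$slot == i]
    expected <- if (aa[i] == master_aa[i]) {
      ref_atoms[[i]]
    } else {
      c("N", "CA", "C", "O", if (aa[i] != "G") "CB")
    }
    setdiff(expected, have)
  })

  slots <- tibble(
    index = 1:85, region = regions$region,
    label = pocket_label(ifelse(gap, "-", aa), 1:85, regions),
    master_aa = master_aa, aa = aa, resno = resno, gap = gap,
    missing_atoms = missing_atoms
  )
  structure(list(kinase_id = kinase_id, slots = slots, atoms = atoms),
            class = "kp_pocket")
}

#' @export
print.kp_pocket <- function(x, ...) {
  cat(sprintf("<kp_pocket> %s: %d/85 slots mapped, %d with missing atoms\n",
              x$kinase_id, sum(!x$slots$gap),
              sum(lengths(x$slots$missing_atoms) > 0)))
  invisible(x)
}

#' @export
tidy.kp_pocket <- function(x, ...) {
  dplyr::mutate(x$slots,
                n_missing_atoms = lengths(.data$missing_atoms))
}

#' @export
glance.kp_pocket <- function(x, ...) {
  tibble(kinase_id = x$kinase_id, n_mapped = sum(!x$slots$gap),
         n_gaps = sum(x$slots$gap),
         n_missing_atoms = sum(lengths(x$slots$missing_atoms)))
}

#' Detect pocket mutations against a reference sequence
#'
#' Lists every slot where the observed residue differs from the reference;
#' GAP slots are excluded (nothing to compare).
#'
#' @param pocket A `kp_pocket`.
#' @param reference_sequence 85-character reference pocket sequence (e.g.
#'   from the canonical protein sequence database entry); defaults to the
#'   master consensus.
#' @return Tibble with columns `index`, `ref`, `obs`.
#' @export
detect_mutations <- function(pocket,
                             reference_sequence = master_pocket_sequence()) {
  ref <- strsplit(reference_sequence, "")[[1]]
  if (length(ref) != 85) stop("reference must cover the 85 pocket slots",
                              call. = FALSE)
  s <- pocket$slots
  keep <- !s$gap & s$aa != ref
  tibble(index = s$index[keep], ref = ref[keep], obs = s$aa[keep])
}

#' Write a pocket alignment to FASTA and CSV
#'
#' @param pocket A `kp_pocket`.
#' @param fasta,csv Output paths (either may be `NULL` to skip).
#' @return Invisibly, the paths written.
#' @export
write_pocket <- function(pocket, fasta = NULL, csv = NULL) {
  paths <- character(0)
  if (!is.null(fasta)) {
    writeLines(c(paste0(">", pocket$kinase_id),
                 paste(pocket$slots$aa, collapse = "")), fasta)
    paths <- c(paths, fasta)
  }
  if (!is.null(csv)) {
    readr::write_csv(tidy.kp_pocket(pocket) |>
                       dplyr::mutate(missing_atoms = vapply(
                         .data$missing_atoms, paste, character(1),
                         collapse = ";")), csv)
    paths <- c(paths, csv)
  }
  invisible(paths)
}
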