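# shared fixtures, built once per test run
.shared <- new.env(parent = emptyenv())

shared_hinge_fixture <- function() {
  if (is.null(.shared$hinge_fx)) {
    .shared$hinge_fx <- generate_complex(fixture_spec(
      seed = 101, contacts = list(list(slot = 47, type = "hbond_acceptor"))))
  }
  .shared$hinge_fx
}

shared_subpocket_model <- function() {
  if (is.null(.shared$sub_model)) {
    .shared$sub_corpus <- generate_subpocket_corpus(100, seed = 11)
    test_i <- seq_along(.shared$sub_corpus) %% 5 == 0
    .shared$sub_model <- train_subpocket_model(.shared$sub_corpus[!test_i])
    .shared$sub_test <- .shared$sub_corpus[test_i]
  }
  .shared$sub_model
}

shared_subpocket_test_set <- function() {
  shared_subpocket_model()
  .shared$sub_test
}

# an engineered collection of annotated records reused by the query tests:
# each record is built to satisfy or violate specific clauses of the three
# worked query shapes
search_fixture_collection <- function() {
  if (!is.null(.shared$collection)) return(.shared$collection)
  model <- shared_subpocket_model()
  mk <- function(seed, id, ...) {
    fx <- generate_complex(fixture_spec(seed = seed, kinase_id = id, ...))
    annotate_structure(fx$monomer, ligand = fixture_ligand(fx),
                       subpocket_model = model)
  }
  hinge <- list(list(slot = 47, type = "hbond_acceptor"))
  two_hb <- c(hinge, list(list(slot = 46, type = "hbond_donor")))
  .shared$collection <- kp_collection(list(
    # gatekeeper-threonine front/gate binder (the selective-inhibitor hit)
    mk(201, "GK01", contacts = hinge, occupy = c("FP-I", "BP-I-A")),
    # same binding mode but reaching the back cleft
    mk(202, "GK02", contacts = hinge,
       occupy = c("FP-I", "BP-I-A", "BP-III")),
    # bulky gatekeeper mutant
    mk(203, "GK03", contacts = hinge, occupy = c("FP-I", "BP-I-A"),
       mutations = c("45" = "M")),
    # conserved-water binder (I4 + I5)
    mk(204, "WAT01", contacts = hinge, waters = c("I4", "I5")),
    # only one of the two waters
    mk(205, "WAT02", contacts = hinge, waters = "I4"),
    # water binder with a leucine at the b.l valine slot
    mk(206, "WAT03", contacts = hinge, waters = c("I4", "I5"),
       mutations = c("36" = "L")),
    # interaction-pattern reference and a chemically-different mimic
    mk(207, "IFP_REF", contacts = two_hb),
    mk(208, "IFP_MIMIC", contacts = two_hb,
       occupy = c("FP-II", "BP-II-in", "BP-IV", "BP-V")),
    # different interaction pattern, similar chemistry to the reference
    mk(209, "IFP_OTHER", contacts = list(
      list(slot = 17, type = "ionic_pos"))),
    # apo structure
    mk(210, "APO01")
  ))
  .shared$collection
}

# a small random "toy complex": random pocket conformation plus a random
# ligand graph scattered through the site
random_toy_complex <- function(seed) {
  set.seed(seed)
  fx <- generate_complex(fixture_spec(
    seed = seed, dfg = sample(c("in", "out", "outlike"), 1),
    alpha_c = sample(c("in", "outlike", "out"), 1)), validate = FALSE)
  pocket <- extract_pocket(NULL, fx$monomer)
  n <- sample(8:20, 1)
  atoms <- tibble::tibble(
    name = paste0("X", seq_len(n)),
    element = sample(c("C", "C", "N", "O", "F"), n, replace = TRUE),
    x = runif(n, -12, 10), y = runif(n, -6, 6), z = runif(n, -8, 6),
    resid = "LIG"
  )
  bonds <- if (n > 1) {
    tibble::tibble(i = 1:(n - 1), j = 2:n,
                   order = sample(c("1", "1", "2"), n - 1, replace = TRUE))
  } else tibble::tibble(i = integer(0), j = integer(0), order = character(0))
  attr(atoms, "kp_bonds") <- bonds
  list(pocket = pocket, ligand = curate_ligand_topology(atoms))
}

# minimal hand-written PDB text (for multi-model / multi-chain / alt-loc
# parsing tests)
pdb_atom_line <- function(serial, name, resn, chain, resno, x, y, z,
                          alt = " ", occ = 1, type = "ATOM") {
  sprintf("%-6s%5d %-4s%1s%3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          type, serial, ifelse(nchar(name) < 4, paste0(" ", name), name),
          alt, resn, chain, resno, x, y, z, occ, 0,
          substr(name, 1, 1))
}

tiny_residue_lines <- function(chain, resno, offset, serial0) {
  nm <- c("N", "CA", "C", "O")
  dx <- c(-1.2, 0, 1.2, 1.2)
  dy <- c(0, 0, 0, 1.23)
  vapply(1:4, function(i) {
    pdb_atom_line(serial0 + i, nm[i], "ALA", chain, resno,
                  offset[1] + dx[i], offset[2] + dy[i], offset[3])
  }, character(1))
}
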