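test_that("homology-hit filtering applies the inclusive identity/e-value rule", {
  hits <- data.frame(
    identity = c(70.0, 69.9, 95.0, 100, 70.0),
    e_value = c(0.001, 1e-50, 0.01, 0, 0.0011))
  expect_equal(filter_homolog_hits(hits), c(1L, 4L))
  expect_error(filter_homolog_hits(data.frame(identity = 80, e_value = -1)),
               "negative")
  expect_error(filter_homolog_hits(data.frame(identity = 120, e_value = 0)),
               "percentage")
})

test_that("split_entry yields one monomer per model x chain pair", {
  # two chains, one model
  lines <- c(tiny_residue_lines("A", 1, c(0, 0, 0), 0),
             tiny_residue_lines("A", 2, c(3.8, 0, 0), 4),
             tiny_residue_lines("B", 1, c(0, 20, 0), 8),
             tiny_residue_lines("B", 2, c(3.8, 20, 0), 12), "END")
  f <- withr::local_tempfile(fileext = ".pdb")
  writeLines(lines, f)
  mono <- split_entry(f)
  expect_length(mono, 2)
  expect_setequal(vapply(mono, `[[`, character(1), "chain_id"), c("A", "B"))

  # two models, one chain
  body <- c(tiny_residue_lines("A", 1, c(0, 0, 0), 0),
            tiny_residue_lines("A", 2, c(3.8, 0, 0), 4))
  lines2 <- c("MODEL     1", body, "ENDMDL", "MODEL     2",
              sub("^ATOM  ", "ATOM  ", body), "ENDMDL", "END")
  f2 <- withr::local_tempfile(fileext = ".pdb")
  writeLines(lines2, f2)
  mono2 <- split_entry(f2)
  expect_length(mono2, 2)
  expect_equal(vapply(mono2, `[[`, integer(1), "model_index"), 1:2)
})

test_that("split_entry attaches hetero groups and parses mmCIF", {
  fx <- shared_hinge_fixture()
  d <- withr::local_tempdir()
  write_fixture(fx, d)
  mono <- split_entry(file.path(d, paste0(fx$spec$kinase_id, "_complex.pdb")))
  expect_length(mono, 1)
  expect_length(hetero_groups(mono[[1]]), 1)

  cif <- system.file("extdata", "toy_entry_synthetic.cif",
                     package = "kinpocket")
  mono_cif <- suppressWarnings(split_entry(cif))
  expect_length(mono_cif, 1)
  expect_equal(dplyr::n_distinct(mono_cif[[1]]$atoms$resno), 85)
  expect_length(hetero_groups(mono_cif[[1]]), 2)
})

test_that("split_entry errors on unparseable input and empty entries", {
  f <- withr::local_tempfile(fileext = ".pdb")
  writeLines("this is not a structure", f)
  expect_error(split_entry(f))
  f2 <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(pdb_atom_line(1, "O", "HOH", "A", 1, 0, 0, 0,
                             type = "HETATM"), "END"), f2)
  expect_error(split_entry(f2), "no protein chains")
})

test_that("alternate locations resolve to the highest-occupancy conformer", {
  lines <- c(
    pdb_atom_line(1, "N", "ALA", "A", 1, 0, 0, 0),
    pdb_atom_line(2, "CA", "ALA", "A", 1, 1.5, 0, 0, alt = "A", occ = 0.4),
    pdb_atom_line(3, "CA", "ALA", "A", 1, 1.5, 5, 0, alt = "B", occ = 0.6),
    pdb_atom_line(4, "C", "ALA", "A", 1, 3, 0, 0, alt = "A", occ = 0.5),
    pdb_atom_line(5, "C", "ALA", "A", 1, 3, 5, 0, alt = "B", occ = 0.5),
    pdb_atom_line(6, "O", "ALA", "A", 1, 3, 1.2, 0),
    "END")
  f <- withr::local_tempfile(fileext = ".pdb")
  writeLines(lines, f)
  at <- split_entry(f)[[1]]$atoms
  expect_equal(nrow(at), 4) # no duplicated (resno, name)
  expect_equal(at$y[at$elety == "CA"], 5)  # occupancy 0.6 wins
  expect_equal(at$y[at$elety == "C"], 0)   # tie -> alphabetically first
})

test_that("write/read round-trips atom counts and coordinates to 3 decimals", {
  fx <- shared_hinge_fixture()
  d <- withr::local_tempdir()
  write_fixture(fx, d)
  path <- file.path(d, paste0(fx$spec$kinase_id, "_complex.pdb"))
  m1 <- split_entry(path)[[1]]
  d2 <- withr::local_tempdir()
  write_atoms_pdb(m1$atoms, m1$hetero, file.path(d2, "again.pdb"))
  m2 <- split_entry(file.path(d2, "again.pdb"))[[1]]
  expect_equal(nrow(m2$atoms), nrow(m1$atoms))
  expect_equal(as.matrix(m2$atoms[, c("x", "y", "z")]),
               as.matrix(m1$atoms[, c("x", "y", "z")]),
               tolerance = 1e-3, ignore_attr = TRUE)
})

test_that("entity classification partitions hetero groups by the rule order", {
  fx <- shared_hinge_fixture()
  mono <- fx$monomer
  far_lig <- dplyr::mutate(mono$hetero[mono$hetero$resid == "LIG", ],
                           resno = 901L, x = x + 40)
  extra <- dplyr::bind_rows(
    tibble::tibble(eleno = 9001L, elety = "MG", resid = "MG", chain = "A",
                   resno = 930L, x = 0, y = 0, z = 0, o = 1, b = 0,
                   elesy = "MG", type = "HETATM"),
    tibble::tibble(eleno = 9002L, elety = "O", resid = "HOH", chain = "A",
                   resno = 931L, x = 2, y = 2, z = 2, o = 1, b = 0,
                   elesy = "O", type = "HETATM"),
    tibble::tibble(eleno = 9003:9005, elety = c("PA", "C1", "N1"),
                   resid = "ATP", chain = "A", resno = 932L,
                   x = c(5, 6, 7), y = 0, z = 0, o = 1, b = 0,
                   elesy = c("P", "C", "N"), type = "HETATM"),
    tibble::tibble(eleno = 9006:9007, elety = c("FE", "C9"),
                   resid = "XOM", chain = "A", resno = 933L,
                   x = c(15, 16), y = 10, z = 0, o = 1, b = 0,
                   elesy = c("FE", "C"), type = "HETATM"),
    far_lig)
  mono$hetero <- dplyr::bind_rows(mono$hetero, extra)
  pocket <- extract_pocket(NULL, mono)
  ent <- classify_entities(mono, pocket)

  expect_equal(sort(ent$manifest$category[match(
    c("MG_930", "HOH_931", "ATP_932", "XOM_933"), ent$manifest$group)]),
    sort(c("ion", "water", "cofactor", "organometallic")))
  # designed hinge binder is orthosteric; the 40 A copy is allosteric
  expect_equal(ent$manifest$category[ent$manifest$group == "LIG_900"],
               "orthosteric_ligand")
  expect_equal(ent$manifest$category[ent$manifest$group == "LIG_901"],
               "allosteric_ligand")
  # partition: every group in exactly one category
  expect_equal(nrow(ent$manifest), length(hetero_groups(mono)))
  n_cat <- length(ent$allosteric_ligands) + length(ent$waters) +
    length(ent$ions) + length(ent$cofactors) + length(ent$organometallics) +
    !is.null(ent$orthosteric_ligand)
  expect_equal(n_cat, nrow(ent$manifest))
})

test_that("write_monomer produces protein PDB, per-group MOL2 and a manifest", {
  fx <- shared_hinge_fixture()
  d <- withr::local_tempdir()
  pocket <- extract_pocket(NULL, fx$monomer)
  ent <- classify_entities(fx$monomer, pocket)
  paths <- write_monomer(fx$monomer, d, entities = ent)
  expect_true(any(grepl("_protein\\.pdb$", paths)))
  expect_true(any(grepl("\\.mol2$", paths)))
  man <- readr::read_csv(file.path(d, "entities.csv"), show_col_types = FALSE)
  expect_equal(nrow(man), nrow(ent$manifest))
})
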