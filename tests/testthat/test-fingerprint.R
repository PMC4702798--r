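phe_residue <- function(z = 0) {
  th <- (0:5) * pi / 3
  tibble::tibble(
    elety = c("N", "CA", "C", "O", "CB",
              c("CG", "CD1", "CE1", "CZ", "CE2", "CD2")),
    resid = "PHE",
    x = c(-3, -2.2, -1.2, -1.2, -2.6, 1.39 * cos(th)),
    y = c(-3.5, -2.8, -3.4, -4.6, -1.6, 1.39 * sin(th)),
    z = z)
}

benzene_at <- function(dx = 0, dy = 0, dz = 0, tilt = 0) {
  atoms <- tibble::tibble(
    name = paste0("C", 1:6), element = "C",
    x = 1.39 * cos((0:5) * pi / 3), y = 1.39 * sin((0:5) * pi / 3), z = 0,
    resid = "LIG")
  if (tilt != 0) {
    R <- kinpocket:::rotation_about(c(1, 0, 0), tilt)
    xyz <- as.matrix(atoms[, c("x", "y", "z")]) %*% R
    atoms$x <- xyz[, 1]; atoms$y <- xyz[, 2]; atoms$z <- xyz[, 3]
  }
  atoms$x <- atoms$x + dx; atoms$y <- atoms$y + dy; atoms$z <- atoms$z + dz
  attr(atoms, "kp_bonds") <- tibble::tibble(i = 1:6, j = c(2:6, 1L),
                                            order = "ar")
  curate_ligand_topology(atoms)
}

test_that("aromatic stacking geometry drives the F2F and E2F bits", {
  res <- phe_residue()
  # parallel ring 3.6 A above the Phe ring plane
  expect_equal(unname(detect_interactions(res, benzene_at(dz = 3.6))[
    c("aromatic_f2f", "aromatic_e2f")]), c(1L, 0L))
  # perpendicular ring at edge-to-face distance
  expect_equal(unname(detect_interactions(
    res, benzene_at(dz = 4.7, tilt = 90))[
      c("aromatic_f2f", "aromatic_e2f")]), c(0L, 1L))
  # parallel but beyond the F2F cutoff
  expect_equal(unname(detect_interactions(res, benzene_at(dz = 4.4))[
    "aromatic_f2f"]), 0L)
})

test_that("a remote ligand produces an all-zero block", {
  far <- benzene_at(dx = 30)
  expect_equal(sum(detect_interactions(phe_residue(), far)), 0L)
})

test_that("an amide donor 2.9 A from the backbone carbonyl sets the
           protein-acceptor bit", {
  res <- phe_residue()
  o <- as.numeric(res[res$elety == "O", c("x", "y", "z")])
  c_ <- as.numeric(res[res$elety == "C", c("x", "y", "z")])
  u <- kinpocket:::unitv(o - c_)
  # donor angle ~165 degrees: antecedent carbon nearly opposite the acceptor
  dN <- o + 2.9 * u
  R <- kinpocket:::rotation_about(kinpocket:::pracma_cross(u, c(0, 0, 1)),
                                  180 - 165)
  ante <- dN + 1.47 * as.numeric(u %*% R)
  atoms <- tibble::tibble(name = c("N1", "C1", "O1"),
                          element = c("N", "C", "O"),
                          x = c(dN[1], ante[1], ante[1] + 1.23),
                          y = c(dN[2], ante[2], ante[2]),
                          z = c(dN[3], ante[3], ante[3] + 1.1),
                          resid = "LIG")
  attr(atoms, "kp_bonds") <- tibble::tibble(i = c(1L, 2L), j = c(2L, 3L),
                                            order = c("1", "2"))
  lig <- curate_ligand_topology(atoms)
  expect_equal(unname(detect_interactions(res, lig)["hbond_acceptor"]), 1L)
  # same donor pushed beyond 3.5 A: bit clears
  atoms2 <- atoms
  shift <- 0.8 * u
  atoms2$x <- atoms2$x + shift[1]; atoms2$y <- atoms2$y + shift[2]
  atoms2$z <- atoms2$z + shift[3]
  attr(atoms2, "kp_bonds") <- attr(atoms, "kp_bonds")
  expect_equal(unname(detect_interactions(
    res, curate_ligand_topology(atoms2))["hbond_acceptor"]), 0L)
})

test_that("fingerprints are always 595 bits with zero blocks at gaps", {
  fx <- generate_complex(fixture_spec(
    seed = 14, gaps = 42, contacts = list(list(slot = 47,
                                               type = "hbond_acceptor"))))
  pocket <- extract_pocket(NULL, fx$monomer)
  fp <- compute_ifp(pocket, fixture_ligand(fx))
  expect_length(fp, 595)
  expect_equal(as.integer(fp)[288:294], rep(0L, 7)) # block 42
  # designed contact: exactly one nonzero block, at the hinge slot
  blocks <- matrix(as.integer(fp), nrow = 7)
  expect_equal(which(colSums(blocks) > 0), 47)
})

test_that("apo structures give an all-zero fingerprint flagged apo", {
  fx <- generate_complex(fixture_spec(seed = 15))
  pocket <- extract_pocket(NULL, fx$monomer)
  fp <- compute_ifp(pocket, NULL)
  expect_length(fp, 595)
  expect_equal(sum(fp), 0L)
  expect_true(attr(fp, "apo"))
})

test_that("the fingerprint is invariant under joint rigid transforms", {
  fx <- shared_hinge_fixture()
  pocket <- extract_pocket(NULL, fx$monomer)
  lig <- fixture_ligand(fx)
  fp0 <- compute_ifp(pocket, lig)
  R <- kinpocket:::rotation_about(c(0.3, -1, 0.5), 117)
  t <- c(-8, 4, 12)
  pocket2 <- pocket
  pxyz <- as.matrix(pocket$atoms[, c("x", "y", "z")]) %*% R
  pocket2$atoms$x <- pxyz[, 1] + t[1]
  pocket2$atoms$y <- pxyz[, 2] + t[2]
  pocket2$atoms$z <- pxyz[, 3] + t[3]
  lig2 <- kinpocket:::transform_ligand(lig, R, t)
  expect_equal(as.integer(compute_ifp(pocket2, lig2)), as.integer(fp0))
})

test_that("fingerprint similarity is a Tanimoto with the all-zero convention", {
  mk <- function(idx) {
    bits <- integer(595); bits[idx] <- 1L
    kinpocket:::new_ifp(bits)
  }
  expect_equal(ifp_similarity(mk(c(1, 2, 3)), mk(c(1, 2, 3))), 1)
  expect_equal(ifp_similarity(mk(c(1, 2)), mk(c(3, 4))), 0)
  expect_equal(ifp_similarity(mk(c(1, 2, 3)), mk(c(2, 3, 4))), 0.5)
  expect_equal(ifp_similarity(mk(integer(0)), mk(integer(0))), 1)
  expect_error(ifp_similarity(mk(1), integer(10)), "length mismatch")
  # symmetry and bounds on random pairs
  set.seed(4)
  for (i in 1:10) {
    a <- mk(sample(595, 20)); b <- mk(sample(595, 20))
    expect_equal(ifp_similarity(a, b), ifp_similarity(b, a))
    expect_gte(ifp_similarity(a, b), 0)
    expect_lte(ifp_similarity(a, b), 1)
  }
})

test_that("pattern matching honours present/absent constraints", {
  fx <- shared_hinge_fixture()
  pocket <- extract_pocket(NULL, fx$monomer)
  fp <- compute_ifp(pocket, fixture_ligand(fx))
  expect_true(match_pattern(fp, kp_pattern()))
  expect_true(match_pattern(fp, kp_pattern(present = "47:hbond_acceptor")))
  expect_false(match_pattern(fp, kp_pattern(absent = "47:hbond_acceptor")))
  expect_false(match_pattern(fp, kp_pattern(present = "46:hbond_donor")))
  expect_error(kp_pattern(present = "99:hbond_donor"))
})

test_that("hex serialization round-trips fingerprints", {
  set.seed(5)
  bits <- integer(595); bits[sample(595, 40)] <- 1L
  fp <- kinpocket:::new_ifp(bits)
  hex <- ifp_to_hex(fp)
  expect_equal(nchar(hex), 150)
  expect_equal(as.integer(ifp_from_hex(hex)), bits)
})

test_that("detection agrees bit-for-bit with the brute-force oracle", {
  for (seed in 300:319) {
    toy <- random_toy_complex(seed)
    fp <- compute_ifp(toy$pocket, toy$ligand)
    expect_equal(as.integer(fp), oracle_ifp(toy$pocket, toy$ligand),
                 info = paste("toy complex seed", seed))
  }
})
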