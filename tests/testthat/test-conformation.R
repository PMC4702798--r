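test_that("a fully enclosed residue has near-zero accessible area", {
  # central atom caged by a dense shell of atoms
  shell <- kinpocket:::sphere_points(80) * 3
  xyz <- rbind(c(0, 0, 0), shell)
  asa <- shrake_rupley(xyz, rep("C", nrow(xyz)), subset = 1)
  expect_lt(asa, 1)
})

test_that("Shrake-Rupley matches an independent Monte-Carlo integrator", {
  # free aspartate-like fragment
  xyz <- rbind(CB = c(0, 0, 0), CG = c(1.5, 0, 0),
               OD1 = c(2.1, 1.1, 0), OD2 = c(2.1, -1.1, 0))
  el <- c("C", "C", "O", "O")
  asa <- shrake_rupley(xyz, el, n_points = 960)
  ref <- mc_sasa(xyz, el, subset = 1:4, n = 30000)
  expect_equal(asa, ref, tolerance = 0.02)
})

test_that("ASA is converged at the default sphere sampling", {
  fx <- generate_complex(fixture_spec(seed = 16))
  pocket <- extract_pocket(NULL, fx$monomer)
  a1 <- accessible_surface_area(pocket, 81, n_points = 960)
  a2 <- accessible_surface_area(pocket, 81, n_points = 1920)
  expect_lt(abs(a1 - a2) / a2, 0.01)
  expect_gte(a1, 0)
})

test_that("descriptors on GAP or truncated slots raise undefined errors", {
  fx <- generate_complex(fixture_spec(seed = 17, gaps = 81))
  pocket <- extract_pocket(NULL, fx$monomer)
  expect_error(accessible_surface_area(pocket, 81), "GAP")
  fx2 <- generate_complex(fixture_spec(seed = 17,
                                       truncations = list("81" = "CG")))
  pocket2 <- extract_pocket(NULL, fx2$monomer)
  expect_error(dfg_vectors(pocket2), "missing CA/CG")
  expect_equal(classify_dfg(list(asa_D81 = NA, yD = 1, yF = 1)), "unknown")
})

test_that("DFG vectors are y-components of Cgamma minus Calpha in the
           master frame", {
  fx <- generate_complex(fixture_spec(seed = 18, conf_jitter = 0,
                                      alpha_c = 0))
  pocket <- extract_pocket(NULL, fx$monomer)
  v <- dfg_vectors(pocket)
  expect_equal(unname(v), c(1.4, -1.3), tolerance = 1e-6)

  # rotating the raw structure first changes nothing after superposition
  mono_rot <- fx$monomer
  R <- kinpocket:::rotation_about(c(1, 2, 3), 65)
  xyz <- as.matrix(mono_rot$atoms[, c("x", "y", "z")]) %*% R
  mono_rot$atoms$x <- xyz[, 1] + 5
  mono_rot$atoms$y <- xyz[, 2] - 9
  mono_rot$atoms$z <- xyz[, 3] + 2
  pocket_rot <- extract_pocket(NULL, mono_rot)
  sp <- superpose(pocket_rot)
  pocket_rot$atoms <- transform_atoms(pocket_rot$atoms, sp)
  expect_equal(dfg_vectors(pocket_rot), v, tolerance = 1e-6)

  # the DFG-out template flips the Phe vector sign
  fx_out <- generate_complex(fixture_spec(seed = 18, dfg = "out",
                                          conf_jitter = 0, alpha_c = 0))
  v_out <- dfg_vectors(extract_pocket(NULL, fx_out$monomer))
  expect_lt(v[["yF"]] * v_out[["yF"]], 0)
  expect_lt(v[["yD"]] * v_out[["yD"]], 0)
})

test_that("the frozen tree reproduces fixture conformation labels", {
  for (cls in c("in", "out", "outlike")) {
    fx <- generate_complex(fixture_spec(seed = 19, dfg = cls))
    pocket <- extract_pocket(NULL, fx$monomer)
    sp <- superpose(pocket)
    pocket$atoms <- transform_atoms(pocket$atoms, sp)
    expect_equal(classify_dfg(conformation_descriptors(pocket)),
                 paste0("DFG-", cls))
  }
})

test_that("the training harness reaches the expected cross-validated
           accuracy on a small corpus", {
  corpus <- generate_corpus(45, seed = 3)
  desc <- purrr::map_dfr(corpus, function(fx) {
    pocket <- extract_pocket(NULL, fx$monomer)
    sp <- superpose(pocket)
    pocket$atoms <- transform_atoms(pocket$atoms, sp)
    d <- conformation_descriptors(pocket)
    d$dfg <- fx$manifest$dfg
    d
  })
  expect_gte(dfg_cv_accuracy(desc, k = 5), 0.95)
  # a freshly trained tree serialises and classifies identically
  tr <- train_dfg_tree(desc)
  f <- withr::local_tempfile(fileext = ".json")
  write_dfg_tree(tr$tree, f)
  reloaded <- load_dfg_tree(f)
  pred1 <- vapply(seq_len(nrow(desc)), function(i)
    classify_dfg(desc[i, ], tr$tree), character(1))
  pred2 <- vapply(seq_len(nrow(desc)), function(i)
    classify_dfg(desc[i, ], reloaded), character(1))
  expect_equal(pred1, pred2)
})

test_that("alphaC classes follow the Calpha-distance thresholds", {
  # boundary convention: d == t1 is still aC-in
  fx <- generate_complex(fixture_spec(seed = 20, alpha_c = 0,
                                      conf_jitter = 0))
  pocket <- extract_pocket(NULL, fx$monomer)
  d0 <- kinpocket:::vnorm(
    kinpocket:::slot_atom(pocket, 82, "CA") -
      kinpocket:::slot_atom(pocket, 24, "CA"))
  expect_equal(classify_alpha_c(pocket), "aC-in")
  expect_equal(classify_alpha_c(pocket, t1 = d0), "aC-in")
  expect_equal(classify_alpha_c(pocket, t1 = d0 - 0.01, t2 = d0 + 1),
               "aC-outlike")

  fx_out <- generate_complex(fixture_spec(seed = 20, alpha_c = 5.8,
                                          conf_jitter = 0))
  expect_equal(classify_alpha_c(extract_pocket(NULL, fx_out$monomer)),
               "aC-out")

  # monotone: growing the distance never moves the class inward
  rank <- c("aC-in" = 1, "aC-outlike" = 2, "aC-out" = 3)
  cls <- vapply(c(0, 1, 2, 3, 4.5, 6), function(shift) {
    fxs <- generate_complex(fixture_spec(seed = 20, alpha_c = shift,
                                         conf_jitter = 0))
    classify_alpha_c(extract_pocket(NULL, fxs$monomer))
  }, character(1))
  expect_true(all(diff(rank[cls]) >= 0))

  fx_gap <- generate_complex(fixture_spec(seed = 20, gaps = 24))
  expect_equal(classify_alpha_c(extract_pocket(NULL, fx_gap$monomer)),
               "unknown")
})

test_that("G-loop descriptors match the frozen master reference and are
           rigid-invariant", {
  fx <- generate_complex(fixture_spec(seed = 21, alpha_c = 0,
                                      conf_jitter = 0))
  pocket <- extract_pocket(NULL, fx$monomer)
  gl <- gloop_descriptors(pocket)
  # golden master-frame triple, frozen at model-build time
  expect_equal(unname(gl), c(74.62640, 17.20598, -27.11305),
               tolerance = 1e-4)

  mono_t <- fx$monomer
  mono_t$atoms$x <- mono_t$atoms$x + 12
  mono_t$atoms$y <- mono_t$atoms$y - 7
  expect_equal(gloop_descriptors(extract_pocket(NULL, mono_t)), gl,
               tolerance = 1e-6)

  # lifting the loop 3 A along the loop/catalytic-loop axis moves the
  # distance descriptor by ~3 A
  fx_lift <- generate_complex(fixture_spec(seed = 21, gloop_lift = 3,
                                           alpha_c = 0, conf_jitter = 0))
  gl_lift <- gloop_descriptors(extract_pocket(NULL, fx_lift$monomer))
  expect_equal(gl_lift[["distance"]] - gl[["distance"]], 3,
               tolerance = 0.05)

  fx_gap <- generate_complex(fixture_spec(seed = 21, gaps = 4:9))
  expect_error(gloop_descriptors(extract_pocket(NULL, fx_gap$monomer)),
               "GAP")
})

test_that("annotate_conformation bundles classes and raw descriptors", {
  fx <- generate_complex(fixture_spec(seed = 22, dfg = "outlike",
                                      alpha_c = "outlike"))
  pocket <- extract_pocket(NULL, fx$monomer)
  sp <- superpose(pocket)
  pocket$atoms <- transform_atoms(pocket$atoms, sp)
  ann <- annotate_conformation(pocket)
  expect_equal(ann$dfg, "DFG-outlike")
  expect_equal(ann$alpha_c, "aC-outlike")
  expect_s3_class(glance(ann), "tbl_df")
  expect_true(all(c("asa_D81", "yD", "yF") %in% names(glance(ann))))
})
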