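test_that("training on disjoint labelled clouds yields disjoint probe sets", {
  cloud <- function(ctr, n = 15, seed = 1) {
    set.seed(seed)
    sweep(matrix(rnorm(3 * n, 0, 0.5), ncol = 3), 2, ctr, "+")
  }
  training <- list(
    list(xyz = cloud(c(6, 0, 0), seed = 1), labels = "front_cleft"),
    list(xyz = cloud(c(6, 0.4, 0), seed = 2), labels = "front_cleft"),
    list(xyz = cloud(c(-5.5, 0, 0), seed = 3), labels = "back_cleft"),
    list(xyz = cloud(c(-5.5, 0.4, 0), seed = 4), labels = "back_cleft"))
  model <- suppressWarnings(train_subpocket_model(training))
  expect_true(all(c("front_cleft", "back_cleft") %in% names(model$probes)))
  d <- kinpocket:::pdist(model$probes$front_cleft, model$probes$back_cleft)
  expect_gt(min(d), 2)
})

test_that("indistinguishable positives and negatives retain no probes", {
  xyz <- kinpocket:::sphere_points(12) * 0.8
  training <- list(list(xyz = xyz, labels = "FP-I"),
                   list(xyz = xyz, labels = "FP-II"))
  model <- suppressWarnings(train_subpocket_model(training))
  expect_null(model$probes[["FP-I"]])
  expect_null(model$probes[["FP-II"]])
})

test_that("halving the grid spacing multiplies probe density ~8x", {
  set.seed(9)
  xyz <- matrix(rnorm(45, 0, 1), ncol = 3)
  training <- list(list(xyz = xyz, labels = "FP-I"))
  m1 <- suppressWarnings(train_subpocket_model(
    training, grid_spacing = 1.0, top_k = 1e6))
  m2 <- suppressWarnings(train_subpocket_model(
    training, grid_spacing = 0.5, top_k = 1e6))
  ratio <- nrow(m2$probes[["FP-I"]]) / nrow(m1$probes[["FP-I"]])
  expect_gt(ratio, 5)
  expect_lt(ratio, 12)
})

test_that("assignment flags fire on probe contact and stay off at >= 2 A", {
  model <- shared_subpocket_model()
  probe <- model$probes[["FP-I"]][1, , drop = FALSE]
  fl <- assign_subpockets(probe, model)
  expect_true(fl$flag[fl$label == "FP-I"])
  expect_true(fl$flag[fl$label == "front_cleft"]) # hierarchy
  far <- matrix(c(50, 50, 50), 1)
  expect_false(any(assign_subpockets(far, model)$flag))
  expect_error(assign_subpockets(far, list(probes = list(),
                                           contact_radius = 1)), "empty")
})

test_that("held-out label recovery meets the 95% target per label", {
  model <- shared_subpocket_model()
  test_set <- shared_subpocket_test_set()
  recov <- purrr::map_dfr(test_set, function(ex) {
    fl <- assign_subpockets(ex$xyz, model)
    tibble::tibble(label = fl$label, pred = fl$flag,
                   true = fl$label %in% ex$labels)
  })
  per_label <- recov |>
    dplyr::group_by(label) |>
    dplyr::summarise(acc = mean(pred == true))
  expect_gte(min(per_label$acc), 0.95)
})

test_that("flags are monotone in the ligand atom set", {
  model <- shared_subpocket_model()
  set.seed(31)
  for (i in 1:5) {
    ex <- shared_subpocket_test_set()[[i]]
    base <- assign_subpockets(ex$xyz, model)
    grown <- rbind(ex$xyz, matrix(runif(9, -10, 10), ncol = 3))
    more <- assign_subpockets(grown, model)
    expect_true(all(!base$flag | more$flag))
  }
})

test_that("a flagged subpocket always implies its major region", {
  model <- shared_subpocket_model()
  labs <- subpocket_labels()
  for (ex in shared_subpocket_test_set()) {
    fl <- assign_subpockets(ex$xyz, model)
    for (k in which(!is.na(fl$parent))) {
      if (fl$flag[k]) expect_true(fl$flag[fl$label == fl$parent[k]])
    }
  }
})

test_that("training is deterministic and the model file round-trips", {
  corpus <- generate_subpocket_corpus(30, seed = 5)
  m1 <- train_subpocket_model(corpus)
  m2 <- train_subpocket_model(corpus)
  expect_equal(m1$probes, m2$probes)
  d <- withr::local_tempdir()
  write_subpocket_model(m1, d)
  m3 <- read_subpocket_model(d)
  expect_equal(names(m3$probes), names(m1$probes))
  for (lab in names(m1$probes)) {
    expect_equal(m3$probes[[lab]], m1$probes[[lab]], tolerance = 1e-3,
                 ignore_attr = TRUE)
  }
})

test_that("waters assign to the nearest cluster with deterministic
           tie-breaks and a drop radius", {
  cl <- load_water_clusters()
  expect_equal(nrow(cl), 13)
  expect_equal(sum(cl$dfg_out_specific), 2)
  i5 <- as.numeric(cl[cl$label == "I5", c("x", "y", "z")])
  out <- assign_water_clusters(matrix(i5, 1), cl)
  expect_equal(out$cluster, "I5")
  # exactly between I4 and I5: lowest label index wins
  i4 <- as.numeric(cl[cl$label == "I4", c("x", "y", "z")])
  mid <- (i4 + i5) / 2
  out_mid <- assign_water_clusters(matrix(mid, 1), cl)
  expect_equal(out_mid$cluster, "I4")
  # 5 A from everything: dropped
  far <- i5 + c(5, 0, 0)
  expect_equal(nrow(assign_water_clusters(matrix(far, 1), cl)), 0)
})

test_that("water assignment partitions kept waters and scores H-bonds", {
  fx <- generate_complex(fixture_spec(seed = 23, waters = c("I2", "I5",
                                                            "off")))
  pocket <- extract_pocket(NULL, fx$monomer)
  out <- assign_water_clusters(fx$waters, pocket = pocket)
  expect_equal(sort(out$cluster), c("I2", "I5"))
  expect_equal(anyDuplicated(out$water), 0)
  expect_type(out$hbond_protein, "logical")
})

test_that("average-linkage clustering re-derives the 13 labelled centroids", {
  set.seed(8)
  sites <- kinpocket:::canonical_water_sites()
  waters <- do.call(rbind, lapply(seq_len(nrow(sites)), function(i) {
    sweep(matrix(rnorm(3 * 25, 0, 0.3), ncol = 3), 2,
          as.numeric(sites[i, c("x", "y", "z")]), "+")
  }))
  cl <- derive_water_clusters(waters, k = 13)
  expect_equal(nrow(cl), 13)
  expect_setequal(cl$label, sites$label)
  d <- sqrt(rowSums((as.matrix(cl[, c("x", "y", "z")]) -
                       as.matrix(sites[match(cl$label, sites$label),
                                       c("x", "y", "z")]))^2))
  expect_lt(max(d), 0.5)
})
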