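test_that("the empty query returns every record, ordered by entry id", {
  col <- search_fixture_collection()
  res <- evaluate_query(col, kp_query())
  expect_equal(nrow(res), length(col))
  expect_equal(res$entry_id, sort(res$entry_id))
})

test_that("gatekeeper + subpocket query isolates the selective binder", {
  col <- search_fixture_collection()
  q <- kp_query(pocket = c("45" = "T"),
                subpocket = c("front_cleft", "gate_area"),
                not_subpocket = "back_cleft")
  expect_equal(evaluate_query(col, q)$entry_id, "GK01_1A")
})

test_that("water-cluster and pocket-composition clauses combine", {
  col <- search_fixture_collection()
  both <- evaluate_query(col, kp_query(water = c("I4", "I5")))
  expect_setequal(both$entry_id, c("WAT01_1A", "WAT03_1A"))
  refined <- evaluate_query(col, kp_query(
    water = c("I4", "I5"),
    pocket = c("45" = "T", "36" = "V", "80" = "A")))
  expect_equal(refined$entry_id, "WAT01_1A")
})

test_that("interaction-similar but chemically-dissimilar search narrows
           the similarity-only result", {
  col <- search_fixture_collection()
  ref <- col[["IFP_REF_1A"]]
  sim_only <- evaluate_query(col, kp_query(ifp_ref = ref$ifp,
                                           ifp_min = 0.75))
  expect_true(all(c("IFP_REF_1A", "IFP_MIMIC_1A") %in% sim_only$entry_id))
  refined <- evaluate_query(col, kp_query(
    ifp_ref = ref$ifp, ifp_min = 0.75,
    ligand_ref = ref$ligand, ligand_kind = "circular", ligand_max = 0.25))
  expect_equal(refined$entry_id, "IFP_MIMIC_1A")
  expect_true(all(refined$entry_id %in% sim_only$entry_id))
  # ordering: descending similarity, then entry id
  expect_equal(sim_only$ifp_similarity, sort(sim_only$ifp_similarity,
                                             decreasing = TRUE))
})

test_that("interaction-pattern clauses work inside queries", {
  col <- search_fixture_collection()
  res <- evaluate_query(col, kp_query(
    pattern = kp_pattern(present = "46:hbond_donor",
                         absent = "17:ionic_pos")))
  expect_setequal(res$entry_id, c("IFP_REF_1A", "IFP_MIMIC_1A"))
})

test_that("adding clauses never grows the result set", {
  col <- search_fixture_collection()
  base <- evaluate_query(col, kp_query(pocket = c("45" = "T")))
  narrowed <- evaluate_query(col, kp_query(pocket = c("45" = "T"),
                                           water = "I4"))
  expect_true(all(narrowed$entry_id %in% base$entry_id))
  expect_lte(nrow(narrowed), nrow(base))
})

test_that("query evaluation is a pure function of records and query", {
  col <- search_fixture_collection()
  q <- kp_query(pocket = c("45" = "T"))
  expect_identical(evaluate_query(col, q), evaluate_query(col, q))
})

test_that("property presets bound ligand descriptors", {
  ro5 <- property_preset("rule_of_five")
  expect_equal(ro5$max[ro5$property == "mw"], 500)
  ro3 <- property_preset("rule_of_three")
  expect_equal(ro3$max[ro3$property == "rotatable"], 3)
  over <- property_preset("rule_of_five", overrides = list(mw = c(0, 600)))
  expect_equal(over$max[over$property == "mw"], 600)
  expect_error(property_preset("rule_of_seven"))

  in_range <- function(d, ranges) {
    all(vapply(seq_len(nrow(ranges)), function(k) {
      p <- ranges$property[k]
      !p %in% names(d) || (d[[p]] >= ranges$min[k] & d[[p]] <= ranges$max[k])
    }, logical(1)))
  }
  heavy <- tibble::tibble(mw = 550, logp = 2, hbd = 1, hba = 4,
                          rotatable = 5)
  small <- tibble::tibble(mw = 250, logp = 2, hbd = 2, hba = 3,
                          rotatable = 2)
  expect_false(in_range(heavy, property_preset("rule_of_five")))
  expect_true(in_range(small, property_preset("rule_of_three")))
})

test_that("property and quality clauses filter records", {
  col <- search_fixture_collection()
  all_bound <- evaluate_query(col, kp_query(preset = "rule_of_three"))
  expect_false("APO01_1A" %in% all_bound$entry_id) # apo has no ligand
  none <- evaluate_query(col, kp_query(ranges = list(mw = c(1e4, 2e4))))
  expect_equal(nrow(none), 0)
  qual <- evaluate_query(col, kp_query(quality_min = 9))
  expect_gt(nrow(qual), 0)
})

test_that("malformed clauses raise errors naming the clause", {
  expect_error(kp_query(ifp_min = 0.5), "ifp")
  expect_error(kp_query(ligand_min = 0.5), "ligand")
  expect_error(kp_query(pocket = c(foo = "T")), "pocket")
  expect_error(kp_query(pattern = "46:hbond_donor"), "pattern")
})

test_that("CSV export is RFC-4180 and round-trips", {
  col <- search_fixture_collection()
  res <- evaluate_query(col, kp_query())
  res$note <- paste0("a,b ", seq_len(nrow(res))) # force quoting
  f <- withr::local_tempfile(fileext = ".csv")
  export_results(res, f)
  lines <- readLines(f)
  expect_equal(length(lines), nrow(res) + 1)
  expect_true(grepl("\"a,b 1\"", paste(lines, collapse = "\n")))
  back <- readr::read_csv(f, show_col_types = FALSE)
  expect_equal(back$entry_id, res$entry_id)
  expect_equal(back$quality, res$quality)
  expect_equal(back$note, res$note)
})

test_that("chemical fingerprints behave as similarity measures", {
  fxa <- shared_hinge_fixture()
  la <- fixture_ligand(fxa)
  expect_equal(ligand_similarity(la, la), 1)
  expect_equal(ligand_similarity(la, la, "structural"), 1)
  expect_length(circular_fp(la), 1024)
  expect_length(structural_fp(la), 166)
  expect_equal(tanimoto(logical(10), logical(10)), 1)
  # tautomer-tolerant identity: same composition, shifted bond orders
  amide1 <- tibble::tibble(name = c("N1", "C1", "O1"),
                           element = c("N", "C", "O"),
                           x = c(0, 1.47, 2.1), y = c(0, 0, 1.05), z = 0,
                           resid = "LIG")
  attr(amide1, "kp_bonds") <- tibble::tibble(i = c(1L, 2L), j = c(2L, 3L),
                                             order = c("1", "2"))
  amide2 <- amide1
  attr(amide2, "kp_bonds") <- tibble::tibble(i = c(1L, 2L), j = c(2L, 3L),
                                             order = c("2", "1"))
  benzene <- tibble::tibble(
    name = paste0("C", 1:6), element = "C",
    x = 1.39 * cos((0:5) * pi / 3), y = 1.39 * sin((0:5) * pi / 3), z = 0,
    resid = "LIG")
  attr(benzene, "kp_bonds") <- tibble::tibble(i = 1:6, j = c(2:6, 1L),
                                              order = "ar")
  expect_true(same_compound(curate_ligand_topology(amide1),
                            curate_ligand_topology(amide2)))
  expect_false(same_compound(curate_ligand_topology(amide1),
                             curate_ligand_topology(benzene)))
})

test_that("record JSON serialization round-trips the searchable content", {
  col <- search_fixture_collection()
  d <- withr::local_tempdir()
  for (r in col) write_record_json(r, d)
  files <- list.files(d, pattern = "\\.json$", full.names = TRUE)
  expect_length(files, length(col))
  reloaded <- kp_collection(lapply(files, read_record_json))
  q <- kp_query(pocket = c("45" = "T"),
                subpocket = c("front_cleft", "gate_area"),
                not_subpocket = "back_cleft")
  expect_equal(evaluate_query(reloaded, q)$entry_id,
               evaluate_query(col, q)$entry_id)
  r0 <- col[[1]]
  r1 <- reloaded[[r0$ids$entry_id]]
  expect_equal(as.integer(r1$ifp), as.integer(r0$ifp))
  expect_equal(r1$conformation$dfg, r0$conformation$dfg)
  expect_equal(r1$quality$score, r0$quality$score)
})

test_that("records and collections expose tidy/glance/autoplot views", {
  col <- search_fixture_collection()
  tbl <- tidy(col)
  expect_equal(nrow(tbl), length(col))
  expect_true(all(c("entry_id", "dfg", "quality", "ifp_hex") %in%
                    names(tbl)))
  g1 <- glance(col[[1]])
  expect_equal(nrow(g1), 1)
  expect_s3_class(autoplot(col), "ggplot")
  expect_s3_class(autoplot(col[[1]]$ifp), "ggplot")
})
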