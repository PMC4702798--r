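#!/usr/bin/env Rscript
# Regenerates the versioned model/data files shipped under inst/extdata:
#   - dfg_tree.json      frozen DFG decision tree (CART on the synthetic
#                        conformational corpus, seed 1)
#   - water_clusters.csv conserved water-cluster centroids (average-linkage
#                        clustering of superposed synthetic pocket waters)
#   - master_profile.fasta / region_table.csv   master pocket profile
# Run from the repository root: Rscript scripts/build_models.R

suppressMessages(devtools::load_all("."))
library(dplyr)

extdata <- "inst/extdata"
dir.create(extdata, showWarnings = FALSE, recursive = TRUE)

# --- DFG tree --------------------------------------------------------------
corpus <- generate_corpus(120, seed = 1)
desc <- purrr::map_dfr(corpus, function(fx) {
  pocket <- extract_pocket(NULL, fx$monomer)
  sp <- superpose(pocket)
  pocket$atoms <- transform_atoms(pocket$atoms, sp)
  d <- conformation_descriptors(pocket)
  d$dfg <- fx$manifest$dfg
  d
})
tr <- train_dfg_tree(desc)
acc <- dfg_cv_accuracy(desc)
message("DFG tree training accuracy (10-fold CV): ", round(acc, 4))
write_dfg_tree(tr$tree, file.path(extdata, "dfg_tree.json"))

# --- water clusters --------------------------------------------------------
set.seed(42)
sites <- kinpocket:::canonical_water_sites()
waters <- purrr::map_dfr(seq_len(nrow(sites)), function(i) {
  n <- 40
  jit <- matrix(rnorm(3 * n), ncol = 3)
  jit <- jit / sqrt(rowSums(jit^2)) * runif(n, 0, 0.45)
  tibble(x = sites$x[i] + jit[, 1], y = sites$y[i] + jit[, 2],
         z = sites$z[i] + jit[, 3])
})
cl <- derive_water_clusters(as.matrix(waters), k = 13)
readr::write_csv(cl, file.path(extdata, "water_clusters.csv"))
message("water clusters written: ", nrow(cl))

# --- master profile --------------------------------------------------------
# the 85-column profile: consensus plus illustrative kinase-like variants
cons <- master_pocket_sequence()
vary <- function(seq, subs) {
  s <- strsplit(seq, "")[[1]]
  for (nm in names(subs)) s[as.integer(nm)] <- subs[[nm]]
  paste(s, collapse = "")
}
profile <- c(
  ">consensus" = cons,
  ">SYN_TK1" = vary(cons, c("45" = "M", "12" = "F", "36" = "L")),
  ">SYN_CMGC1" = vary(cons, c("24" = "D", "5" = "A", "60" = "V")),
  ">SYN_STE1" = vary(cons, c("45" = "F", "47" = "F", "71" = "I"))
)
writeLines(rbind(names(profile), unname(profile)),
           file.path(extdata, "master_profile.fasta"))
readr::write_csv(kp_regions(), file.path(extdata, "region_table.csv"))
message("master profile + region table written")
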