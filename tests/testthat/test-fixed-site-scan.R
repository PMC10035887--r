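# a hand-built 15-species orthogroup with known column patterns:
# col 1: fully conserved K
# col 2: human K, all others R          (human-strict candidate)
# col 3: apes V, others split L/I       (ape-relaxed only)
# col 4: human K, others R, one gap     (ineligible: gap column)
# col 5: apes V, others all L           (ape-strict candidate)
scanFixture <- function() {
  apes <- c("Homo_sapiens", "Pan_troglodytes", "Pan_paniscus",
            "Gorilla_gorilla", "Pongo_abelii")
  others <- paste0("Monkey", 1:10)
  species <- c(apes, others)
  cols <- matrix("", nrow = 15, ncol = 5, dimnames = list(species, NULL))
  cols[, 1] <- "K"
  cols[, 2] <- "R"; cols["Homo_sapiens", 2] <- "K"
  cols[, 3] <- rep_len(c("L", "I"), 15); cols[apes, 3] <- "V"
  cols[, 4] <- "R"; cols["Homo_sapiens", 4] <- "K"; cols["Monkey7", 4] <- "-"
  cols[, 5] <- "L"; cols[apes, 5] <- "V"
  og <- orthogroupFromColumns(cols, id = "SCN", gene = "SCN")
  ann <- new("SiteAnnotationTable", gene = "SCN",
             table = data.frame(column = 1:5, human_position = 1:5,
                                class = "ligand_binding",
                                ligand_types = "DNA"))
  list(og = og, ann = ann, apes = apes)
}

test_that("strict human scan calls sites with one human residue against a fixed background", {
  fx <- scanFixture()
  calls <- scanLineageSpecific(fx$og, fx$ann, "Homo_sapiens", "strict",
                               cladeName = "human")
  expect_identical(calls$column, 2L)
  expect_identical(calls$focal_residue, "K")
  expect_identical(calls$background_residues, "R")
  expect_identical(calls$mode, "human_strict")
})

test_that("ape strict requires a fixed background; relaxed only a non-overlapping one", {
  fx <- scanFixture()
  strict <- scanLineageSpecific(fx$og, fx$ann, fx$apes, "strict", "ape")
  relaxed <- scanLineageSpecific(fx$og, fx$ann, fx$apes, "relaxed", "ape")
  expect_identical(strict$column, 5L)
  expect_setequal(relaxed$column, c(5L, 3L))
  expect_identical(relaxed$background_residues[relaxed$column == 3L],
                   "I,L")
  # strict calls are a subset of relaxed calls
  expect_true(all(strict$column %in% relaxed$column))
})

test_that("conserved columns and gap-containing columns yield no calls", {
  fx <- scanFixture()
  human <- scanLineageSpecific(fx$og, fx$ann, "Homo_sapiens", "strict",
                               "human")
  expect_false(1L %in% human$column)   # conserved
  expect_false(4L %in% human$column)   # gap among retained species
  relaxedHuman <- scanLineageSpecific(fx$og, fx$ann, "Homo_sapiens",
                                      "relaxed", "human")
  expect_false(4L %in% relaxedHuman$column)
})

test_that("orthogroups missing focal taxa are skipped with a message", {
  fx <- scanFixture()
  expect_message(
    out <- scanLineageSpecific(fx$og, fx$ann, c(fx$apes, "Nomascus_leucogenys"),
                               "strict", "ape"),
    "skipped")
  expect_identical(nrow(out), 0L)
})

test_that("population filter applies the inclusive 0.01 frequency rule and disease flags", {
  fx <- scanFixture()
  calls <- scanLineageSpecific(fx$og, fx$ann, "Homo_sapiens", "strict",
                               "human")
  # no overlapping variant: pass
  v0 <- data.frame(gene = "SCN", position = 99, ref_aa = "K", alt_aa = "R",
                   allele_frequency = 0.5, disease_flag = FALSE)
  expect_true(applyPopulationFilter(calls, v0)$population_pass)
  # common variant at the site: fail
  v1 <- data.frame(gene = "SCN", position = 2, ref_aa = "K", alt_aa = "R",
                   allele_frequency = 0.05, disease_flag = FALSE)
  f1 <- applyPopulationFilter(calls, v1)
  expect_false(f1$population_pass)
  expect_identical(f1$reason, "common_variant")
  # frequency exactly 0.01 is fixed enough: pass
  v2 <- v1; v2$allele_frequency <- 0.01
  expect_true(applyPopulationFilter(calls, v2)$population_pass)
  # rare but disease-flagged: fail
  v3 <- v1; v3$allele_frequency <- 0.001; v3$disease_flag <- TRUE
  f3 <- applyPopulationFilter(calls, v3)
  expect_false(f3$population_pass)
  expect_identical(f3$reason, "disease_variant")
})

test_that("planted human-specific sites are recovered exactly on synthetic data", {
  cfg <- simulationConfig(n_orthogroups = 4, n_planted_human_specific = 5,
                          seed = 202)
  st <- simulateStudy(cfg)
  planted <- st$groundTruth[st$groundTruth$planted_human_specific, ]
  found <- do.call(rbind, lapply(st$orthogroups, function(og) {
    ann <- annotateOrthogroup(og, st$matches, st$profiles)
    calls <- scanLineageSpecific(og, ann, "Homo_sapiens", "strict", "human")
    applyPopulationFilter(calls, st$variants)
  }))
  key <- paste(found$gene, found$column)
  expect_true(all(paste(planted$gene, planted$column) %in% key))
  expect_true(all(found$population_pass[key %in%
                                          paste(planted$gene, planted$column)]))
  # every call the scanner makes is a genuine human-specific pattern
  for (i in seq_len(nrow(found))) {
    og <- st$orthogroups[[found$gene[i]]]
    col <- substring(as.character(msa(og)), found$column[i],
                     found$column[i])
    names(col) <- speciesNames(og)
    expect_false(col[["Homo_sapiens"]] %in% col[names(col) !=
                                                  "Homo_sapiens"])
    expect_length(unique(col[names(col) != "Homo_sapiens"]), 1L)
  }
})
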