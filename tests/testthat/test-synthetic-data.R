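test_that("binding-profile generation is deterministic and respects class probabilities", {
  p1 <- generateBindingProfiles(5, seed = 1)
  p2 <- generateBindingProfiles(5, seed = 1)
  expect_identical(p1, p2)

  # all frequencies forced to zero -> no position classifies as binding
  p0 <- generateBindingProfiles(4, seed = 2, pBinding = 0,
                                pNonBinding = 1)
  cls <- classifyDomainPosition(p0$binding_frequency, p0$cv_precision,
                                p0$ligand_type)
  expect_false(any(cls == "binding"))
  expect_true(all(cls == "non_binding"))

  # 20% of positions above the 0.10 cutoff at precision 0.9
  p20 <- generateBindingProfiles(40, seed = 3, pBinding = 0.20,
                                 precisionRange = c(0.9, 0.9))
  cls20 <- classifyDomainPosition(p20$binding_frequency, p20$cv_precision,
                                  p20$ligand_type)
  frac <- mean(cls20 == "binding")
  se <- sqrt(0.2 * 0.8 / nrow(p20))
  expect_lt(abs(frac - 0.20), 4 * se)
})

test_that("simulated orthogroups carry the planted rate structure", {
  phy <- loadReferenceTree()
  cfg <- simulationConfig(n_orthogroups = 6, seed = 101,
                          rate_multiplier_binding = 0.5)
  st <- simulateStudy(cfg)
  gt <- st$groundTruth
  isB <- gt$class == "ligand_binding"
  isO <- gt$class %in% c("other_within_domain", "other_outside_domain")
  expect_gt(sum(isB), 150)
  ratio <- mean(gt$true_rate[isB]) / mean(gt$true_rate[isO])
  expect_lt(abs(ratio - 0.5), 0.05)   # within 10% of the 0.5 multiplier

  # null configuration: no rate difference between classes
  cfgN <- simulationConfig(n_orthogroups = 6, seed = 102,
                           rate_multiplier_binding = 1)
  gtN <- simulateStudy(cfgN)$groundTruth
  isBN <- gtN$class == "ligand_binding"
  isON <- gtN$class %in% c("other_within_domain", "other_outside_domain")
  ratioN <- mean(gtN$true_rate[isBN]) / mean(gtN$true_rate[isON])
  expect_lt(abs(ratioN - 1), 0.2)
})

test_that("zero binding multiplier freezes binding columns except planted sites", {
  phy <- loadReferenceTree()
  profiles <- generateBindingProfiles(8, seed = 7)
  cfg <- simulationConfig(rate_multiplier_binding = 0, seed = 7)
  set.seed(7)
  sim <- simulateOrthogroup(phy, profiles, cfg, gene = "GZ", nPlanted = 2)
  charMat <- do.call(rbind, strsplit(as.character(msa(sim$orthogroup)), ""))
  gt <- sim$groundTruth
  for (j in which(gt$class == "ligand_binding")) {
    col <- charMat[, j]
    if (gt$planted_human_specific[j]) {
      expect_length(unique(col), 2L)
    } else {
      expect_length(unique(col), 1L)
    }
  }
})

test_that("planting more human-specific sites than available binding columns errors", {
  phy <- loadReferenceTree()
  profiles <- generateBindingProfiles(8, seed = 9)
  cfg <- simulationConfig(seq_length_range = c(40L, 50L), seed = 9)
  set.seed(9)
  expect_error(simulateOrthogroup(phy, profiles, cfg, nPlanted = 10000),
               "planted")
})

test_that("studies are byte-identical under a fixed configuration", {
  cfg <- simulationConfig(n_orthogroups = 2, seed = 77,
                          n_planted_human_specific = 1)
  s1 <- simulateStudy(cfg)
  s2 <- simulateStudy(cfg)
  expect_identical(lapply(s1$orthogroups, function(o)
    as.character(msa(o))), lapply(s2$orthogroups, function(o)
      as.character(msa(o))))
  expect_identical(s1$groundTruth, s2$groundTruth)
  expect_identical(s1$variants, s2$variants)
  expect_identical(s1$go, s2$go)
})

test_that("population variants respect the frequency mixture and planted-site safety", {
  cfg <- simulationConfig(n_orthogroups = 8, seed = 55,
                          n_planted_human_specific = 6,
                          variant_maf_mix = list(p_variant = 0.2,
                                                 p_common = 0.10,
                                                 p_disease = 0.02))
  st <- simulateStudy(cfg)
  v <- st$variants
  expect_gt(nrow(v), 100)
  expect_true(all(v$allele_frequency >= 0 & v$allele_frequency <= 1))
  fracCommon <- mean(v$allele_frequency > 0.01)
  se <- sqrt(0.1 * 0.9 / nrow(v))
  expect_lt(abs(fracCommon - 0.10), 4 * se)
  planted <- st$groundTruth[st$groundTruth$planted_human_specific, ]
  key <- paste(v$gene, v$position)
  pv <- v[key %in% paste(planted$gene, planted$column), , drop = FALSE]
  if (nrow(pv)) {
    expect_true(all(pv$allele_frequency <= 0.01))
    expect_false(any(pv$disease_flag))
  }

  # no orthogroups -> empty table with the full schema
  empty <- generatePopulationVariants(list(), st$groundTruth[0, ], cfg)
  expect_identical(nrow(empty), 0L)
  expect_true(all(c("gene", "position", "ref_aa", "alt_aa",
                    "allele_frequency", "disease_flag") %in% names(empty)))
})

test_that("GO annotation generation is deterministic and plants real enrichment", {
  genes <- sprintf("G%03d", 1:200)
  a1 <- generateGoAnnotations(genes, nTerms = 10, seed = 5)
  a2 <- generateGoAnnotations(genes, nTerms = 10, seed = 5)
  expect_identical(a1, a2)
  expect_error(generateGoAnnotations(genes, plantedGenes = "NOPE"),
               "subset")

  # planted term covering a 50-gene study set vs ~5% background
  study <- genes[1:50]
  ann <- generateGoAnnotations(genes, nTerms = 10, plantedTerm = "GO:X",
                               plantedGenes = study, seed = 6,
                               baseRateRange = c(0.05, 0.05))
  hit <- unique(ann$gene[ann$term_id == "GO:X"])
  p <- hyperTail(length(intersect(hit, study)), length(hit), 200, 50)
  expect_lt(p, 1e-10)
})

test_that("without a planted term, no term reaches FDR < 0.05 in most seeds", {
  genes <- sprintf("G%03d", 1:150)
  hits <- vapply(1:50, function(s) {
    ann <- generateGoAnnotations(genes, nTerms = 20, seed = 400 + s)
    study <- sample(genes, 40)
    res <- goOverrepresentation(study, genes, ann)
    any(res$significant)
  }, logical(1))
  expect_gte(mean(!hits), 0.9)
})
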