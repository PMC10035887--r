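test_that("domain positions classify by frequency and ligand-specific precision thresholds", {
  expect_identical(classifyDomainPosition(0.15, 0.60, "DNA"), "binding")
  expect_identical(classifyDomainPosition(0.0, 0.9, "peptide"), "non_binding")
  expect_identical(classifyDomainPosition(0.15, 0.60, "ion"), "excluded")
  expect_identical(classifyDomainPosition(0.15, 0.80, "ion"), "binding")
  expect_identical(classifyDomainPosition(0.05, 0.99, "RNA"), "excluded")
  # boundary: cutoffs are inclusive
  expect_identical(classifyDomainPosition(0.10, 0.50, "small_molecule"),
                   "binding")
  expect_error(classifyDomainPosition(1.2, 0.5, "DNA"), "\\[0, 1\\]")
  expect_error(classifyDomainPosition(0.5, 0.5, "sugar"), "ligand")
})

test_that("raising the frequency cutoff never increases the binding-site count", {
  set.seed(41)
  f <- runif(300); p <- runif(300, 0.4, 1)
  lt <- sample(c("DNA", "ion", "peptide"), 300, TRUE)
  counts <- vapply(seq(0, 1, by = 0.1), function(cut)
    sum(classifyDomainPosition(f, p, lt, frequencyCutoff = cut) == "binding"),
    numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("labels transfer through matches with binding > excluded > non_binding precedence", {
  profiles <- rbind(
    allBindingProfile("D_ION", len = 5, ligand = "ion", precision = 0.9),
    data.frame(domain_id = "D_PEP", ligand_type = "peptide",
               match_state = 1:5, binding_frequency = 0,
               cv_precision = 0.9),
    data.frame(domain_id = "D_EXC", ligand_type = "RNA",
               match_state = 1:5, binding_frequency = 0.05,
               cv_precision = 0.9))
  # overlapping matches at positions 3..7 (ion binding) and 1..5 (peptide
  # non-binding), 6..10 excluded RNA
  matches <- rbind(matchRows("G1", "D_PEP", 1:5, 1:5),
                   matchRows("G1", "D_ION", 1:5, 3:7),
                   matchRows("G1", "D_EXC", 1:5, 6:10))
  lab <- transferAnnotations("G1", 12, matches, profiles)
  expect_identical(lab$class[1:2], rep("other_within_domain", 2))
  expect_identical(lab$class[3:7], rep("ligand_binding", 5))
  expect_identical(lab$ligand_types[3], "ion")
  expect_identical(lab$class[8:10], rep("excluded", 3))
  expect_identical(lab$class[11:12], rep("other_outside_domain", 2))

  # permuting the order of matches changes nothing
  perm <- matches[sample(nrow(matches)), ]
  expect_identical(transferAnnotations("G1", 12, perm, profiles), lab)
})

test_that("multi-ligand positions union their ligand types", {
  profiles <- rbind(allBindingProfile("D1", 4, "DNA"),
                    allBindingProfile("D2", 4, "ion"))
  matches <- rbind(matchRows("G1", "D1", 1:4, 1:4),
                   matchRows("G1", "D2", 1:4, 3:6))
  lab <- transferAnnotations("G1", 6, matches, profiles)
  expect_identical(lab$ligand_types[3], "DNA,ion")
  expect_identical(lab$ligand_types[1], "DNA")
  expect_identical(lab$ligand_types[5], "ion")
})

test_that("a match state absent from the profile fails, naming domain and index", {
  profiles <- allBindingProfile("D1", 4, "DNA")
  matches <- matchRows("G1", "D1", 1:6, 1:6)
  expect_error(transferAnnotations("G1", 10, matches, profiles),
               "D1.*5")
})

test_that("projection to columns respects human gaps and round-trips", {
  # gapless human: columns equal positions
  og <- Orthogroup(c(Homo_sapiens = "AKLV", Pan_troglodytes = "AKLV"),
                   id = "OG1")
  lab <- data.frame(position = 1:4,
                    class = c("ligand_binding", "other_within_domain",
                              "excluded", "other_outside_domain"),
                    ligand_types = c("DNA", "", "", ""))
  ann <- projectToColumns(og, lab)
  expect_identical(siteTable(ann)$class, lab$class)
  expect_identical(siteTable(ann)$human_position, 1:4)

  # leading human gap shifts everything by one column
  og2 <- Orthogroup(c(Homo_sapiens = "-AKLV", Pan_troglodytes = "MAKLV"),
                    id = "OG2")
  ann2 <- projectToColumns(og2, lab)
  tab2 <- siteTable(ann2)
  expect_identical(tab2$class[1], "unannotated")
  expect_true(is.na(tab2$human_position[1]))
  expect_identical(tab2$class[-1], lab$class)

  # random gap pattern: ungapping the labelled columns recovers the labels
  set.seed(11)
  for (i in 1:5) {
    n <- 30
    gaps <- sort(sample(n, 8))
    human <- rep("A", n); human[gaps] <- "-"
    other <- sample(AA20, n, TRUE)
    og3 <- Orthogroup(c(Homo_sapiens = paste(human, collapse = ""),
                        Pan_troglodytes = paste(other, collapse = "")),
                      id = "OG3")
    lab3 <- data.frame(position = seq_len(n - 8),
                       class = sample(c("ligand_binding",
                                        "other_within_domain",
                                        "other_outside_domain", "excluded"),
                                      n - 8, TRUE),
                       ligand_types = "ion")
    lab3$ligand_types[lab3$class != "ligand_binding"] <- ""
    tab3 <- siteTable(projectToColumns(og3, lab3))
    expect_identical(tab3$class[human != "-"], lab3$class)
    expect_identical(tab3$class[human == "-"], rep("unannotated", 8))
  }

  # length mismatch reports both lengths
  expect_error(projectToColumns(og, lab[1:3, ]), "3.*4")
})

test_that("site classes partition the human residues of an annotated orthogroup", {
  set.seed(21)
  cfg <- simulationConfig(n_orthogroups = 3, seed = 21)
  st <- simulateStudy(cfg)
  for (og in st$orthogroups) {
    ann <- annotateOrthogroup(og, st$matches, st$profiles)
    tab <- siteTable(ann)
    nHuman <- sum(strsplit(as.character(msa(og)[[og@humanSpecies]]),
                           "")[[1]] != "-")
    expect_identical(sum(tab$class != "unannotated"), as.integer(nHuman))
    expect_gt(sum(tab$class == "ligand_binding"), 0)
  }
})
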