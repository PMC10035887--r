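test_that("conservation table counts classes and multi-ligand sites correctly", {
  mets <- data.frame(
    class = c(rep("ligand_binding", 10), rep("other_within_domain", 6),
              rep("other_outside_domain", 4)),
    ligand_types = c(rep("DNA", 9), "DNA,ion", rep("", 10)),
    variable = c(rep(FALSE, 9), TRUE, rep(c(TRUE, FALSE), 3),
                 rep(FALSE, 4)))
  tab <- conservationTable(mets)
  lb <- tab[tab$class == "ligand_binding", ]
  expect_equal(lb$n_sites, 10)
  expect_equal(lb$percent_conserved, 90)
  expect_equal(tab$n_sites[tab$class == "DNA"], 10)
  expect_equal(tab$n_sites[tab$class == "ion"], 1)
  expect_equal(tab$n_sites[tab$class == "other_sites"], 10)
  expect_equal(tab$n_sites[tab$class == "other_sites_within_domains"], 6)
})

test_that("conservation summaries add over disjoint orthogroup subsets", {
  set.seed(37)
  mets <- data.frame(
    orthogroup = sample(c("a", "b", "c"), 200, TRUE),
    class = sample(c("ligand_binding", "other_within_domain",
                     "other_outside_domain"), 200, TRUE),
    ligand_types = "", variable = sample(c(TRUE, FALSE), 200, TRUE))
  mets$ligand_types[mets$class == "ligand_binding"] <- "RNA"
  whole <- conservationTable(mets)
  parts <- lapply(split(mets, mets$orthogroup), conservationTable)
  summed <- Reduce(function(x, y) {
    x$n_sites <- x$n_sites + y$n_sites
    x$n_conserved <- x$n_conserved + y$n_conserved
    x
  }, parts)
  expect_equal(whole$n_sites, summed$n_sites)
  expect_equal(whole$n_conserved, summed$n_conserved)
})

test_that("Fisher 2x2 matches enumeration, fisher.test, and is table-symmetric", {
  expect_equal(fisherExact2x2(matrix(c(5, 5, 5, 5), 2)), 1)
  # full enumeration for margins (4,4)x(4,4): five possible tables
  tab <- matrix(c(3, 1, 1, 3), 2, byrow = TRUE)
  dh <- dhyper(0:4, 4, 4, 4)
  manual <- sum(dh[dh <= dh[4] + 1e-12])   # observed x = 3
  expect_equal(fisherExact2x2(tab), manual, tolerance = 1e-12)
  set.seed(43)
  for (i in 1:10) {
    t2 <- matrix(rpois(4, 15), 2)
    if (any(rowSums(t2) == 0) || any(colSums(t2) == 0)) next
    p <- fisherExact2x2(t2)
    expect_equal(p, fisher.test(t2)$p.value, tolerance = 1e-9)
    expect_equal(p, fisherExact2x2(t(t2)), tolerance = 1e-12)
    expect_equal(p, fisherExact2x2(t2[2:1, 2:1]), tolerance = 1e-12)
  }
  # million-scale counts stay finite and agree with fisher.test
  big <- matrix(c(60518, 7305, 916497, 166473), 2, byrow = TRUE)
  expect_equal(fisherExact2x2(big), fisher.test(big)$p.value,
               tolerance = 1e-6)
  expect_warning(pz <- fisherExact2x2(matrix(c(0, 0, 3, 4), 2,
                                             byrow = TRUE)), "margin")
  expect_equal(pz, 1)
})

test_that("Mann-Whitney U handles exact, tied and asymptotic regimes", {
  expect_equal(mannWhitneyU(c(1, 2, 3), c(1, 2, 3))$p.value, 1)
  expect_equal(mannWhitneyU(c(1, 2), c(3, 4))$p.value, 2 / 6)
  set.seed(47)
  # exact, no ties: agree with wilcox.test
  x <- rnorm(8); y <- rnorm(10)
  expect_equal(mannWhitneyU(x, y)$p.value,
               wilcox.test(x, y, exact = TRUE)$p.value, tolerance = 1e-12)
  # large samples with ties: agree with the corrected normal approximation
  x <- sample(1:8, 300, TRUE); y <- sample(1:8, 250, TRUE) + 0.5
  expect_equal(mannWhitneyU(x, y)$p.value,
               wilcox.test(x, y, exact = FALSE, correct = TRUE)$p.value,
               tolerance = 1e-9)
})

test_that("Mann-Whitney U rejects at the nominal level under the null", {
  set.seed(53)
  rej <- mean(replicate(400, {
    mannWhitneyU(rnorm(40), rnorm(40))$p.value < 0.05
  }))
  expect_gt(rej, 0.02); expect_lt(rej, 0.09)
})

test_that("Kruskal-Wallis H matches the rank formula and degenerate input rules", {
  kw <- kruskalWallis(list(1:3, 4:6, 7:9))
  expect_equal(kw$statistic, 7.2, tolerance = 1e-12)  # hand-evaluated
  expect_equal(kw$df, 2)
  kw0 <- kruskalWallis(list(rep(2, 4), rep(2, 4), rep(2, 4)))
  expect_equal(kw0$statistic, 0)
  expect_equal(kw0$p.value, 1)
  expect_error(kruskalWallis(list(1:3)), "two groups")
  expect_error(kruskalWallis(list(1:3, numeric())), "non-empty")
})

test_that("Conover post-hoc matches an independent oracle and separates groups", {
  g <- list(a = rep(1, 5), b = rep(1, 5), c = rep(1, 5), d = rep(1, 5),
            e = rep(1, 5))
  res <- conoverPosthoc(g)
  expect_true(all(res$adj_p == 1))

  g2 <- list(lo = c(1, 2, 3, 2, 1), mid = c(10, 11, 12, 10, 13),
             hi = c(30, 31, 29, 32, 33))
  r2 <- conoverPosthoc(g2)
  expect_true(all(r2$adj_p < 0.05))
  expect_identical(r2$direction[r2$group_a == "lo" & r2$group_b == "hi"],
                   "col_faster")
  expect_identical(r2$direction[r2$group_a == "hi" & r2$group_b == "lo"],
                   character(0))

  set.seed(59)
  for (i in 1:5) {
    k <- sample(3:5, 1)
    g3 <- lapply(seq_len(k), function(j) rnorm(sample(6:15, 1), mean = j / 2))
    names(g3) <- letters[seq_len(k)]
    expect_equal(conoverPosthoc(g3)$adj_p, unname(conoverOracle(g3)),
                 tolerance = 1e-8)
  }
})

test_that("conservationFisher reconstructs 2x2 tables from summary rows", {
  summ <- data.frame(class = c("x", "y"), n_sites = c(100, 200),
                     n_conserved = c(90, 120))
  expect_equal(conservationFisher(summ, "x", "y"),
               fisher.test(matrix(c(90, 10, 120, 80), 2,
                                  byrow = TRUE))$p.value,
               tolerance = 1e-9)
  expect_error(conservationFisher(summ, "x", "z"), "not found")
})
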