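# Forward simulator and group-set/expression generators.

test_that("zero branch lengths copy the root and omega ~ 0 forbids
          nonsynonymous change", {
  phy <- ape::read.tree(text = "((a:0,b:0):0,c:0);")
  tr <- labeledTree(phy, "a")
  par <- modelAParams(2, 0.5, 1, 0.7, 0.3, codonFrequencies(rep(1, 61)))
  sim <- simulateAlignment(tr, par, 50, seed = 1, model = "A1")
  expect_identical(sim$alignment@seqs[1, ], sim$alignment@seqs[2, ])
  expect_identical(sim$alignment@seqs[1, ], sim$alignment@seqs[3, ])

  # one long branch, omega at the domain floor, all sites purifying:
  # no nonsynonymous differences survive
  phy2 <- ape::read.tree(text = "(a:3,b:0);")
  tr2 <- labeledTree(phy2, "a")
  par2 <- modelAParams(2, 1e-6, 1, 1 - 1e-9, 1e-9,
                       codonFrequencies(rep(1, 61)))
  sim2 <- simulateAlignment(tr2, par2, 4000, seed = 2, model = "A1")
  aa <- translateCodon(senseCodons())
  s <- sim2$alignment@states
  diffAa <- aa[s[1, ]] != aa[s[2, ]]
  expect_lte(sum(diffAa), 2)  # omega = 1e-6 leaves ~0 of them
  # but synonymous changes did happen on a branch of length 3
  expect_gt(sum(s[1, ] != s[2, ]), 100)
})

test_that("site classes are drawn at the model proportions", {
  fx <- fixtureAlignment(nSites = 2, seed = 1)
  par <- modelAParams(2, 0.2, 4, 0.5, 0.3, codonFrequencies(rep(1, 61)))
  sim <- simulateAlignment(fx$tree, par, 10000, seed = 3, model = "A")
  emp <- table(factor(sim$siteClasses, c("0", "1", "2a", "2b"))) / 10000
  expect_equal(as.numeric(emp), unname(siteClassProportions(par)),
               tolerance = 0.02)
})

test_that("single-branch empirical transitions match the mixture of
          P(t) rows (chi-square goodness of fit)", {
  phy <- ape::read.tree(text = "(a:0.5,b:0);")
  tr <- labeledTree(phy, "a")
  pi <- codonFrequencies(rep(1, 61))
  par <- modelAParams(2.5, 0.2, 4, 0.55, 0.25, pi)
  n <- 50000
  sim <- simulateAlignment(tr, par, n, seed = 4, model = "A")
  s <- sim$alignment@states
  # b sits at the root (zero branch); a is one P(0.5) step away, under
  # the common-scale convention, mixed over site classes
  tab <- siteClassTable(par, "A")
  uQ <- function(om) buildRateMatrix(par@kappa, om, pi, scale = FALSE)@q
  rate <- function(om) -sum(pi@pi * diag(uQ(om)))
  f <- sum(tab$proportion * vapply(tab$omegaBackground, rate, 0))
  Pmix <- Reduce(`+`, lapply(1:4, function(k)
    tab$proportion[k] *
      as.matrix(Matrix::expm(uQ(tab$omegaForeground[k]) / f * 0.5))))
  obs <- table(factor(s[2, ], levels = 1:61),
               factor(s[1, ], levels = 1:61))
  exp_ <- outer(pi@pi, rep(1, 61)) * Pmix * n
  keep <- exp_ >= 5
  chi <- sum((obs[keep] - exp_[keep])^2 / exp_[keep])
  df <- sum(keep) - 1
  expect_gt(pchisq(chi, df, lower.tail = FALSE), 0.01)
})

test_that("group sets are deterministic, allocate truth exactly and
          exercise the filters", {
  gs1 <- simulateGroupSet(10, fracForeSelected = 0.2,
                          fracCounterSelected = 0.1,
                          nSitesRange = c(30, 60), seed = 17,
                          shortSeqRate = 1)
  gs2 <- simulateGroupSet(10, fracForeSelected = 0.2,
                          fracCounterSelected = 0.1,
                          nSitesRange = c(30, 60), seed = 17,
                          shortSeqRate = 1)
  # byte-identical regeneration
  expect_identical(lapply(gs1@groups, function(g) g@alignment@seqs),
                   lapply(gs2@groups, function(g) g@alignment@seqs))
  expect_identical(gs1@truth, gs2@truth)
  # deterministic truth allocation
  expect_identical(sum(gs1@truth$truth == "foreground-selected"), 2L)
  expect_identical(sum(gs1@truth$truth == "counter-foreground-selected"),
                   1L)
  # every group covered exactly once
  expect_setequal(gs1@truth$groupId,
                  vapply(gs1@groups, function(g) g@groupId, ""))
  # shortSeqRate = 1: groups with ingroup taxa carry one truncated
  # sequence that the length filter must drop
  withIngroup <- Filter(function(g)
    any(g@speciesRoles == "ingroup"), gs1@groups)
  dropped <- vapply(withIngroup, function(g)
    nrow(filterShortSequences(g)$dropped), 0L)
  expect_true(all(dropped >= 1L))
  expect_error(simulateGroupSet(10, fracForeSelected = 0.9,
                                fracCounterSelected = 0.3, seed = 1),
               "fractions")
})

test_that("the on-disk layout round-trips through the readers", {
  gs <- simulateGroupSet(3, fracForeSelected = 0, nTaxaRange = c(5, 6),
                         nSitesRange = c(20, 30), seed = 23)
  dir <- tempfile()
  writeGroupSet(gs, dir)
  expect_true(file.exists(file.path(dir, "truth.tsv")))
  back <- readGroupsDir(dir)
  expect_length(back, 3L)
  expect_identical(back[[1]]@alignment@seqs, gs@groups[[1]]@alignment@seqs)
  expect_setequal(back[[2]]@tree$tip.label, gs@groups[[2]]@tree$tip.label)
  expect_identical(unname(back[[1]]@speciesRoles["fg_species"]),
                   "foreground-species")
})

test_that("expression tables honour their probabilities and layout", {
  ids <- sprintf("G%04d", 1:1000)
  tissues <- c("salivary_gland", "midgut", "fat_body", "spermatophore")
  all1 <- simulateExpressionTable(ids, tissues, pExpressed = 1, seed = 1)
  expect_true(all(all1$expressed))
  expect_identical(nrow(all1), 4000L)
  none <- simulateExpressionTable(ids, tissues, pExpressed = 0, seed = 1)
  expect_false(any(none$expressed))
  half <- simulateExpressionTable(ids, tissues, pExpressed = 0.5,
                                  seed = 2)
  counts <- tapply(half$expressed, half$tissue, sum)
  sigma <- sqrt(1000 * 0.25)
  expect_true(all(abs(counts - 500) <= 3 * sigma))
  # regulation rows: separate contrast-labelled rows, valid statuses
  reg <- simulateExpressionTable(ids[1:50], tissues,
                                 contrasts = c("apo", "inf"),
                                 pRegulated = 1, seed = 3)
  rr <- reg[!is.na(reg$contrast), ]
  expect_setequal(unique(rr$contrast), c("apo", "inf"))
  expect_true(all(rr$regulation %in% c("up", "down", "unchanged")))
  expect_error(simulateExpressionTable(ids, character()), "non-empty")
})
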