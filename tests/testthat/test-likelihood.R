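# Branch-site likelihood: class structure, pruning vs exhaustive
# enumeration, structural invariances, empirical Bayes posteriors.

test_that("site-class table derives the 2a/2b proportions correctly", {
  p <- modelAParams(2, 0.3, 4, 0.6, 0.2, codonFrequencies(rep(1, 61)))
  tab <- siteClassTable(p, "A")
  expect_equal(tab$proportion, c(0.6, 0.2, 0.15, 0.05))
  expect_equal(tab$omegaForeground, c(0.3, 1, 4, 4))
  expect_equal(tab$omegaBackground, c(0.3, 1, 0.3, 1))
  expect_equal(sum(siteClassProportions(p)), 1, tolerance = 1e-12)

  # symmetric case p0 = p1 = 0.25 -> p2a = p2b = 0.25
  ps <- modelAParams(2, 0.3, 4, 0.25, 0.25, codonFrequencies(rep(1, 61)))
  expect_equal(unname(siteClassProportions(ps)),
               c(0.25, 0.25, 0.25, 0.25))
  # degenerate p0 = 1: single effective class
  pd <- modelAParams(2, 0.3, 4, 1, 0, codonFrequencies(rep(1, 61)))
  expect_equal(unname(siteClassProportions(pd)), c(1, 0, 0, 0))
  # null model table forces omega2 = 1
  expect_equal(siteClassTable(p, "A1")$omegaForeground, c(0.3, 1, 1, 1))
  expect_error(modelAParams(2, 0.3, 4, 0.8, 0.4,
                            codonFrequencies(rep(1, 61))))
})

codonsFor <- function(idx) paste(senseCodons()[idx], collapse = "")

test_that("pruning equals exhaustive enumeration on a 3-taxon tree", {
  set.seed(21)
  pi <- codonFrequencies(runif(61, 0.3, 2))
  params <- modelAParams(2.2, 0.25, 3.5, 0.55, 0.25, pi)
  phy <- ape::read.tree(text = "(a:0.2,b:0.3,c:0.4);")
  tr <- labeledTree(phy, "a")
  edges <- rbind(c("r", "a"), c("r", "b"), c("r", "c"))
  blens <- c(0.2, 0.3, 0.4)

  cols <- list(c(a = 5L, b = 9L, c = 5L),
               c(a = 33L, b = 33L, c = 33L),
               c(a = 12L, b = NA, c = 48L))
  for (model in c("A", "A1")) {
    for (cl in cols) {
      seqs <- vapply(cl, function(s)
        if (is.na(s)) "---" else senseCodons()[s], "")
      aln <- codonAlignment(seqs, "fix")
      got <- totalLogLikelihood(aln, tr, params, model)@lnL
      want <- log(oracleColumnLik(cl, edges, blens, 1L, params, model))
      expect_equal(got, want, tolerance = 1e-8)
    }
  }
})

test_that("pruning equals exhaustive enumeration with two internal
          nodes, including gap and ambiguity columns", {
  set.seed(22)
  pi <- codonFrequencies(runif(61, 0.5, 1.5))
  params <- modelAParams(1.8, 0.15, 5, 0.5, 0.3, pi)
  phy <- ape::read.tree(text = "((a:0.2,b:0.3):0.15,c:0.25,d:0.4);")
  tr <- labeledTree(phy, "a")
  # oracle edge list mirrors the same topology rooted at the basal node
  edges <- rbind(c("r", "u"), c("u", "a"), c("u", "b"),
                 c("r", "c"), c("r", "d"))
  blens <- c(0.15, 0.2, 0.3, 0.25, 0.4)
  fgE <- 2L

  cols <- list(c(a = 10L, b = 20L, c = 30L, d = 40L),
               c(a = 7L, b = 7L, c = 7L, d = 7L),
               c(a = 61L, b = NA, c = 1L, d = 61L))
  codons <- senseCodons()
  for (cl in cols) {
    seqs <- vapply(cl, function(s) if (is.na(s)) "---" else codons[s], "")
    aln <- codonAlignment(seqs, "fix")
    got <- totalLogLikelihood(aln, tr, params, "A")@lnL
    want <- log(oracleColumnLik(cl, edges, blens, fgE, params, "A"))
    expect_equal(got, want, tolerance = 1e-8)
  }

  # ambiguity codon is treated exactly like a gap (missing data)
  alnGap <- codonAlignment(c(a = "---", b = codons[3], c = codons[9],
                             d = codons[9]), "g1")
  alnAmb <- codonAlignment(c(a = "ANG", b = codons[3], c = codons[9],
                             d = codons[9]), "g2")
  expect_equal(totalLogLikelihood(alnGap, tr, params, "A")@lnL,
               totalLogLikelihood(alnAmb, tr, params, "A")@lnL,
               tolerance = 1e-12)

  # an all-gap column carries no information: log-likelihood 0
  alnAll <- codonAlignment(c(a = "---", b = "---", c = "---", d = "---"),
                           "g3")
  expect_equal(totalLogLikelihood(alnAll, tr, params, "A")@lnL, 0,
               tolerance = 1e-10)
})

test_that("likelihood is invariant to taxon order and column order,
          and duplicating columns doubles lnL", {
  fx <- fixtureAlignment(nSites = 30, seed = 5, omega2 = 3, nTaxa = 5)
  params <- fx$params
  params@branchLengths <- numeric(0)
  base <- totalLogLikelihood(fx$alignment, fx$tree, params, "A")

  # taxon reordering
  perm <- rev(fx$alignment@taxa)
  seqs <- setNames(apply(fx$alignment@seqs, 1, paste, collapse = ""),
                   fx$alignment@taxa)[perm]
  alnP <- codonAlignment(seqs, "perm")
  expect_equal(totalLogLikelihood(alnP, fx$tree, params, "A")@lnL,
               base@lnL, tolerance = 1e-8)

  # column permutation
  set.seed(9)
  ord <- sample(ncol(fx$alignment@seqs))
  seqs2 <- setNames(apply(fx$alignment@seqs[, ord, drop = FALSE], 1,
                          paste, collapse = ""), fx$alignment@taxa)
  alnC <- codonAlignment(seqs2, "colperm")
  expect_equal(totalLogLikelihood(alnC, fx$tree, params, "A")@lnL,
               base@lnL, tolerance = 1e-8)
  expect_equal(sort(totalLogLikelihood(alnC, fx$tree, params,
                                       "A")@perSiteLnL),
               sort(base@perSiteLnL), tolerance = 1e-8)

  # duplicated columns: lnL exactly doubles (i.i.d. sites)
  seqs3 <- setNames(paste0(seqs2, seqs2), fx$alignment@taxa)
  alnD <- codonAlignment(seqs3, "dup")
  expect_equal(totalLogLikelihood(alnD, fx$tree, params, "A")@lnL,
               2 * base@lnL, tolerance = 1e-8)
})

test_that("model A at omega2 = 1 coincides with the null A1", {
  fx <- fixtureAlignment(nSites = 25, seed = 6)
  p1 <- modelAParams(2, 0.2, 1, 0.6, 0.2, fx$params@pi)
  a <- totalLogLikelihood(fx$alignment, fx$tree, p1, "A")
  n <- totalLogLikelihood(fx$alignment, fx$tree, p1, "A1")
  expect_equal(a@lnL, n@lnL, tolerance = 1e-10)
  # and lnL always equals the per-site sum
  expect_equal(sum(a@perSiteLnL), a@lnL, tolerance = 1e-8)
})

test_that("alignment/tree taxon mismatches are rejected", {
  fx <- fixtureAlignment(nSites = 5, seed = 2)
  phy <- ape::read.tree(text = "((x:0.1,y:0.1):0.1,z:0.2);")
  expect_error(totalLogLikelihood(fx$alignment, labeledTree(phy, "x"),
                                  fx$params, "A"), "match")
})

test_that("NEB posteriors follow Bayes' rule on an enumerable fixture", {
  set.seed(23)
  pi <- codonFrequencies(runif(61, 0.5, 1.5))
  params <- modelAParams(2, 0.2, 6, 0.5, 0.3, pi)
  phy <- ape::read.tree(text = "(a:0.3,b:0.2,c:0.4);")
  tr <- labeledTree(phy, "a")
  edges <- rbind(c("r", "a"), c("r", "b"), c("r", "c"))
  blens <- c(0.3, 0.2, 0.4)
  codons <- senseCodons()
  cols <- list(c(a = 14L, b = 2L, c = 2L), c(a = 30L, b = 30L, c = 30L))
  seqs <- setNames(vapply(c("a", "b", "c"), function(tx)
    paste(codons[vapply(cols, `[[`, 1L, tx)], collapse = ""), ""),
    c("a", "b", "c"))
  aln <- codonAlignment(seqs, "neb")
  fit <- new("LikelihoodResult", lnL = 0, perSiteLnL = numeric(0),
             params = params, model = "A", converged = TRUE,
             nRestartsUsed = 1L)
  post <- sitePosteriors(aln, tr, fit, "NEB")
  pr <- siteClassProportions(params)
  for (s in 1:2) {
    cls <- oracleColumnLik(cols[[s]], edges, blens, 1L, params, "A",
                           perClass = TRUE)
    want <- pr * cls / sum(pr * cls)
    expect_equal(unlist(post[s, c("post0", "post1", "post2a", "post2b")]),
                 unname(want), tolerance = 1e-8, ignore_attr = TRUE)
  }
  expect_equal(post$pSelected, post$post2a + post$post2b,
               tolerance = 1e-12)
  expect_equal(rowSums(post[, c("post0", "post1", "post2a", "post2b")]),
               rep(1, 2), tolerance = 1e-9)
})

test_that("NEB with all prior mass on classes 0/1 gives pSelected 0,
          and BEB still returns valid posteriors", {
  fx <- fixtureAlignment(nSites = 20, seed = 8)
  degen <- modelAParams(2, 0.2, 3, 0.7, 0.3 - 1e-9, fx$params@pi)
  fit <- new("LikelihoodResult", lnL = 0, perSiteLnL = numeric(0),
             params = degen, model = "A", converged = TRUE,
             nRestartsUsed = 1L)
  post <- sitePosteriors(fx$alignment, fx$tree, fit, "NEB")
  expect_true(all(post$pSelected < 1e-6))

  beb <- sitePosteriors(fx$alignment, fx$tree, fit, "BEB")
  expect_equal(rowSums(beb[, c("post0", "post1", "post2a", "post2b")]),
               rep(1, nrow(beb)), tolerance = 1e-9)
  expect_true(all(beb$pSelected >= 0 & beb$pSelected <= 1))
})
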