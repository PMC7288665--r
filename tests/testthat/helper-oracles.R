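# Independent oracles used across the suite.  These deliberately avoid
# the package's own computational paths: brute-force enumeration,
# Matrix::expm exponentials and hand-rolled step-up FDR.

# ---- genetic-code oracle --------------------------------------------

# classify a single-step codon pair from first principles
oracleClassify <- function(ci, cj) {
  gc <- Biostrings::GENETIC_CODE
  a1 <- unname(gc[[ci]]); a2 <- unname(gc[[cj]])
  s1 <- strsplit(ci, "")[[1]]; s2 <- strsplit(cj, "")[[1]]
  d <- which(s1 != s2)
  if (length(d) != 1L) return("multi-step")
  pur <- c("A", "G")
  ts <- (s1[d] %in% pur) == (s2[d] %in% pur)
  paste0(if (a1 == a2) "synonymous-" else "nonsynonymous-",
         if (ts) "transition" else "transversion")
}

# ---- brute-force Benjamini-Hochberg ---------------------------------

oracleBH <- function(p) {
  # q_i = min over p_j >= p_i of m * p_j / rank(p_j), capped at 1
  m <- length(p)
  o <- order(p)
  r <- match(seq_len(m), o)        # rank of each p
  cand <- m * p[o] / seq_len(m)
  runmin <- rev(cummin(rev(cand))) # step-up from the largest p down
  pmin(runmin[r], 1)
}

# ---- brute-force branch-site likelihood -----------------------------

# Exhaustive enumeration over internal-node states for one codon column,
# under the common-scale convention (all classes share one scaling
# factor: the background-mixture average rate).  Tree given explicitly
# as an edge list; feasible for <= 2 internal nodes.
oracleColumnLik <- function(column, edges, blens, fgEdge, params,
                            model = "A", perClass = FALSE) {
  codons <- senseCodons()
  tab <- siteClassTable(params, model)
  piv <- params@pi@pi
  uQ <- function(om) buildRateMatrix(params@kappa, om, params@pi,
                                     scale = FALSE)@q
  rate <- function(om) -sum(piv * diag(uQ(om)))
  f <- sum(tab$proportion * vapply(tab$omegaBackground, rate, 0))
  nodes <- sort(unique(c(edges)))
  tips <- names(column)
  internals <- setdiff(nodes, tips)
  root <- setdiff(edges[, 1], edges[, 2])
  total <- 0
  classLik <- numeric(4)
  for (k in 1:4) {
    Pk <- lapply(seq_len(nrow(edges)), function(e) {
      om <- if (e == fgEdge) tab$omegaForeground[k]
      else tab$omegaBackground[k]
      as.matrix(Matrix::expm(uQ(om) / f * blens[e]))
    })
    lik <- 0
    grid <- do.call(expand.grid, rep(list(seq_along(codons)),
                                     length(internals)))
    for (g in seq_len(nrow(grid))) {
      assign_ <- setNames(as.integer(grid[g, ]), internals)
      state <- function(nd) {
        if (nd %in% tips) column[[nd]] else assign_[[nd]]
      }
      term <- unname(piv[state(root)])
      ok <- TRUE
      for (e in seq_len(nrow(edges))) {
        sP <- state(edges[e, 1]); sC <- state(edges[e, 2])
        if (is.na(sC)) next  # missing tip: marginalised, P row sums to 1
        if (is.na(sP)) { ok <- FALSE; break }
        term <- term * Pk[[e]][sP, sC]
      }
      if (ok) lik <- lik + term
    }
    classLik[k] <- lik
    total <- total + tab$proportion[k] * lik
  }
  if (perClass) classLik else total
}

# ---- small simulated fixtures ---------------------------------------

fixtureAlignment <- function(nSites = 40, seed = 42, omega2 = 1,
                             nTaxa = 4, model = if (omega2 > 1) "A" else "A1") {
  phys <- list(
    `4` = "(((fg:0.25,cf:0.2):0.1,in1:0.3):0.1,out:0.4);",
    `5` = "((((fg:0.25,cf:0.2):0.1,in1:0.3):0.05,in2:0.25):0.1,out:0.4);",
    `6` = "(((((fg:0.25,cf:0.2):0.1,in1:0.3):0.05,in2:0.25):0.05,in3:0.2):0.1,out:0.4);")
  phy <- ape::read.tree(text = phys[[as.character(nTaxa)]])
  tree <- labeledTree(phy, "fg")
  params <- modelAParams(2, 0.2, max(omega2, 1), 0.6, 0.2,
                         codonFrequencies(rep(1, 61), "equal"))
  sim <- simulateAlignment(tree, params, nSites, seed = seed,
                           model = model)
  tags <- setNames(c("foreground-species", "counter-foreground",
                     rep("ingroup", nTaxa - 3), "outgroup"),
                   c("fg", "cf", paste0("in", seq_len(nTaxa - 3)), "out"))
  sim$alignment@lineageTags <- tags
  list(alignment = sim$alignment, tree = tree, params = params,
       siteClasses = sim$siteClasses, phy = phy)
}
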