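# Forward simulation of codon alignments under the branch-site model,
# ortholog-group sets with known ground truth, and matched synthetic
# tissue-expression tables.

#' Simulated group set
#'
#' @slot groups list of [OrthologGroup-class].
#' @slot truth data.frame with columns `groupId` and `truth` (one of
#'   `"null"`, `"foreground-selected"`, `"counter-foreground-selected"`),
#'   one row per group.
#' @slot config list echoing the generator settings and seed.
#' @export
setClass("SimulatedGroupSet",
  representation(groups = "list", truth = "data.frame", config = "list"),
  validity = function(object) {
    ids <- vapply(object@groups, function(g) g@groupId, "")
    if (!identical(sort(ids), sort(object@truth$groupId)))
      "truth must cover every group exactly once"
    else TRUE
  })

setMethod("show", "SimulatedGroupSet", function(object) {
  cat("SimulatedGroupSet:", length(object@groups), "groups (",
      paste(names(table(object@truth$truth)),
            table(object@truth$truth), sep = "=", collapse = ", "),
      ")\n")
})

# Run `expr` under a private RNG stream seeded with `seed`, restoring
# the caller's stream afterwards.
.withSeed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  old <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) suppressWarnings(rm(".Random.seed",
                                          envir = globalenv()))
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

# per-group seed expansion: one global seed, counter-based, kept < 2^31
.childSeed <- function(seed, i) {
  as.integer((as.numeric(seed) + 104729 * as.numeric(i)) %% 2147483647)
}

# uniform integer draw from an inclusive range (safe when lo == hi)
.sampleRange <- function(range) {
  lo <- as.integer(range[1]); hi <- as.integer(range[2])
  if (lo >= hi) lo else lo + sample.int(hi - lo + 1L, 1L) - 1L
}

#' Simulate a codon alignment under the branch-site model
#'
#' Each site is assigned one of the four site classes with probabilities
#' `(p0, p1, p2a, p2b)`; the class is fixed across the whole tree.  The
#' root codon is drawn from `pi` and evolved along each branch by
#' sampling from the class- and branch-appropriate transition matrix;
#' only the flagged foreground branch uses `omega2` (classes 2a/2b).
#' Under `model = "A1"` the foreground omega is 1, i.e. the null.
#'
#' @param tree a [LabeledTree-class] (branch lengths in expected
#'   substitutions per codon).
#' @param params a [ModelAParams-class]; tree branch lengths are used
#'   (the `branchLengths` slot is ignored here).
#' @param nSites number of codon sites.
#' @param seed optional integer seed (private RNG stream).
#' @param model `"A"` or `"A1"`.
#' @param groupId identifier for the resulting alignment.
#' @return list with `alignment` (a [CodonAlignment-class]) and
#'   `siteClasses` (character vector of true classes, `"0"`, `"1"`,
#'   `"2a"`, `"2b"`).
#' @export
simulateAlignment <- function(tree, params, nSites, seed = NULL,
                              model = c("A", "A1"), groupId = "sim") {
  model <- match.arg(model)
  .withSeed(seed, {
    codons <- senseCodons()
    phy <- ape::reorder.phylo(tree@phy, "postorder")
    fgChild <- tree@phy$edge[tree@foregroundEdge, 2]
    fgEdge <- which(phy$edge[, 2] == fgChild)
    tab <- siteClassTable(params, model)
    classes <- sample.int(4, nSites, replace = TRUE,
                          prob = tab$proportion)
    piv <- params@pi@pi
    omegaFg <- tab$omegaForeground
    omegaBg <- tab$omegaBackground
    uo <- sort(unique(c(omegaFg, omegaBg)))
    # same mixture rate scaling as the likelihood: one common factor,
    # the class-mixture average rate on a background branch
    parts <- .codonRateParts(piv)
    rates <- vapply(uo, function(o) .codonRate(params@kappa, o, parts), 0)
    f <- sum(tab$proportion * rates[match(omegaBg, uo)])
    Plist <- lapply(seq_along(uo), function(k) {
      eg <- .codonEigen(params@kappa, uo[k], params@pi)
      lapply(phy$edge.length * rates[k] / f, function(t) {
        p <- eg$Vh %*% (exp(eg$lam * t) * eg$W)
        p[p < 0] <- 0
        p
      })
    })
    nNode <- length(phy$tip.label) + phy$Nnode
    states <- matrix(NA_integer_, nNode, nSites)
    root <- phy$edge[nrow(phy$edge), 1]
    states[root, ] <- sample.int(61, nSites, replace = TRUE, prob = piv)
    # preorder = reverse postorder
    for (e in rev(seq_len(nrow(phy$edge)))) {
      parent <- phy$edge[e, 1]; child <- phy$edge[e, 2]
      omEdge <- if (e == fgEdge) omegaFg else omegaBg
      for (k in 1:4) {
        sites <- which(classes == k)
        if (!length(sites)) next
        P <- Plist[[match(omEdge[k], uo)]][[e]]
        ps <- states[parent, sites]
        for (s in unique(ps)) {
          sel <- sites[ps == s]
          states[child, sel] <- sample.int(61, length(sel),
                                           replace = TRUE, prob = P[s, ])
        }
      }
    }
    tipSeqs <- vapply(seq_along(phy$tip.label), function(i)
      paste(codons[states[i, ]], collapse = ""), "")
    names(tipSeqs) <- phy$tip.label
    aln <- codonAlignment(tipSeqs, groupId = groupId)
    list(alignment = aln,
         siteClasses = c("0", "1", "2a", "2b")[classes])
  })
}

# random rooted topology: outgroup as sister to a random ingroup tree
.randomGroupTree <- function(taxa, outgroup, blRange) {
  inner <- setdiff(taxa, outgroup)
  sub <- ape::rtree(length(inner), tip.label = sample(inner), br = NULL)
  nwk <- paste0("(", sub(";$", "", ape::write.tree(sub)), ",",
                outgroup, ");")
  phy <- ape::read.tree(text = nwk)
  phy$edge.length <- runif(nrow(phy$edge), blRange[1], blRange[2])
  phy
}

#' Simulate a set of orthologous groups with known truth
#'
#' Emulates a scan-scale collection: a stated fraction of groups carries
#' a branch-site selection signal on the foreground species' terminal
#' branch, another fraction on the counter-foreground's, and the rest
#' evolve under the null.  Truth categories are allocated
#' deterministically (first `k` groups after a seeded shuffle), so the
#' expected counts are exact.  Nuisance parameters are drawn per group
#' from `kappa ~ U[1,4]`, `omega0 ~ U[0.05,0.5]`,
#' `omega2 ~ U[2,8]` (selected groups), branch lengths uniform in
#' `blRange`, and group sizes uniform in `nTaxaRange` (the lower end may
#' fall below the five-species filter threshold on purpose).  A fraction
#' `shortSeqRate` of groups gets one mostly-gapped ingroup sequence to
#' exercise the length filter.
#'
#' @param nGroups number of groups.
#' @param fracForeSelected,fracCounterSelected truth fractions (sum <=
#'   1; remainder is null).
#' @param nTaxaRange integer range of taxa per group.
#' @param nSitesRange integer range of codon sites per group.
#' @param blRange branch-length range (substitutions/codon).
#' @param p0Range,p1Range ranges of the class-0/1 proportions.
#' @param omega2Range selected-class dN/dS range for selected groups.
#' @param shortSeqRate fraction of groups given one truncated
#'   (mostly-gap) dispensable sequence.
#' @param gapBlockRate per-group probability of a random gap block
#'   (alignment-quality corruption).
#' @param seed integer seed; expanded to per-group seeds by a counter
#'   scheme.
#' @return a [SimulatedGroupSet-class].
#' @export
simulateGroupSet <- function(nGroups,
                             fracForeSelected = 0.2,
                             fracCounterSelected = 0,
                             nTaxaRange = c(4, 10),
                             nSitesRange = c(200, 600),
                             blRange = c(0.05, 0.5),
                             p0Range = c(0.45, 0.75),
                             p1Range = c(0.10, 0.25),
                             omega2Range = c(2, 8),
                             shortSeqRate = 0,
                             gapBlockRate = 0,
                             seed = 1) {
  if (fracForeSelected < 0 || fracCounterSelected < 0 ||
      fracForeSelected + fracCounterSelected > 1)
    stop("truth fractions must be non-negative and sum to <= 1")
  nFore <- round(fracForeSelected * nGroups)
  nCounter <- round(fracCounterSelected * nGroups)
  truthCats <- .withSeed(.childSeed(seed, 0), {
    ord <- sample.int(nGroups)
    cats <- rep("null", nGroups)
    cats[ord[seq_len(nFore)]] <- "foreground-selected"
    if (nCounter > 0)
      cats[ord[nFore + seq_len(nCounter)]] <- "counter-foreground-selected"
    cats
  })
  groups <- vector("list", nGroups)
  for (i in seq_len(nGroups)) {
    gid <- sprintf("OG%04d", i)
    gseed <- .childSeed(seed, i)
    groups[[i]] <- .withSeed(gseed, {
      nTaxa <- .sampleRange(nTaxaRange)
      nIn <- max(nTaxa - 3L, 0L)
      taxa <- c("fg_species", "counter_fg", "outgroup1",
                if (nIn > 0) paste0("ingroup", seq_len(nIn)))
      roles <- setNames(c("foreground-species", "counter-foreground",
                          "outgroup", rep("ingroup", nIn)), taxa)
      phy <- .randomGroupTree(taxa, "outgroup1", blRange)
      nSites <- .sampleRange(nSitesRange)
      truth <- truthCats[i]
      selected <- truth != "null"
      fgTaxon <- if (truth == "counter-foreground-selected")
        "counter_fg" else "fg_species"
      params <- modelAParams(
        kappa = runif(1, 1, 4),
        omega0 = runif(1, 0.05, 0.5),
        omega2 = if (selected) runif(1, omega2Range[1], omega2Range[2])
                 else 1,
        p0 = runif(1, p0Range[1], p0Range[2]),
        p1 = runif(1, p1Range[1], p1Range[2]),
        pi = codonFrequencies(rep(1, 61), "equal"))
      sim <- simulateAlignment(labeledTree(phy, fgTaxon), params,
                               nSites,
                               model = if (selected) "A" else "A1",
                               groupId = gid)
      aln <- sim$alignment
      seqs <- setNames(apply(aln@seqs, 1, paste, collapse = ""),
                       aln@taxa)
      if (nIn > 0 && runif(1) < shortSeqRate) {
        # truncate one dispensable ingroup sequence below half mean
        victim <- paste0("ingroup", sample.int(nIn, 1))
        keep <- max(1L, floor(nSites * 0.3))
        seqs[victim] <- paste0(substr(seqs[victim], 1, 3 * keep),
                               strrep("-", 3 * (nSites - keep)))
      }
      if (runif(1) < gapBlockRate && nSites >= 20) {
        width <- sample(5:10, 1)
        at <- sample.int(nSites - width, 1)
        gapTaxa <- sample(taxa, max(2L, ceiling(length(taxa) * 0.6)))
        for (tx in gapTaxa)
          substr(seqs[tx], 3 * at + 1, 3 * (at + width)) <-
            strrep("-", 3 * width)
      }
      aln <- codonAlignment(seqs, groupId = gid, lineageTags = roles)
      g <- new("OrthologGroup", groupId = gid, alignment = aln,
               tree = phy, speciesRoles = roles)
      attr(g, "siteClasses") <- sim$siteClasses
      g
    })
  }
  new("SimulatedGroupSet",
      groups = groups,
      truth = data.frame(groupId = vapply(groups, function(g) g@groupId, ""),
                         truth = truthCats, stringsAsFactors = FALSE),
      config = list(nGroups = nGroups,
                    fracForeSelected = fracForeSelected,
                    fracCounterSelected = fracCounterSelected,
                    nTaxaRange = nTaxaRange, nSitesRange = nSitesRange,
                    blRange = blRange, omega2Range = omega2Range,
                    shortSeqRate = shortSeqRate,
                    gapBlockRate = gapBlockRate, seed = seed))
}

#' Write a simulated group set to the on-disk scan layout
#'
#' One aligned FASTA and one Newick per group, a `roles.tsv` map and a
#' `truth.tsv` table — the same layout [runScan()] consumes.
#'
#' @param groupSet a [SimulatedGroupSet-class].
#' @param dir output directory (created).
#' @return `dir`, invisibly.
#' @export
writeGroupSet <- function(groupSet, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (g in groupSet@groups) {
    writeCodonAlignment(g@alignment, file.path(dir, paste0(g@groupId,
                                                           ".fasta")))
    ape::write.tree(g@tree, file.path(dir, paste0(g@groupId, ".nwk")))
  }
  roles <- groupSet@groups[[1]]@speciesRoles
  rolesAll <- unique(do.call(rbind, lapply(groupSet@groups, function(g)
    data.frame(taxon = names(g@speciesRoles),
               role = unname(g@speciesRoles)))))
  write.table(rolesAll, file.path(dir, "roles.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(groupSet@truth, file.path(dir, "truth.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' Simulate tissue-expression tables matched to a group set
#'
#' One row per gene per tissue with a Bernoulli expressed flag; a
#' configurable fraction of genes additionally receives a regulation
#' status per contrast, emulating differential-expression tables.
#'
#' @param groupIds gene/group identifiers (e.g.
#'   `groupSet@truth$groupId`).
#' @param tissues character vector of tissue names.
#' @param pExpressed scalar or per-tissue named vector of expression
#'   probabilities.
#' @param contrasts character vector of contrast labels (may be empty).
#' @param pRegulated fraction of genes that receive a regulation call
#'   per contrast.
#' @param pRegulation probabilities for `up`, `down`, `unchanged`.
#' @param seed integer seed.
#' @return data.frame with columns `gene_id`, `tissue`, `expressed`,
#'   `regulation`, `contrast`.
#' @export
simulateExpressionTable <- function(groupIds, tissues,
                                    pExpressed = 0.5,
                                    contrasts = character(),
                                    pRegulated = 0.5,
                                    pRegulation = c(up = 0.2, down = 0.2,
                                                    unchanged = 0.6),
                                    seed = 1) {
  if (!length(tissues)) stop("tissues must be non-empty")
  if (length(pExpressed) == 1L)
    pExpressed <- setNames(rep(pExpressed, length(tissues)), tissues)
  .withSeed(seed, {
    rows <- do.call(rbind, lapply(tissues, function(ts)
      data.frame(gene_id = groupIds, tissue = ts,
                 expressed = runif(length(groupIds)) < pExpressed[[ts]],
                 regulation = NA_character_, contrast = NA_character_,
                 stringsAsFactors = FALSE)))
    for (ct in contrasts) {
      sel <- groupIds[runif(length(groupIds)) < pRegulated]
      if (!length(sel)) next
      reg <- sample(names(pRegulation), length(sel), replace = TRUE,
                    prob = pRegulation)
      rows <- rbind(rows, data.frame(
        gene_id = sel, tissue = tissues[1], expressed = TRUE,
        regulation = reg, contrast = ct, stringsAsFactors = FALSE))
    }
    rownames(rows) <- NULL
    rows
  })
}
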