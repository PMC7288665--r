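# Branch-site likelihood: site-pattern compression, per-class pruning
# (C++ core), total log-likelihood and empirical Bayes site posteriors.

# Precompute everything that depends only on (alignment, tree): postorder
# edge list, tip states in tree tip order, compressed site patterns, the
# foreground edge index in postorder numbering, and branch lengths.
.likContext <- function(aln, tree) {
  phy <- tree@phy
  if (!setequal(phy$tip.label, aln@taxa))
    stop("alignment taxa and tree tips do not match for group '",
         aln@groupId, "'")
  po <- ape::reorder.phylo(phy, "postorder")
  fgChild <- phy$edge[tree@foregroundEdge, 2]
  fgEdge <- which(po$edge[, 2] == fgChild)
  states <- aln@states[match(po$tip.label, aln@taxa), , drop = FALSE]
  key <- apply(states, 2, paste, collapse = ",")
  ukey <- unique(key)
  patIdx <- match(key, ukey)
  first <- match(ukey, key)
  tipState0 <- states[, first, drop = FALSE]
  tipState0[is.na(tipState0)] <- 0L
  tipState0 <- tipState0 - 1L           # 0-based, -1 = missing
  storage.mode(tipState0) <- "integer"
  edge <- po$edge
  storage.mode(edge) <- "integer"
  list(edge = edge,
       nTip = length(po$tip.label),
       nNode = length(po$tip.label) + po$Nnode,
       tipState0 = tipState0,
       fgEdge = fgEdge,
       patIdx = patIdx,
       weights = tabulate(patIdx, nbins = length(ukey)),
       nSites = length(key),
       edgeLengths = po$edge.length,
       tipOrder = po$tip.label)
}

# Per-class log site likelihoods (nPat x 4) for the four branch-site
# classes, at the given parameter values.  Classes that induce identical
# per-branch omega assignments (e.g. 2b == 1 under the null) are pruned
# once and copied.
.classLogLik <- function(ctx, kappa, omega0, omega2, piObj, tvec,
                         model = "A", cache = NULL,
                         proportions = NULL) {
  w2 <- if (model == "A1") 1 else omega2
  omegas <- c(omega0, 1, w2)
  uo <- unique(omegas)
  eig <- lapply(uo, function(o) .codonEigenCached(kappa, o, piObj, cache))
  oi <- match(omegas, uo)
  # one common rate scale across classes: branch lengths are expected
  # substitutions per codon averaged over the site-class mixture on a
  # background branch, so the omega2 class genuinely evolves faster
  parts <- .codonRateParts(piObj@pi)
  rates <- vapply(uo, function(o) .codonRate(kappa, o, parts), 0)
  if (is.null(proportions)) proportions <- rep(0.25, 4)
  bgRates <- rates[oi[c(1, 2, 1, 2)]]
  f <- sum(proportions * bgRates)
  rateScale <- rates / f
  nE <- nrow(ctx$edge)
  col2a <- rep(oi[1], nE); col2a[ctx$fgEdge] <- oi[3]
  col2b <- rep(oi[2], nE); col2b[ctx$fgEdge] <- oi[3]
  cols <- cbind(rep(oi[1], nE), rep(oi[2], nE), col2a, col2b)
  # classes are duplicates iff their (background, foreground) omega
  # pair coincides -- no need to hash whole columns
  keyc <- c(oi[1] * 8L + oi[1], oi[2] * 8L + oi[2],
            oi[1] * 8L + oi[3], oi[2] * 8L + oi[3])
  uniq <- !duplicated(keyc)
  map <- match(keyc, keyc[uniq])
  storage.mode(cols) <- "integer"
  res <- prune_class_loglik(ctx$edge, ctx$nTip, ctx$nNode, ctx$tipState0,
                            eig, tvec, cols[, uniq, drop = FALSE],
                            rateScale, piObj@pi)
  res[, map, drop = FALSE]
}

# Small per-fit memo for eigendecompositions keyed by (kappa, omega):
# finite-difference gradients perturb one parameter at a time, so most
# evaluations reuse two of the three decompositions.  `cache` is an
# environment local to one fit (pi is fixed within it).
.codonEigenCached <- function(kappa, omega, piObj, cache = NULL) {
  if (is.null(cache)) return(.codonEigen(kappa, omega, piObj))
  key <- paste(format(kappa, digits = 17), format(omega, digits = 17))
  val <- cache[[key]]
  if (!is.null(val)) return(val)
  if (length(ls(cache)) > 24L) rm(list = ls(cache), envir = cache)
  cache[[key]] <- .codonEigen(kappa, omega, piObj)
}

# Mixture of class likelihoods -> per-pattern log-likelihood (stable).
.mixPatternLnl <- function(classLog, proportions) {
  m <- classLog[, 1]
  for (k in seq_len(ncol(classLog))[-1]) m <- pmax(m, classLog[, k])
  m + log(as.vector(exp(classLog - m) %*% proportions))
}

#' Total branch-site log-likelihood at fixed parameters
#'
#' Evaluates the branch-site model A (or its null A1, which forces
#' `omega2 = 1`) log-likelihood by Felsenstein pruning with site-pattern
#' compression.  No fitting is performed; see [fitBranchSite()].
#'
#' @param alignment a [CodonAlignment-class].
#' @param tree a [LabeledTree-class] over the same taxa.
#' @param params a [ModelAParams-class]; if `params@branchLengths` is
#'   empty the tree's own branch lengths are used.
#' @param model `"A"` (alternative) or `"A1"` (null).
#' @return a [LikelihoodResult-class] with per-site log-likelihoods.
#' @export
totalLogLikelihood <- function(alignment, tree, params,
                               model = c("A", "A1")) {
  model <- match.arg(model)
  ctx <- .likContext(alignment, tree)
  tvec <- if (length(params@branchLengths))
    .mapBranchLengths(params@branchLengths, tree, ctx) else ctx$edgeLengths
  pr <- siteClassProportions(params)
  classLog <- .classLogLik(ctx, params@kappa, params@omega0,
                           params@omega2, params@pi, tvec, model,
                           proportions = pr)
  patLnl <- .mixPatternLnl(classLog, pr)
  perSite <- patLnl[ctx$patIdx]
  new("LikelihoodResult", lnL = sum(perSite), perSiteLnL = perSite,
      params = params, model = model, converged = TRUE,
      nRestartsUsed = 0L)
}

# ModelAParams@branchLengths are stored in the *input* tree's edge order;
# map them onto the postorder edge order of the likelihood context.
.mapBranchLengths <- function(bl, tree, ctx) {
  if (length(bl) != nrow(tree@phy$edge))
    stop("branchLengths must have one entry per tree edge")
  bl[match(ctx$edge[, 2], tree@phy$edge[, 2])]
}

#' Empirical Bayes posteriors of the selected site classes
#'
#' For each codon site, the posterior probability of each of the four
#' site classes of the branch-site model, and `pSelected`, the posterior
#' of the positively selected classes (2a or 2b) on the foreground
#' branch.  `"NEB"` plugs the maximum-likelihood estimates into Bayes'
#' rule; `"BEB"` additionally averages over a discrete uniform prior grid
#' (10 points per dimension) on `(p0, p1, omega0, omega2)`, accounting
#' for parameter uncertainty.
#'
#' @param alignment a [CodonAlignment-class].
#' @param tree a [LabeledTree-class].
#' @param fit a converged model-A [LikelihoodResult-class] from
#'   [fitBranchSite()].
#' @param method `"NEB"` (default) or `"BEB"`.
#' @return data.frame with columns `site`, `post0`, `post1`, `post2a`,
#'   `post2b`, `pSelected`, `method`.
#' @export
sitePosteriors <- function(alignment, tree, fit,
                           method = c("NEB", "BEB")) {
  method <- match.arg(method)
  if (fit@model != "A")
    stop("site posteriors require an alternative-model (A) fit")
  ctx <- .likContext(alignment, tree)
  params <- fit@params
  tvec <- if (length(params@branchLengths))
    .mapBranchLengths(params@branchLengths, tree, ctx) else ctx$edgeLengths
  if (method == "NEB") {
    pr <- siteClassProportions(params)
    classLog <- .classLogLik(ctx, params@kappa, params@omega0,
                             params@omega2, params@pi, tvec, "A",
                             proportions = pr)
    post <- .classPosterior(classLog, pr)
  } else {
    post <- .bebPosterior(ctx, params, tvec)
  }
  post <- post[ctx$patIdx, , drop = FALSE]
  data.frame(site = seq_len(ctx$nSites),
             post0 = post[, 1], post1 = post[, 2],
             post2a = post[, 3], post2b = post[, 4],
             pSelected = post[, 3] + post[, 4],
             method = method,
             row.names = NULL)
}

.classPosterior <- function(classLog, proportions) {
  lw <- sweep(classLog, 2, log(ifelse(proportions > 0, proportions, NA)),
              "+")
  lw[is.na(lw)] <- -Inf
  m <- apply(lw, 1, max)
  w <- exp(lw - m)
  w / rowSums(w)
}

# BEB: uniform prior grids (10 midpoints each) on omega0 in (0,1),
# omega2 in (1,11), and the (p0,p1) pairs of the same grid restricted to
# the simplex.  kappa, branch lengths and codon frequencies stay at the
# MLEs, as in the usual branch-site BEB.
.bebPosterior <- function(ctx, params, tvec) {
  # branch lengths, kappa and the mixture rate scaling stay at the MLEs
  # (as in the usual BEB); the grid varies the prior parameters only
  mleProps <- siteClassProportions(params)
  cache <- new.env(parent = emptyenv())
  gridPts <- (seq_len(10) - 0.5) / 10
  w0grid <- gridPts
  w2grid <- 1 + 10 * gridPts
  pp <- expand.grid(p0 = gridPts, p1 = gridPts)
  pp <- pp[pp$p0 + pp$p1 <= 1, ]
  props <- t(apply(pp, 1, function(r) {
    rest <- 1 - r[1] - r[2]
    c(r[1], r[2], rest * r[1] / (r[1] + r[2]),
      rest * r[2] / (r[1] + r[2]))
  }))
  npat <- ncol(ctx$tipState0)
  acc <- matrix(0, npat, 4)
  logwts <- c()
  contribs <- list()
  k <- 0L
  for (i in seq_along(w0grid)) {
    for (j in seq_along(w2grid)) {
      classLog <- .classLogLik(ctx, params@kappa, w0grid[i], w2grid[j],
                               params@pi, tvec, "A", cache = cache,
                               proportions = mleProps)
      for (r in seq_len(nrow(props))) {
        k <- k + 1L
        patLnl <- .mixPatternLnl(classLog, props[r, ])
        logwts[k] <- sum(ctx$weights * patLnl)
        contribs[[k]] <- .classPosterior(classLog, props[r, ])
      }
    }
  }
  m <- max(logwts)
  wts <- exp(logwts - m)
  wts <- wts / sum(wts)
  for (k in seq_along(wts))
    acc <- acc + wts[k] * contribs[[k]]
  acc
}
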