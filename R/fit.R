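# Maximum-likelihood fitting of the branch-site models by bounded
# quasi-Newton optimisation on transformed parameters, with multi-start.

.W0_LO <- 1e-4
.W0_HI <- 0.999

# internal instrumentation (likelihood evaluations per session)
.fitEvalCounter <- new.env(parent = emptyenv())
.fitEvalCounter$n <- 0L

.fitControl <- function(control = list()) {
  defaults <- list(
    screenIter = 3L,     # iterations per start during screening
    maxit = 400L,        # iterations for the polishing run
    midIter = 14L,       # iterations for the codon-parameter pre-polish
    jointIter = 12L,     # iterations for the joint (+branch-length) stage
    factr = 4.5e9,       # ~1e-6 lnL convergence tolerance in L-BFGS-B
    kappaBounds = c(0.1, 99),
    omega2Max = 999,
    blBounds = c(1e-7, 20))
  defaults[names(control)] <- control
  defaults
}

# transform helpers ---------------------------------------------------

.softmaxP <- function(x0, x1) {
  e0 <- exp(x0); e1 <- exp(x1)
  d <- 1 + e0 + e1
  c(p0 = e0 / d, p1 = e1 / d)
}

.invSoftmaxP <- function(p0, p1) {
  p2 <- max(1 - p0 - p1, 1e-8)
  c(x0 = log(max(p0, 1e-8) / p2), x1 = log(max(p1, 1e-8) / p2))
}

.packPar <- function(kappa, w0, w2, p0, p1, bl, model, optimizeBl) {
  par <- c(lkappa = log(kappa),
           xw0 = stats::qlogis(min(max((w0 - .W0_LO) / (.W0_HI - .W0_LO),
                                       1e-9), 1 - 1e-9)))
  if (model == "A")
    par <- c(par, sw2 = log(max(w2 - 1, 0) + 1e-8))
  par <- c(par, .invSoftmaxP(p0, p1))
  if (optimizeBl)
    par <- c(par, setNames(log(pmax(bl, 1e-7)),
                           paste0("t", seq_along(bl))))
  par
}

.unpackPar <- function(par, model, optimizeBl, tvecFixed) {
  kappa <- exp(par[["lkappa"]])
  w0 <- .W0_LO + (.W0_HI - .W0_LO) * stats::plogis(par[["xw0"]])
  w2 <- if (model == "A") 1 + exp(par[["sw2"]]) - 1e-8 else 1
  w2 <- max(w2, 1)
  p <- .softmaxP(par[["x0"]], par[["x1"]])
  tvec <- if (optimizeBl)
    exp(unname(par[grep("^t", names(par))])) else tvecFixed
  list(kappa = kappa, w0 = w0, w2 = w2, p0 = unname(p[1]),
       p1 = unname(p[2]), tvec = tvec)
}

.parBounds <- function(par, model, optimizeBl, ctl) {
  lower <- c(lkappa = log(ctl$kappaBounds[1]), xw0 = -12)
  upper <- c(lkappa = log(ctl$kappaBounds[2]), xw0 = 12)
  if (model == "A") {
    lower <- c(lower, sw2 = log(1e-8))
    upper <- c(upper, sw2 = log(ctl$omega2Max - 1))
  }
  lower <- c(lower, x0 = -12, x1 = -12)
  upper <- c(upper, x0 = 12, x1 = 12)
  if (optimizeBl) {
    nb <- sum(grepl("^t", names(par)))
    lower <- c(lower, rep(log(ctl$blBounds[1]), nb))
    upper <- c(upper, rep(log(ctl$blBounds[2]), nb))
  }
  list(lower = lower, upper = upper)
}

# default deterministic multi-start grids -----------------------------

.nullStarts <- function() {
  list(c(kappa = 2, w0 = 0.5, p0 = 0.45, p1 = 0.45),
       c(kappa = 2, w0 = 0.05, p0 = 0.85, p1 = 0.10),
       c(kappa = 4, w0 = 0.2, p0 = 0.60, p1 = 0.30))
}

.altStarts <- function(nullParams) {
  out <- list()
  if (!is.null(nullParams)) {
    out[[1]] <- c(kappa = nullParams@kappa, w0 = nullParams@omega0,
                  w2 = 1, p0 = nullParams@p0, p1 = nullParams@p1)
    out[[2]] <- c(kappa = nullParams@kappa, w0 = nullParams@omega0,
                  w2 = 4, p0 = 0.8 * nullParams@p0,
                  p1 = 0.8 * nullParams@p1)
  }
  out <- c(out,
           list(c(kappa = 2, w0 = 0.1, w2 = 5, p0 = 0.6, p1 = 0.2),
                c(kappa = 2, w0 = 0.2, w2 = 2, p0 = 0.6, p1 = 0.3),
                c(kappa = 3, w0 = 0.4, w2 = 1.5, p0 = 0.45, p1 = 0.45)))
  out
}

#' Fit a branch-site model by maximum likelihood
#'
#' Fits model A (`model = "A"`) or its null A1 (`omega2` fixed at 1) by
#' bounded L-BFGS-B on transformed parameters (`log kappa`, logistic
#' `omega0`, `log(omega2 - 1)`, softmax class proportions, log branch
#' lengths), from several deterministic starting points: a neutral-ish
#' start, a strong-purifying (null) or strong-selection (alternative)
#' start, and a dispersed third start; for the alternative model the
#' null-model optimum, when supplied via `nullFit`, is always a start,
#' which guarantees the nesting inequality.  Starts are screened with a
#' few iterations each; the best is then polished in stages (codon
#' parameters, a bounded joint pass including branch lengths, and a
#' final codon-parameter polish).
#'
#' Branch lengths are optimised by default when fitting the null and are
#' meant to be reused, fixed, for the alternative (pass
#' `branchLengths = nullBranchLengths(fit)`); this stabilises the LRT.
#'
#' @param alignment a [CodonAlignment-class].
#' @param tree a [LabeledTree-class] with one foreground branch.
#' @param model `"A"` or `"A1"`.
#' @param branchLengths optional fixed per-edge lengths (input-tree edge
#'   order); when given, branch lengths are not optimised.
#' @param nullFit optional null-model [LikelihoodResult-class]; its
#'   optimum seeds the alternative fit and its branch lengths are reused
#'   when `branchLengths` is missing.
#' @param freqMethod codon-frequency estimator passed to
#'   [estimateCodonFrequencies()].
#' @param nRestarts number of starting points (1..3 plus the null seed).
#' @param control optimiser control overrides (`screenIter`, `midIter`,
#'   `jointIter`, `maxit`, `factr`, `kappaBounds`, `omega2Max`,
#'   `blBounds`).
#' @return a [LikelihoodResult-class]; `converged = FALSE` flags an
#'   optimiser failure (never an error).
#' @export
fitBranchSite <- function(alignment, tree, model = c("A", "A1"),
                          branchLengths = NULL, nullFit = NULL,
                          freqMethod = "F3x4", nRestarts = 3,
                          control = list()) {
  model <- match.arg(model)
  ctl <- .fitControl(control)
  ctx <- .likContext(alignment, tree)
  piObj <- estimateCodonFrequencies(alignment, freqMethod)

  if (is.null(branchLengths) && !is.null(nullFit) &&
      length(nullFit@params@branchLengths))
    branchLengths <- nullFit@params@branchLengths
  optimizeBl <- is.null(branchLengths)
  tvecFixed <- if (!optimizeBl)
    .mapBranchLengths(branchLengths, tree, ctx) else NULL
  blStart <- if (optimizeBl) pmax(ctx$edgeLengths, 1e-6) else NULL

  cache <- new.env(parent = emptyenv())
  negLnl <- function(par) {
    .fitEvalCounter$n <- .fitEvalCounter$n + 1L
    u <- .unpackPar(par, model, optimizeBl, tvecFixed)
    pr <- c(u$p0, u$p1,
            (1 - u$p0 - u$p1) * c(u$p0, u$p1) / (u$p0 + u$p1))
    cl <- .classLogLik(ctx, u$kappa, u$w0, u$w2, piObj, u$tvec, model,
                       cache = cache, proportions = pr)
    v <- -sum(ctx$weights * .mixPatternLnl(cl, pr))
    if (!is.finite(v)) 1e10 else v
  }

  starts <- if (model == "A1") .nullStarts() else
    .altStarts(if (!is.null(nullFit)) nullFit@params else NULL)
  starts <- starts[seq_len(min(length(starts), max(1L, nRestarts)))]

  packed <- lapply(starts, function(s) {
    .packPar(s[["kappa"]], s[["w0"]],
             if (model == "A") s[["w2"]] else 1,
             s[["p0"]], s[["p1"]], blStart, model, optimizeBl)
  })
  bounds <- .parBounds(packed[[1]], model, optimizeBl, ctl)

  # optimise over a subset of the packed parameters, the rest held fixed
  runOpt <- function(par, maxit, idx = seq_along(par)) {
    fn <- function(p) { full <- par; full[idx] <- p; negLnl(full) }
    res <- optim(par[idx], fn, method = "L-BFGS-B",
                 lower = bounds$lower[idx], upper = bounds$upper[idx],
                 control = list(maxit = maxit, factr = ctl$factr))
    full <- par; full[idx] <- res$par
    list(par = full, value = res$value, convergence = res$convergence)
  }
  safeOpt <- function(par, maxit, idx = seq_along(par)) {
    tryCatch(runOpt(par, maxit, idx),
             error = function(e) list(par = par, value = negLnl(par),
                                      convergence = 99L))
  }
  codonIdx <- which(!grepl("^t\\d", names(packed[[1]])))
  # screen starts on the cheap codon-parameter subproblem
  screened <- lapply(packed, function(p) safeOpt(p, ctl$screenIter,
                                                 codonIdx))
  best <- screened[[which.min(vapply(screened, `[[`, 0, "value"))]]
  if (optimizeBl) {
    mid <- safeOpt(best$par, ctl$midIter, codonIdx)
    if (mid$value <= best$value) best <- mid
    # joint stage over codon parameters and branch lengths, then a
    # final codon-parameter polish at the refined branch lengths (the
    # LRT is insensitive to residual branch-length error because the
    # alternative reuses the null's lengths)
    joint <- safeOpt(best$par, ctl$jointIter)
    if (joint$value <= best$value) best <- joint
  }
  final <- safeOpt(best$par, ctl$maxit,
                   if (optimizeBl) codonIdx else seq_along(best$par))
  if (final$value > best$value) final <- best

  u <- .unpackPar(final$par, model, optimizeBl, tvecFixed)
  # branch lengths back in input-tree edge order
  blOut <- numeric(nrow(tree@phy$edge))
  blOut[match(ctx$edge[, 2], tree@phy$edge[, 2])] <-
    if (optimizeBl) u$tvec else tvecFixed
  params <- modelAParams(u$kappa, u$w0, if (model == "A") u$w2 else 1,
                         u$p0, u$p1, piObj, blOut)
  cl <- .classLogLik(ctx, u$kappa, u$w0, u$w2, piObj, u$tvec, model,
                     proportions = siteClassProportions(params))
  patLnl <- .mixPatternLnl(cl, siteClassProportions(params))
  perSite <- patLnl[ctx$patIdx]
  new("LikelihoodResult", lnL = sum(perSite), perSiteLnL = perSite,
      params = params, model = model,
      converged = !is.null(final$convergence) && final$convergence == 0L,
      nRestartsUsed = length(starts))
}

#' Branch lengths estimated by a fit
#' @param fit a [LikelihoodResult-class].
#' @return numeric vector in the input tree's edge order.
#' @export
nullBranchLengths <- function(fit) fit@params@branchLengths

#' Likelihood-ratio test of the branch-site models
#'
#' Statistic `2 (lnL_A - lnL_A1)`, clamped at zero, compared to the
#' chi-square distribution with one degree of freedom (the convention of
#' the branch-site test 2; conservative for this boundary hypothesis).
#' Set `mixture = TRUE` for the 50:50 point-mass/chi-square mixture null
#' instead.
#'
#' @param null a model-A1 [LikelihoodResult-class].
#' @param alt a model-A [LikelihoodResult-class] on the same data.
#' @param mixture use the boundary mixture null distribution.
#' @return list with `statistic`, `pValue`, and `optimFailure` (`TRUE`
#'   when the alternative log-likelihood falls below the null by more
#'   than 1e-4, signalling that a refit is needed).
#' @export
lrt <- function(null, alt, mixture = FALSE) {
  if (null@model != "A1" || alt@model != "A")
    stop("lrt() expects a null (A1) and an alternative (A) result")
  delta <- alt@lnL - null@lnL
  stat <- max(0, 2 * delta)
  p <- pchisq(stat, df = 1, lower.tail = FALSE)
  if (mixture) p <- if (stat <= 0) 1 else 0.5 * p
  list(statistic = stat, pValue = p, optimFailure = delta < -1e-4)
}

#' Run one complete branch-site test
#'
#' Fits the null (branch lengths optimised), then the alternative
#' (branch lengths reused from the null by default, optimum-seeded), and
#' computes the likelihood-ratio test.  If the alternative lands below
#' the null (optimiser failure) one refit with more iterations is
#' attempted.
#'
#' @inheritParams fitBranchSite
#' @param reoptBranchLengths re-optimise branch lengths under the
#'   alternative model instead of reusing the null's.
#' @param mixture see [lrt()].
#' @param posteriorMethod method for candidate-site posteriors.
#' @param posteriorThreshold report sites with `pSelected` above this.
#' @return list with `null`, `alt` ([LikelihoodResult-class]),
#'   `statistic`, `pValue`, `sites` (full posterior table) and
#'   `candidateSites` (rows above the threshold).
#' @export
branchSiteTest <- function(alignment, tree, reoptBranchLengths = FALSE,
                           freqMethod = "F3x4", nRestarts = 3,
                           mixture = FALSE,
                           posteriorMethod = c("NEB", "BEB"),
                           posteriorThreshold = 0.95,
                           control = list()) {
  posteriorMethod <- match.arg(posteriorMethod)
  nullFit <- fitBranchSite(alignment, tree, "A1",
                           freqMethod = freqMethod,
                           nRestarts = nRestarts, control = control)
  altFit <- fitBranchSite(alignment, tree, "A",
                          branchLengths = if (reoptBranchLengths) NULL
                          else nullBranchLengths(nullFit),
                          nullFit = nullFit, freqMethod = freqMethod,
                          nRestarts = nRestarts, control = control)
  res <- lrt(nullFit, altFit, mixture = mixture)
  if (res$optimFailure) {
    ctl <- .fitControl(control)
    ctl$maxit <- 2L * ctl$maxit
    altFit2 <- fitBranchSite(alignment, tree, "A",
                             branchLengths = nullBranchLengths(nullFit),
                             nullFit = nullFit, freqMethod = freqMethod,
                             nRestarts = 3, control = ctl)
    if (altFit2@lnL > altFit@lnL) altFit <- altFit2
    res <- lrt(nullFit, altFit, mixture = mixture)
  }
  sites <- sitePosteriors(alignment, tree, altFit,
                          method = posteriorMethod)
  list(null = nullFit, alt = altFit,
       statistic = res$statistic, pValue = res$pValue,
       optimFailure = res$optimFailure,
       sites = sites,
       candidateSites = sites[sites$pSelected > posteriorThreshold, ,
                              drop = FALSE])
}
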