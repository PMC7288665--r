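# Branch-site model A parameter container and the four-class structure.

#' Construct branch-site model A parameters
#'
#' @param kappa transition/transversion ratio (> 0).
#' @param omega0 purifying-class dN/dS, in (0, 1).
#' @param omega2 foreground selected-class dN/dS (>= 1); fixed at 1 under
#'   the null model A1.
#' @param p0,p1 proportions of the purifying and neutral site classes;
#'   `p0 + p1 <= 1` and `p0 + p1 > 0`.
#' @param pi a [CodonFrequencies-class].
#' @param branchLengths optional per-edge lengths (tree edge order).
#' @return a [ModelAParams-class].
#' @examples
#' modelAParams(2, 0.1, 4, 0.7, 0.2, codonFrequencies(rep(1, 61)))
#' @export
modelAParams <- function(kappa, omega0, omega2 = 1, p0, p1,
                         pi = codonFrequencies(rep(1, 61), "equal"),
                         branchLengths = numeric()) {
  new("ModelAParams", kappa = kappa, omega0 = omega0, omega2 = omega2,
      p0 = p0, p1 = p1, pi = pi, branchLengths = as.numeric(branchLengths))
}

#' Site-class proportions (p0, p1, p2a, p2b)
#'
#' The two selected classes split the remaining mass `1 - p0 - p1` in
#' proportion to `p0 : p1`, i.e. `p2a = (1-p0-p1) p0/(p0+p1)` and
#' `p2b = (1-p0-p1) p1/(p0+p1)`.
#'
#' @param params a [ModelAParams-class].
#' @return named numeric vector summing to 1.
#' @export
siteClassProportions <- function(params) {
  p0 <- params@p0; p1 <- params@p1
  rest <- max(0, 1 - p0 - p1)
  c(p0 = p0, p1 = p1,
    p2a = rest * p0 / (p0 + p1),
    p2b = rest * p1 / (p0 + p1))
}

#' Site-class table of the branch-site model
#'
#' The four classes and their foreground/background dN/dS values: class 0
#' is purifying everywhere (`omega0`), class 1 neutral everywhere (1),
#' class 2a switches from `omega0` (background) to `omega2` (foreground),
#' class 2b from 1 to `omega2`.  Under the null model A1 the foreground
#' `omega2` is fixed at 1.
#'
#' @param params a [ModelAParams-class].
#' @param model `"A"` (alternative) or `"A1"` (null).
#' @return data.frame with columns `class`, `proportion`,
#'   `omegaForeground`, `omegaBackground`.
#' @export
siteClassTable <- function(params, model = c("A", "A1")) {
  model <- match.arg(model)
  w2 <- if (model == "A1") 1 else params@omega2
  pr <- siteClassProportions(params)
  data.frame(
    class = c("0", "1", "2a", "2b"),
    proportion = unname(pr),
    omegaForeground = c(params@omega0, 1, w2, w2),
    omegaBackground = c(params@omega0, 1, params@omega0, 1),
    stringsAsFactors = FALSE)
}

setMethod("show", "ModelAParams", function(object) {
  pr <- siteClassProportions(object)
  cat("ModelAParams: kappa=", signif(object@kappa, 4),
      " omega0=", signif(object@omega0, 4),
      " omega2=", signif(object@omega2, 4), "\n  proportions: ",
      paste(names(pr), signif(pr, 4), sep = "=", collapse = " "),
      "\n  pi: ", object@pi@method,
      if (length(object@branchLengths))
        paste0("; ", length(object@branchLengths), " branch lengths")
      else "; branch lengths unset",
      "\n", sep = "")
})

setMethod("show", "LikelihoodResult", function(object) {
  cat("LikelihoodResult (model ", object@model, "): lnL = ",
      sprintf("%.4f", object@lnL),
      if (!object@converged) "  [NOT converged]" else "",
      "\n", sep = "")
  show(object@params)
})
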