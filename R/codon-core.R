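# Codon alphabet, genetic code, substitution classification and the
# GY94-style rate matrix over the 61 sense codons.

.NUC <- c("A", "C", "G", "T")
.PURINES <- c("A", "G")

.allCodons <- function() {
  g <- expand.grid(p3 = .NUC, p2 = .NUC, p1 = .NUC,
                   stringsAsFactors = FALSE)
  sort(paste0(g$p1, g$p2, g$p3))
}

#' The standard nuclear genetic code
#'
#' Builds a [GeneticCode-class] from the standard code shipped with
#' \pkg{Biostrings}.  Alternative tables can be supplied as a named
#' 64-vector through `table`.
#'
#' @param table optional named character vector (triplet -> amino acid or
#'   `"*"`); defaults to the standard nuclear code.
#' @param tableId identifier stored with the code.
#' @return a [GeneticCode-class] object.
#' @examples
#' code <- standardGeneticCode()
#' translateCodon("ATG", code)
#' @export
standardGeneticCode <- function(table = NULL, tableId = "standard") {
  if (is.null(table)) {
    gc <- Biostrings::GENETIC_CODE
    table <- setNames(as.character(gc), names(gc))
  }
  codons <- .allCodons()
  if (!all(codons %in% names(table)))
    stop("genetic code table must cover all 64 triplets")
  new("GeneticCode", tableId = tableId, codonToAa = table[codons])
}

#' Sense codons of a genetic code
#'
#' @param code a [GeneticCode-class]; defaults to the standard code.
#' @return character vector of sense codons (61 under the standard code),
#'   in the fixed alphabetical order used as the model's state space.
#' @export
senseCodons <- function(code = standardGeneticCode()) {
  names(code@codonToAa)[code@codonToAa != "*"]
}

#' Translate a codon
#'
#' @param codon triplet (character scalar or vector).
#' @param code a [GeneticCode-class].
#' @return amino acid one-letter code, `"*"` for stops.
#' @export
translateCodon <- function(codon, code = standardGeneticCode()) {
  aa <- code@codonToAa[toupper(codon)]
  if (anyNA(aa)) stop("unknown codon(s): ",
                      paste(codon[is.na(aa)], collapse = ", "))
  unname(aa)
}

#' Is a codon a stop codon?
#' @inheritParams translateCodon
#' @return logical vector.
#' @export
isStopCodon <- function(codon, code = standardGeneticCode()) {
  translateCodon(codon, code) == "*"
}

#' Classify a single codon substitution
#'
#' Distinguishes the rate factors of the GY94 parameterisation: codon
#' pairs differing at two or more positions are `"multi-step"` (rate
#' zero); single-nucleotide exchanges are classified by synonymy (same
#' amino acid or not) and by transition (purine-purine or
#' pyrimidine-pyrimidine) versus transversion.
#'
#' @param codonI,codonJ sense codon triplets.
#' @param code a [GeneticCode-class].
#' @return one of `"multi-step"`, `"synonymous-transition"`,
#'   `"synonymous-transversion"`, `"nonsynonymous-transition"`,
#'   `"nonsynonymous-transversion"`.  Symmetric in its arguments.
#' @examples
#' classifySubstitution("TTT", "TTC")  # synonymous-transition (Phe/Phe)
#' @export
classifySubstitution <- function(codonI, codonJ,
                                 code = standardGeneticCode()) {
  codonI <- toupper(codonI); codonJ <- toupper(codonJ)
  aaI <- translateCodon(codonI, code); aaJ <- translateCodon(codonJ, code)
  if (aaI == "*" || aaJ == "*")
    stop("stop codons are outside the model state space")
  if (codonI == codonJ)
    stop("identical codons do not form a substitution")
  ci <- strsplit(codonI, "")[[1]]; cj <- strsplit(codonJ, "")[[1]]
  diff <- which(ci != cj)
  if (length(diff) > 1L) return("multi-step")
  transition <- (ci[diff] %in% .PURINES) == (cj[diff] %in% .PURINES)
  paste0(if (aaI == aaJ) "synonymous-" else "nonsynonymous-",
         if (transition) "transition" else "transversion")
}

# Precomputed single-step structure over the sense-codon state space:
# for each ordered pair (i, j) differing at one position, the row, column
# and multiplier selector (1 syn-tv, 2 syn-ts, 3 nonsyn-tv, 4 nonsyn-ts).
.codonPairStructure <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    code <- standardGeneticCode()
    codons <- senseCodons(code)
    n <- length(codons)
    chars <- do.call(rbind, strsplit(codons, ""))
    aa <- code@codonToAa[codons]
    ii <- jj <- tt <- integer(0)
    for (i in seq_len(n)) {
      ndiff <- rowSums(chars != matrix(chars[i, ], n, 3, byrow = TRUE))
      js <- which(ndiff == 1L)
      for (j in js) {
        pos <- which(chars[i, ] != chars[j, ])
        ts <- (chars[i, pos] %in% .PURINES) == (chars[j, pos] %in% .PURINES)
        syn <- aa[i] == aa[j]
        ii <- c(ii, i); jj <- c(jj, j)
        tt <- c(tt, 1L + ts + 2L * !syn)
      }
    }
    cache <<- list(codons = codons, i = ii, j = jj, type = tt,
                   idx = cbind(ii, jj))
    cache
  }
})

# Mean equilibrium rate of the *unscaled* GY94 matrix, linear in the
# four rate multipliers: rate = S1 + kappa S2 + omega S3 + omega kappa S4
# with S_t = sum over ordered single-step pairs of type t of pi_i pi_j.
# Used to scale all site classes by one common factor (the
# background-mixture average), preserving the relative acceleration of
# the selected class.
.codonRateParts <- function(piv) {
  st <- .codonPairStructure()
  w <- piv[st$i] * piv[st$j]
  vapply(1:4, function(t) sum(w[st$type == t]), 0)
}

.codonRate <- function(kappa, omega, parts) {
  parts[1] + kappa * parts[2] + omega * parts[3] + omega * kappa * parts[4]
}

# fast internal constructor of the scaled GY94 rate matrix (no S4, no
# dimnames) for the likelihood hot path
.codonQ <- function(kappa, omega, piv) {
  st <- .codonPairStructure()
  mult <- c(1, kappa, omega, omega * kappa)[st$type]
  q <- matrix(0, 61L, 61L)
  q[st$idx] <- mult * piv[st$j]
  diag(q) <- -rowSums(q)
  rate <- -sum(piv * diag(q))
  q / rate
}

#' Construct codon equilibrium frequencies
#'
#' @param pi numeric vector of length 61 (order of [senseCodons()]);
#'   will be normalised.
#' @param method label recorded with the object.
#' @return a [CodonFrequencies-class].
#' @export
codonFrequencies <- function(pi, method = "empirical") {
  codons <- senseCodons()
  if (length(pi) != length(codons))
    stop("pi must have one entry per sense codon")
  pi <- setNames(as.numeric(pi) / sum(pi), codons)
  new("CodonFrequencies", pi = pi, method = method)
}

#' Estimate codon equilibrium frequencies from an alignment
#'
#' `F3x4` (the default, matching the usual codeml convention) estimates
#' nucleotide frequencies separately at each codon position, forms codon
#' frequencies as position products, and renormalises over the sense
#' codons.  `F1x4` pools the three positions; `empirical` counts codons
#' directly; `equal` gives 1/61 to every sense codon.  A pseudocount of
#' one observation per nucleotide (or codon, for `empirical`) cell keeps
#' every frequency strictly positive on small alignments.
#'
#' @param alignment a [CodonAlignment-class].
#' @param method one of `"F3x4"`, `"F1x4"`, `"empirical"`, `"equal"`.
#' @param pseudocount added to each count cell; default 1.
#' @return a [CodonFrequencies-class].
#' @export
estimateCodonFrequencies <- function(alignment,
                                     method = c("F3x4", "F1x4",
                                                "empirical", "equal"),
                                     pseudocount = 1) {
  method <- match.arg(method)
  codons <- senseCodons()
  if (method == "equal")
    return(codonFrequencies(rep(1 / 61, 61), "equal"))
  if (length(alignment@taxa) == 0L || ncol(alignment@seqs) == 0L)
    stop("cannot estimate frequencies from an empty alignment")
  obs <- alignment@seqs[!is.na(alignment@states)]
  if (method == "empirical") {
    cnt <- table(factor(obs, levels = codons)) + pseudocount
    return(codonFrequencies(as.numeric(cnt), "empirical"))
  }
  chars <- do.call(rbind, strsplit(obs, ""))
  if (method == "F1x4") {
    f <- table(factor(chars, levels = .NUC)) + 3 * pseudocount
    f <- f / sum(f)
    fmat <- rbind(f, f, f)
  } else {
    fmat <- t(vapply(1:3, function(p) {
      f <- table(factor(chars[, p], levels = .NUC)) + pseudocount
      as.numeric(f / sum(f))
    }, numeric(4)))
    colnames(fmat) <- .NUC
  }
  cc <- do.call(rbind, strsplit(codons, ""))
  pi <- fmat[1, cc[, 1]] * fmat[2, cc[, 2]] * fmat[3, cc[, 3]]
  codonFrequencies(pi, method)
}

#' Build the GY94-style codon rate matrix
#'
#' Off-diagonal rate from codon i to codon j is 0 for multi-step changes
#' and otherwise `pi_j` times `kappa` for transitions and `omega` for
#' nonsynonymous changes.  The diagonal closes the rows to zero and, when
#' `scale = TRUE`, the matrix is normalised so that the expected rate at
#' equilibrium equals one substitution per codon per unit branch length.
#'
#' @param kappa transition/transversion ratio, > 0.
#' @param omega nonsynonymous/synonymous ratio, >= 0.
#' @param pi a [CodonFrequencies-class].
#' @param scale normalise the mean equilibrium rate to 1 (default).
#' @return a [RateMatrix-class].
#' @examples
#' q <- buildRateMatrix(2, 0.5, codonFrequencies(rep(1, 61)))
#' @export
buildRateMatrix <- function(kappa, omega, pi, scale = TRUE) {
  if (!is.numeric(kappa) || kappa <= 0)
    stop("kappa must be a positive number")
  if (!is.numeric(omega) || omega < 0)
    stop("omega must be non-negative")
  st <- .codonPairStructure()
  n <- length(st$codons)
  piv <- pi@pi
  mult <- c(1, kappa, omega, omega * kappa)[st$type]
  q <- matrix(0, n, n, dimnames = list(st$codons, st$codons))
  q[cbind(st$i, st$j)] <- mult * piv[st$j]
  diag(q) <- -rowSums(q)
  if (scale) {
    rate <- -sum(piv * diag(q))
    if (rate > 0) q <- q / rate
  }
  new("RateMatrix", q = q, kappa = kappa, omega = omega,
      pi = piv, scaled = scale)
}

# Symmetrised eigendecomposition of a reversible Q: returns factors such
# that P(t) = Vh %*% diag(exp(lam * t)) %*% W.  Exact because
# diag(sqrt(pi)) Q diag(1/sqrt(pi)) is symmetric under detailed balance.
.rateMatrixEigen <- function(q, pi) {
  s <- sqrt(pi)
  A <- q * outer(s, 1 / s)
  A <- (A + t(A)) / 2        # numerical symmetrisation
  e <- eigen(A, symmetric = TRUE)
  n <- length(s)
  list(Vh = e$vectors / s,                       # diag(1/s) %*% V
       W = t(e$vectors) * rep(s, each = n),      # t(V) %*% diag(s)
       lam = e$values)
}

.codonEigen <- function(kappa, omega, pi) {
  st <- .codonPairStructure()
  codon_eigen_cpp(kappa, omega, st$i - 1L, st$j - 1L, st$type, pi@pi)
}

#' Transition probability matrix P(t) = exp(Qt)
#'
#' Computed through the symmetrised eigendecomposition available for
#' time-reversible rate matrices, with a dense matrix-exponential
#' fallback (\code{Matrix::expm}) if the decomposition is
#' ill-conditioned.
#'
#' @param rateMatrix a [RateMatrix-class].
#' @param t branch length, >= 0.
#' @return 61 x 61 stochastic matrix; rows sum to 1.
#' @export
transitionMatrix <- function(rateMatrix, t) {
  if (!is.numeric(t) || length(t) != 1L || is.na(t) || t < 0)
    stop("t must be a single non-negative number")
  eg <- .rateMatrixEigen(rateMatrix@q, rateMatrix@pi)
  p <- eg$Vh %*% (exp(eg$lam * t) * eg$W)
  if (any(!is.finite(p)) || max(abs(rowSums(p) - 1)) > 1e-7) {
    p <- as.matrix(Matrix::expm(rateMatrix@q * t))
  }
  p[p < 0] <- 0
  dimnames(p) <- dimnames(rateMatrix@q)
  p
}
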