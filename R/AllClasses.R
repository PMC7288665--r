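#' @import methods
#' @importFrom stats optim pchisq p.adjust runif rbinom setNames
#' @importFrom utils read.delim write.table
#' @useDynLib PSGscan, .registration = TRUE
#' @importFrom Rcpp evalCpp
NULL

#' Genetic code table
#'
#' Maps each of the 64 nucleotide triplets to an amino acid (one-letter
#' code) or `"*"` for a stop.  Only the 61 sense codons of the standard
#' nuclear code form the state space of the codon substitution model; stop
#' codons are excluded everywhere downstream.
#'
#' @slot tableId identifier of the code table (e.g. `"standard"`).
#' @slot codonToAa named character vector of length 64; names are triplets
#'   over `{A,C,G,T}`, values are amino acids or `"*"`.
#' @export
setClass("GeneticCode",
  representation(tableId = "character", codonToAa = "character"),
  validity = function(object) {
    msg <- character()
    if (length(object@codonToAa) != 64L)
      msg <- c(msg, "codonToAa must have 64 entries")
    if (anyNA(object@codonToAa))
      msg <- c(msg, "translation must be total (no NA)")
    if (sum(object@codonToAa != "*") != 61L && object@tableId == "standard")
      msg <- c(msg, "standard code must have exactly 61 sense codons")
    if (length(msg)) msg else TRUE
  })

#' Equilibrium codon frequencies
#'
#' A probability vector over the 61 sense codons, together with the
#' estimation method that produced it.
#'
#' @slot pi named numeric vector of length 61 summing to 1; all entries
#'   strictly positive (a pseudocount is applied during estimation).
#' @slot method one of `"equal"`, `"F1x4"`, `"F3x4"`, `"empirical"`.
#' @export
setClass("CodonFrequencies",
  representation(pi = "numeric", method = "character"),
  validity = function(object) {
    msg <- character()
    if (length(object@pi) != 61L)
      msg <- c(msg, "pi must have 61 entries (sense codons)")
    if (any(object@pi <= 0))
      msg <- c(msg, "all frequencies must be > 0")
    if (abs(sum(object@pi) - 1) > 1e-12)
      msg <- c(msg, "frequencies must sum to 1 within 1e-12")
    if (length(msg)) msg else TRUE
  })

#' Codon substitution rate matrix
#'
#' Instantaneous rate matrix of the GY94-style codon model with
#' transition/transversion ratio `kappa` and nonsynonymous/synonymous
#' ratio `omega`; rate to a target codon is proportional to that codon's
#' equilibrium frequency.  Codons differing at two or more positions have
#' rate zero.  The matrix is time-reversible with respect to `pi` and,
#' when `scaled`, normalised so the expected substitution rate at
#' equilibrium is one (branch lengths are then expected substitutions per
#' codon).
#'
#' @slot q 61 x 61 rate matrix, rows summing to zero.
#' @slot kappa transition/transversion rate ratio.
#' @slot omega nonsynonymous/synonymous rate ratio.
#' @slot pi equilibrium frequencies used to build the matrix.
#' @slot scaled logical; `TRUE` when the mean equilibrium rate is 1.
#' @export
setClass("RateMatrix",
  representation(q = "matrix", kappa = "numeric", omega = "numeric",
                 pi = "numeric", scaled = "logical"))

#' In-frame codon alignment for one orthologous group
#'
#' Aligned coding sequences stored codon-wise.  Gap codons (`---`) and
#' codons containing any non-`ACGT` character are treated as fully missing
#' data by the likelihood machinery.  In-frame stop codons are rejected at
#' construction.
#'
#' @slot taxa character vector of unique taxon names (row order).
#' @slot seqs character matrix, taxa x codon sites, entries are triplets.
#' @slot states integer matrix of the same shape: index of the sense codon
#'   (1..61) or `NA` for gap/ambiguous codons.
#' @slot groupId orthologous-group identifier.
#' @slot lineageTags named character vector mapping taxa to roles
#'   (`"foreground-species"`, `"counter-foreground"`, `"ingroup"`,
#'   `"outgroup"`); may be empty.
#' @export
setClass("CodonAlignment",
  representation(taxa = "character", seqs = "matrix", states = "matrix",
                 groupId = "character", lineageTags = "character"),
  validity = function(object) {
    msg <- character()
    if (anyDuplicated(object@taxa))
      msg <- c(msg, "taxon names must be unique")
    if (nrow(object@seqs) != length(object@taxa))
      msg <- c(msg, "seqs rows must match taxa")
    if (!identical(dim(object@seqs), dim(object@states)))
      msg <- c(msg, "seqs and states must have the same shape")
    if (length(msg)) msg else TRUE
  })

#' Phylogeny with a flagged foreground branch
#'
#' Wraps an \code{ape} \code{phylo} object (with branch lengths in
#' expected substitutions per codon) and flags exactly one branch as the
#' foreground lineage of the branch-site model; all other branches are
#' background.
#'
#' @slot phy an \code{ape::phylo} tree with `edge.length`.
#' @slot foregroundEdge integer index into `phy$edge` rows; exactly one.
#' @export
setClass("LabeledTree",
  representation(phy = "ANY", foregroundEdge = "integer"),
  validity = function(object) {
    msg <- character()
    if (!inherits(object@phy, "phylo"))
      msg <- c(msg, "phy must be an ape phylo object")
    else {
      if (is.null(object@phy$edge.length))
        msg <- c(msg, "tree must have branch lengths")
      else if (any(object@phy$edge.length < 0))
        msg <- c(msg, "branch lengths must be non-negative")
      if (length(object@foregroundEdge) != 1L ||
          is.na(object@foregroundEdge) ||
          object@foregroundEdge < 1L ||
          object@foregroundEdge > nrow(object@phy$edge))
        msg <- c(msg, "exactly one valid foreground edge is required")
      if (anyDuplicated(object@phy$tip.label))
        msg <- c(msg, "tip labels must be unique")
    }
    if (length(msg)) msg else TRUE
  })

#' Branch-site model A parameters
#'
#' Free parameters of the branch-site model: `kappa`, the purifying ratio
#' `omega0` in (0,1), the foreground selection ratio `omega2 >= 1`, the
#' site-class weights `p0` and `p1`, equilibrium codon frequencies and
#' per-branch lengths.  The proportions of the four site classes are
#' `(p0, p1, p2a, p2b)` with `p2a = (1-p0-p1) p0/(p0+p1)` and
#' `p2b = (1-p0-p1) p1/(p0+p1)`.  The null model is the restriction
#' `omega2 = 1`.
#'
#' @slot kappa transition/transversion ratio, > 0.
#' @slot omega0 purifying-class dN/dS, in (0,1).
#' @slot omega2 foreground selected-class dN/dS, >= 1.
#' @slot p0,p1 base class proportions, `p0 + p1 <= 1`, `p0 + p1 > 0`.
#' @slot pi a [CodonFrequencies-class].
#' @slot branchLengths numeric vector of per-edge lengths (edge order of
#'   the associated tree); may be length 0 when unset.
#' @export
setClass("ModelAParams",
  representation(kappa = "numeric", omega0 = "numeric", omega2 = "numeric",
                 p0 = "numeric", p1 = "numeric", pi = "CodonFrequencies",
                 branchLengths = "numeric"),
  validity = function(object) {
    msg <- character()
    if (object@kappa <= 0) msg <- c(msg, "kappa must be > 0")
    if (object@omega0 <= 0 || object@omega0 >= 1)
      msg <- c(msg, "omega0 must be in (0, 1)")
    if (object@omega2 < 1) msg <- c(msg, "omega2 must be >= 1")
    if (object@p0 < 0 || object@p1 < 0)
      msg <- c(msg, "proportions must be non-negative")
    if (object@p0 + object@p1 > 1 + 1e-12)
      msg <- c(msg, "p0 + p1 must be <= 1")
    if (object@p0 + object@p1 <= 0)
      msg <- c(msg, "p0 + p1 must be > 0")
    if (any(object@branchLengths < 0))
      msg <- c(msg, "branch lengths must be non-negative")
    if (length(msg)) msg else TRUE
  })

#' Result of a (fitted or evaluated) branch-site likelihood
#'
#' @slot lnL total log-likelihood.
#' @slot perSiteLnL per-codon-site log-likelihoods (sums to `lnL`).
#' @slot params the [ModelAParams-class] at which the likelihood was
#'   evaluated (for fits, the maximum-likelihood estimates).
#' @slot model `"A"` (alternative) or `"A1"` (null, omega2 fixed at 1).
#' @slot converged logical optimisation status (`TRUE` for plain
#'   evaluations).
#' @slot nRestartsUsed number of optimisation starts actually run.
#' @export
setClass("LikelihoodResult",
  representation(lnL = "numeric", perSiteLnL = "numeric",
                 params = "ModelAParams", model = "character",
                 converged = "logical", nRestartsUsed = "integer"),
  validity = function(object) {
    if (length(object@perSiteLnL) &&
        abs(sum(object@perSiteLnL) - object@lnL) > 1e-6)
      "lnL must equal the sum of per-site log-likelihoods within 1e-6"
    else TRUE
  })

#' One orthologous group ready for scanning
#'
#' @slot groupId group identifier.
#' @slot alignment a [CodonAlignment-class].
#' @slot tree a [LabeledTree-class] or `NULL` (a neighbour-joining
#'   fallback topology is built when absent).
#' @slot speciesRoles named character vector taxon -> role.
#' @export
setClass("OrthologGroup",
  representation(groupId = "character", alignment = "CodonAlignment",
                 tree = "ANY", speciesRoles = "character"))
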