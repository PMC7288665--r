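# Group-level quality-control filters of the scan: the half-mean
# sequence-length rule and the minimum-taxa requirements.

#' Construct an ortholog group
#'
#' @param alignment a [CodonAlignment-class].
#' @param tree an \code{ape::phylo} tree over the same taxa, or `NULL`
#'   (a neighbour-joining fallback is built from codon distances at test
#'   time, and logged).
#' @param speciesRoles named character vector taxon -> role
#'   (`"foreground-species"`, `"counter-foreground"`, `"ingroup"`,
#'   `"outgroup"`); defaults to the alignment's lineage tags.
#' @param groupId identifier; defaults to the alignment's.
#' @return an [OrthologGroup-class].
#' @export
orthologGroup <- function(alignment, tree = NULL,
                          speciesRoles = alignment@lineageTags,
                          groupId = alignment@groupId) {
  new("OrthologGroup", groupId = as.character(groupId),
      alignment = alignment, tree = tree, speciesRoles = speciesRoles)
}

setMethod("show", "OrthologGroup", function(object) {
  cat("OrthologGroup '", object@groupId, "': ",
      length(object@alignment@taxa), " taxa, ",
      ncol(object@alignment@seqs), " codon sites",
      if (is.null(object@tree)) " (no tree)" else "", "\n", sep = "")
})

#' Drop sequences shorter than half the group's mean length
#'
#' Removes, in a single pass, every sequence whose ungapped nucleotide
#' length is strictly less than half the mean ungapped length of the
#' group, the mean being computed over all sequences before any removal
#' (so the outcome does not depend on processing order).
#'
#' @param group an [OrthologGroup-class].
#' @return list with `group` (sequences dropped), `dropped` (data.frame
#'   `taxon`, `reason`), `excluded` and `exclusionReason` (set when no
#'   sequence survives).
#' @examples
#' # lengths (300, 300, 120): half-mean is 120, and 120 is NOT < 120,
#' # so nothing is dropped (strict inequality)
#' @export
filterShortSequences <- function(group) {
  lens <- ungappedLengths(group@alignment)
  half <- mean(lens) / 2
  drop <- names(lens)[lens < half]
  dropped <- data.frame(taxon = drop,
                        reason = rep("shorter-than-half-mean",
                                     length(drop)),
                        stringsAsFactors = FALSE)
  keep <- setdiff(group@alignment@taxa, drop)
  if (!length(keep))
    return(list(group = group, dropped = dropped, excluded = TRUE,
                exclusionReason = "too-few-species"))
  aln <- subsetTaxa(group@alignment, keep)
  tree <- group@tree
  if (!is.null(tree) && length(drop))
    tree <- ape::drop.tip(tree, intersect(tree$tip.label, drop))
  list(group = new("OrthologGroup", groupId = group@groupId,
                   alignment = aln, tree = tree,
                   speciesRoles = group@speciesRoles[
                     names(group@speciesRoles) %in% keep]),
       dropped = dropped, excluded = FALSE, exclusionReason = "none")
}

#' Exclude groups with insufficient taxon sampling
#'
#' A group is excluded when, after sequence-level filtering, it has
#' fewer than `minSpecies` species, fewer than `minIngroup` ingroup
#' species (the ingroup comprises every non-outgroup taxon, i.e. the
#' foreground species, the counter-foreground and the `"ingroup"`-tagged
#' taxa), or is missing the foreground species, the counter-foreground,
#' or all outgroups.
#'
#' @param group an [OrthologGroup-class] (after
#'   [filterShortSequences()]).
#' @param minSpecies minimum total species (default 5).
#' @param minIngroup minimum ingroup species (default 4).
#' @return list with `excluded` (logical) and `exclusionReason` (one of
#'   `"too-few-species"`, `"too-few-ingroup"`,
#'   `"missing-required-taxon"`, `"none"`).
#' @export
filterGroupMinimumTaxa <- function(group, minSpecies = 5,
                                   minIngroup = 4) {
  taxa <- group@alignment@taxa
  roles <- group@speciesRoles[taxa]
  nIngroup <- sum(roles %in% c("ingroup", "foreground-species",
                               "counter-foreground"))
  reason <- if (length(taxa) < minSpecies) "too-few-species"
  else if (nIngroup < minIngroup) "too-few-ingroup"
  else if (!any(roles == "foreground-species") ||
           !any(roles == "counter-foreground") ||
           !any(roles == "outgroup")) "missing-required-taxon"
  else "none"
  list(excluded = reason != "none", exclusionReason = reason)
}

#' Apply all group-level filters
#'
#' Runs [filterShortSequences()] then [filterGroupMinimumTaxa()] and
#' returns the surviving group together with a one-row filter report.
#'
#' @inheritParams filterGroupMinimumTaxa
#' @return list with `group` (possibly reduced; `NULL` when excluded),
#'   `report` (data.frame `groupId`, `nDropped`, `droppedTaxa`,
#'   `excluded`, `exclusionReason`).
#' @export
applyGroupFilters <- function(group, minSpecies = 5, minIngroup = 4) {
  fs <- filterShortSequences(group)
  if (fs$excluded) {
    rep <- data.frame(groupId = group@groupId,
                      nDropped = nrow(fs$dropped),
                      droppedTaxa = paste(fs$dropped$taxon,
                                          collapse = ","),
                      excluded = TRUE,
                      exclusionReason = fs$exclusionReason,
                      stringsAsFactors = FALSE)
    return(list(group = NULL, report = rep))
  }
  ft <- filterGroupMinimumTaxa(fs$group, minSpecies, minIngroup)
  rep <- data.frame(groupId = group@groupId,
                    nDropped = nrow(fs$dropped),
                    droppedTaxa = paste(fs$dropped$taxon, collapse = ","),
                    excluded = ft$excluded,
                    exclusionReason = ft$exclusionReason,
                    stringsAsFactors = FALSE)
  list(group = if (ft$excluded) NULL else fs$group, report = rep)
}
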