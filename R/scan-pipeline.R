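# The dual-foreground scan: test scheduling, per-group branch-site
# tests, pooled FDR correction, the exclusivity cross-validation rule,
# site-level filters and final verdicts.

#' Schedule the likelihood-ratio tests of a scan
#'
#' Every group is tested twice: once with the foreground species'
#' terminal branch as foreground (test I) and once with the
#' counter-foreground's (test II).  All scheduled tests form a single
#' FDR family, so `nrow` of the schedule is exactly twice the number of
#' groups.
#'
#' @param groupIds character vector of group identifiers (groups that
#'   passed the filters).
#' @return data.frame with columns `groupId` and `test` (`"I"`/`"II"`),
#'   two rows per group.
#' @export
scheduleTests <- function(groupIds) {
  if (is.list(groupIds))
    groupIds <- vapply(groupIds, function(g) g@groupId, "")
  data.frame(groupId = rep(groupIds, each = 2L),
             test = rep(c("I", "II"), length(groupIds)),
             stringsAsFactors = FALSE)
}

# neighbour-joining fallback topology from codon mismatch distances
.njFallbackTree <- function(aln) {
  st <- aln@states
  n <- nrow(st)
  d <- matrix(0, n, n, dimnames = list(aln@taxa, aln@taxa))
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    ok <- !is.na(st[i, ]) & !is.na(st[j, ])
    d[i, j] <- d[j, i] <- if (any(ok))
      mean(st[i, ok] != st[j, ok]) else 0.5
  }
  phy <- ape::nj(as.dist(d))
  phy$edge.length[phy$edge.length < 1e-4] <- 1e-4
  phy
}

#' Run both branch-site tests on one group
#'
#' Test I flags the terminal branch of the foreground species, test II
#' the terminal branch of the counter-foreground species; everything
#' else about the two tests is identical.  Candidate sites are the
#' positions with selected-class posterior above `posteriorThreshold`
#' under each test's alternative fit.
#'
#' @param group an [OrthologGroup-class] that passed the filters.
#' @param alpha retained in the records for downstream thresholding.
#' @param posteriorThreshold candidate-site posterior cutoff
#'   (default 0.95).
#' @param posteriorMethod `"NEB"` or `"BEB"`.
#' @param mixture use the mixture null for p-values (see [lrt()]).
#' @param control optimiser controls (see [fitBranchSite()]).
#' @return list with `records` (two-row data.frame: `groupId`, `test`,
#'   `foreground`, `lnLNull`, `lnLAlt`, `statistic`, `pValue`,
#'   `qValue` (NA until [correctFDR()]), `nCandidateSites`,
#'   `optimFailure`, `treeFallback`) and `sites` (candidate-site rows:
#'   `groupId`, `test`, `site`, `pSelected`).
#' @export
runDualTests <- function(group, alpha = 0.05, posteriorThreshold = 0.95,
                         posteriorMethod = "NEB", mixture = FALSE,
                         control = list()) {
  roles <- group@speciesRoles
  fgTaxon <- names(roles)[roles == "foreground-species"][1]
  cfTaxon <- names(roles)[roles == "counter-foreground"][1]
  treeFallback <- is.null(group@tree)
  phy <- if (treeFallback) .njFallbackTree(group@alignment) else
    group@tree
  oneTest <- function(label, taxon) {
    bt <- branchSiteTest(group@alignment, labeledTree(phy, taxon),
                         posteriorMethod = posteriorMethod,
                         posteriorThreshold = posteriorThreshold,
                         mixture = mixture, control = control)
    rec <- data.frame(groupId = group@groupId, test = label,
                      foreground = taxon,
                      lnLNull = bt$null@lnL, lnLAlt = bt$alt@lnL,
                      statistic = bt$statistic, pValue = bt$pValue,
                      qValue = NA_real_,
                      nCandidateSites = nrow(bt$candidateSites),
                      optimFailure = bt$optimFailure ||
                        !(bt$null@converged && bt$alt@converged),
                      treeFallback = treeFallback,
                      stringsAsFactors = FALSE)
    sites <- if (nrow(bt$candidateSites))
      data.frame(groupId = group@groupId, test = label,
                 site = bt$candidateSites$site,
                 pSelected = bt$candidateSites$pSelected,
                 stringsAsFactors = FALSE)
    else data.frame(groupId = character(), test = character(),
                    site = integer(), pSelected = numeric())
    list(record = rec, sites = sites)
  }
  t1 <- oneTest("I", fgTaxon)
  t2 <- oneTest("II", cfTaxon)
  list(records = rbind(t1$record, t2$record),
       sites = rbind(t1$sites, t2$sites))
}

#' Benjamini-Hochberg correction over the pooled test family
#'
#' All test records — both foreground assignments of every group — form
#' one family; q-values are the BH step-up adjusted p-values.
#'
#' @param records data.frame of test records with a `pValue` column.
#' @return the records with `qValue` filled in.
#' @export
correctFDR <- function(records) {
  if (!nrow(records)) return(records)
  records$qValue <- p.adjust(records$pValue, method = "BH")
  records
}

#' The dual-foreground exclusivity rule
#'
#' A test is *positive* when its q-value is at most `alpha` AND it has
#' at least one candidate site above the posterior threshold.  A group
#' is a candidate lineage-exclusive PSG if and only if test I is
#' positive and test II is not; positive selection inferred in both
#' lineages — whether on the same or on different codon sites — discards
#' the gene.
#'
#' @param recordI,recordII one-row test records for the same group
#'   (q-values assigned).
#' @param alpha q-value threshold (default 0.05).
#' @return list with `candidate` (logical), `reason` (one of
#'   `"test-I-not-positive"`, `"positive-in-both"`, `"candidate"`, or
#'   `"optimization-failure"`).
#' @export
exclusivityRule <- function(recordI, recordII, alpha = 0.05) {
  if (isTRUE(recordI$optimFailure) || isTRUE(recordII$optimFailure))
    return(list(candidate = FALSE, reason = "optimization-failure"))
  positive <- function(r) r$qValue <= alpha && r$nCandidateSites >= 1
  pI <- positive(recordI); pII <- positive(recordII)
  if (pI && pII) list(candidate = FALSE, reason = "positive-in-both")
  else if (!pI) list(candidate = FALSE, reason = "test-I-not-positive")
  else list(candidate = TRUE, reason = "candidate")
}

#' Remove candidate sites in gap-rich alignment regions
#'
#' Automated proxy for manual curation of low-quality alignment
#' regions: a candidate site is removed when the mean gap fraction
#' across taxa within `window` codons on either side (the window is
#' truncated at the alignment ends) exceeds `maxGapFraction`.  A codon
#' containing any gap character counts as gapped.
#'
#' @param alignment a [CodonAlignment-class].
#' @param sites integer vector of candidate codon sites.
#' @param window half-width in codons (default 5).
#' @param maxGapFraction removal threshold (default 0.5).
#' @return data.frame `site`, `gapFraction`, `removed`.
#' @export
siteQualityFilter <- function(alignment, sites, window = 5,
                              maxGapFraction = 0.5) {
  if (!length(sites))
    return(data.frame(site = integer(), gapFraction = numeric(),
                      removed = logical()))
  gapped <- matrix(grepl("-", alignment@seqs, fixed = TRUE),
                   nrow(alignment@seqs))
  L <- ncol(gapped)
  gf <- vapply(sites, function(s) {
    cols <- max(1L, s - window):min(L, s + window)
    mean(gapped[, cols])
  }, 0)
  data.frame(site = sites, gapFraction = gf,
             removed = gf > maxGapFraction)
}

#' Remove candidate sites whose foreground codon codes for serine
#'
#' Serine is reachable through two disconnected codon families (TCN and
#' AGY), so apparent selection at serine sites can be an artifact of
#' multiple synonymous paths; such sites are excluded.  The amino acid
#' is read from the foreground species' codon; if that codon is gapped
#' or ambiguous the site is removed as indeterminate.
#'
#' @param alignment a [CodonAlignment-class].
#' @param sites integer vector of candidate codon sites.
#' @param foregroundTaxon taxon whose codon defines the site's amino
#'   acid; defaults to the alignment's `"foreground-species"` tag.
#' @return data.frame `site`, `codon`, `aa`, `removed`, `reason`
#'   (`"serine"`, `"serine-indeterminate"` or `"none"`).
#' @export
serineSiteFilter <- function(alignment, sites,
                             foregroundTaxon = NULL) {
  if (is.null(foregroundTaxon)) {
    tags <- alignment@lineageTags
    foregroundTaxon <- names(tags)[tags == "foreground-species"][1]
  }
  if (length(foregroundTaxon) != 1L || is.na(foregroundTaxon) ||
      !foregroundTaxon %in% alignment@taxa)
    stop("cannot resolve the foreground species' sequence")
  if (!length(sites))
    return(data.frame(site = integer(), codon = character(),
                      aa = character(), removed = logical(),
                      reason = character()))
  row <- match(foregroundTaxon, alignment@taxa)
  codon <- alignment@seqs[row, sites]
  state <- alignment@states[row, sites]
  aa <- rep(NA_character_, length(sites))
  aa[!is.na(state)] <- translateCodon(codon[!is.na(state)])
  removed <- is.na(state) | (!is.na(aa) & aa == "S")
  reason <- ifelse(is.na(state), "serine-indeterminate",
                   ifelse(aa == "S", "serine", "none"))
  data.frame(site = sites, codon = codon, aa = aa,
             removed = removed, reason = reason,
             stringsAsFactors = FALSE)
}

#' Final verdicts over all processed groups
#'
#' A gene is a lineage-exclusive PSG if and only if it survived the
#' exclusivity rule and at least one of its test-I candidate sites
#' survives both the alignment-quality and the serine filter.
#'
#' @param verdicts data.frame assembled by [runScan()] (one row per
#'   tested group with `candidate` and surviving-site counts).
#' @return the data.frame with an `isPsgExclusive` column.
#' @export
finalizePSGSet <- function(verdicts) {
  verdicts$isPsgExclusive <- verdicts$candidate &
    verdicts$nSurvivingSites >= 1
  verdicts
}

#' Run the full dual-foreground positive-selection scan
#'
#' End to end: group filters, dual branch-site tests, pooled BH FDR,
#' the exclusivity rule, site-level filters, final PSG verdicts.
#'
#' @param groups a [SimulatedGroupSet-class], a list of
#'   [OrthologGroup-class], or a directory in the layout written by
#'   [writeGroupSet()].
#' @param alpha q-value threshold for positivity (default 0.05).
#' @param posteriorThreshold candidate-site posterior cutoff (0.95).
#' @param minSpecies,minIngroup see [filterGroupMinimumTaxa()].
#' @param window,maxGapFraction see [siteQualityFilter()].
#' @param posteriorMethod `"NEB"` or `"BEB"`.
#' @param mixture use the mixture null distribution for p-values.
#' @param seed recorded in the manifest (the scan itself is
#'   deterministic; the seed documents the provenance of simulated
#'   inputs).
#' @param control optimiser controls (see [fitBranchSite()]).
#' @param verbose print progress.
#' @return a list of class `ScanReport`: data.frames `tests`,
#'   `verdicts`, `sites`, `filterLog` and a `manifest` list (settings,
#'   seed, config hash).
#' @export
runScan <- function(groups, alpha = 0.05, posteriorThreshold = 0.95,
                    minSpecies = 5, minIngroup = 4, window = 5,
                    maxGapFraction = 0.5, posteriorMethod = "NEB",
                    mixture = FALSE, seed = NA_integer_,
                    control = list(), verbose = FALSE) {
  if (is(groups, "SimulatedGroupSet")) groups <- groups@groups
  if (is.character(groups) && length(groups) == 1L)
    groups <- readGroupsDir(groups)

  filterLog <- list(); kept <- list()
  for (g in groups) {
    fr <- applyGroupFilters(g, minSpecies, minIngroup)
    filterLog[[length(filterLog) + 1L]] <- fr$report
    if (!is.null(fr$group)) kept[[length(kept) + 1L]] <- fr$group
  }
  filterLog <- do.call(rbind, filterLog)

  schedule <- scheduleTests(kept)
  records <- list(); siteRows <- list()
  for (i in seq_along(kept)) {
    if (verbose) message("testing group ", kept[[i]]@groupId,
                         " (", i, "/", length(kept), ")")
    dt <- runDualTests(kept[[i]], alpha = alpha,
                       posteriorThreshold = posteriorThreshold,
                       posteriorMethod = posteriorMethod,
                       mixture = mixture, control = control)
    records[[i]] <- dt$records
    siteRows[[i]] <- dt$sites
  }
  tests <- correctFDR(do.call(rbind, records))
  sites <- do.call(rbind, siteRows)
  stopifnot(nrow(tests) == nrow(schedule))

  verdictRows <- list(); keptSiteRows <- list()
  for (i in seq_along(kept)) {
    g <- kept[[i]]
    recI <- tests[tests$groupId == g@groupId & tests$test == "I", ]
    recII <- tests[tests$groupId == g@groupId & tests$test == "II", ]
    ex <- exclusivityRule(recI, recII, alpha)
    candSites <- sites[sites$groupId == g@groupId & sites$test == "I",
                       "site"]
    nSurv <- 0L
    if (ex$candidate && length(candSites)) {
      qual <- siteQualityFilter(g@alignment, candSites, window,
                                maxGapFraction)
      left <- qual$site[!qual$removed]
      ser <- serineSiteFilter(g@alignment, left,
                              names(g@speciesRoles)[
                                g@speciesRoles == "foreground-species"][1])
      surv <- ser$site[!ser$removed]
      nSurv <- length(surv)
      if (length(candSites)) {
        log1 <- data.frame(groupId = g@groupId, site = qual$site,
                           stage = "alignment-quality",
                           removed = qual$removed,
                           reason = ifelse(qual$removed,
                                           "low-quality-region", "none"),
                           stringsAsFactors = FALSE)
        log2 <- if (nrow(ser))
          data.frame(groupId = g@groupId, site = ser$site,
                     stage = "serine", removed = ser$removed,
                     reason = ser$reason, stringsAsFactors = FALSE)
        else NULL
        keptSiteRows[[length(keptSiteRows) + 1L]] <- rbind(log1, log2)
      }
    }
    verdictRows[[i]] <- data.frame(
      groupId = g@groupId, candidate = ex$candidate,
      reason = ex$reason, nCandidateSites = length(candSites),
      nSurvivingSites = nSurv, stringsAsFactors = FALSE)
  }
  verdicts <- finalizePSGSet(do.call(rbind, verdictRows))
  removalLog <- if (length(keptSiteRows)) do.call(rbind, keptSiteRows)
  else data.frame(groupId = character(), site = integer(),
                  stage = character(), removed = logical(),
                  reason = character())

  settings <- list(alpha = alpha,
                   posteriorThreshold = posteriorThreshold,
                   minSpecies = minSpecies, minIngroup = minIngroup,
                   window = window, maxGapFraction = maxGapFraction,
                   posteriorMethod = posteriorMethod,
                   mixture = mixture)
  cfg <- tempfile()
  writeLines(paste(names(unlist(settings)), unlist(settings),
                   sep = "="), cfg)
  manifest <- list(settings = settings, seed = seed,
                   nGroupsInput = length(groups),
                   nGroupsTested = length(kept),
                   nTests = nrow(tests),
                   configHash = unname(tools::md5sum(cfg)))
  unlink(cfg)
  structure(list(tests = tests, verdicts = verdicts,
                 sites = sites, removalLog = removalLog,
                 filterLog = filterLog, manifest = manifest),
            class = "ScanReport")
}

#' Print a scan report summary
#' @param x a `ScanReport` from [runScan()].
#' @param ... ignored.
#' @return `x`, invisibly.
#' @exportS3Method base::print
print.ScanReport <- function(x, ...) {
  cat("ScanReport:", x$manifest$nGroupsTested, "of",
      x$manifest$nGroupsInput, "groups tested (",
      x$manifest$nTests, "LRTs in one FDR family );",
      sum(x$verdicts$isPsgExclusive), "exclusive PSGs\n")
  invisible(x)
}

#' Write a scan report as TSV files
#'
#' Emits `tests.tsv`, `verdicts.tsv`, `sites.tsv`, `filter_log.tsv`,
#' `removal_log.tsv` and `manifest.txt` into `dir`.  Output is
#' deterministic: identical inputs give byte-identical files.
#'
#' @param report a `ScanReport` from [runScan()].
#' @param dir output directory (created).
#' @return `dir`, invisibly.
#' @export
writeScanReport <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  wt <- function(df, name) {
    num <- vapply(df, is.numeric, TRUE) & !vapply(df, is.integer, TRUE)
    df[num] <- lapply(df[num], function(x) sprintf("%.10g", x))
    write.table(df, file.path(dir, name), sep = "\t", quote = FALSE,
                row.names = FALSE)
  }
  wt(report$tests, "tests.tsv")
  wt(report$verdicts, "verdicts.tsv")
  wt(report$sites, "sites.tsv")
  wt(report$filterLog, "filter_log.tsv")
  wt(report$removalLog, "removal_log.tsv")
  writeLines(c(paste0("configHash\t", report$manifest$configHash),
               paste0("seed\t", report$manifest$seed),
               paste0("nGroupsInput\t", report$manifest$nGroupsInput),
               paste0("nGroupsTested\t", report$manifest$nGroupsTested),
               paste0("nTests\t", report$manifest$nTests)),
             file.path(dir, "manifest.txt"))
  invisible(dir)
}

#' Read a directory of per-group FASTA + Newick + roles
#'
#' Expects the layout written by [writeGroupSet()]: `<group>.fasta`,
#' `<group>.nwk` (optional) and a `roles.tsv` (columns `taxon`,
#' `role`).
#'
#' @param dir directory path.
#' @return list of [OrthologGroup-class].
#' @export
readGroupsDir <- function(dir) {
  rolesFile <- file.path(dir, "roles.tsv")
  roles <- if (file.exists(rolesFile)) {
    df <- read.delim(rolesFile, stringsAsFactors = FALSE)
    setNames(df$role, df$taxon)
  } else character()
  fas <- sort(list.files(dir, pattern = "\\.(fa|fasta)$",
                         full.names = TRUE))
  lapply(fas, function(f) {
    gid <- sub("\\.[^.]*$", "", basename(f))
    aln <- readCodonAlignment(f, groupId = gid)
    aln@lineageTags <- roles[names(roles) %in% aln@taxa]
    nwk <- file.path(dir, paste0(gid, ".nwk"))
    tree <- if (file.exists(nwk)) ape::read.tree(nwk) else NULL
    orthologGroup(aln, tree, speciesRoles = aln@lineageTags,
                  groupId = gid)
  })
}
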