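# Cross-reference of final PSG verdicts against tissue expression and
# regulation tables: presence, tissue exclusivity, regulation overlap.

#' Read a tissue-expression table
#'
#' TSV with columns `gene_id`, `tissue`, `expressed` (logical or 0/1)
#' and optional `regulation` (`up`/`down`/`unchanged`/NA) and
#' `contrast`.  Rows must be unique on (gene, tissue, contrast).
#'
#' @param file path.
#' @return data.frame in the canonical column layout.
#' @export
readExpressionTable <- function(file) {
  df <- read.delim(file, stringsAsFactors = FALSE)
  .validateExpressionTable(df)
}

.validateExpressionTable <- function(df) {
  need <- c("gene_id", "tissue", "expressed")
  if (!all(need %in% names(df)))
    stop("expression table needs columns: ",
         paste(need, collapse = ", "))
  if (!"regulation" %in% names(df)) df$regulation <- NA_character_
  if (!"contrast" %in% names(df)) df$contrast <- NA_character_
  df$expressed <- as.logical(df$expressed)
  key <- paste(df$gene_id, df$tissue, df$contrast, sep = "\r")
  if (anyDuplicated(key))
    stop("duplicate (gene_id, tissue, contrast) rows in the ",
         "expression table")
  df
}

#' Join PSG verdicts with an expression table
#'
#' Left join on the PSG set: every exclusive PSG appears; genes with no
#' expression rows are flagged `unobserved`.  Gene identifiers must
#' already share a namespace; a synonym map (data.frame or TSV with
#' columns `old_id`, `new_id`) can be supplied to translate the
#' expression table's ids first.
#'
#' @param verdicts a `ScanReport` from [runScan()], or a data.frame
#'   with columns `groupId` and `isPsgExclusive`.
#' @param expression expression data.frame (see
#'   [readExpressionTable()]).
#' @param synonyms optional id map applied to `expression$gene_id`.
#' @return data.frame of expression rows restricted to PSGs, plus one
#'   `unobserved = TRUE` row per PSG absent from the table.
#' @export
joinPSGExpression <- function(verdicts, expression, synonyms = NULL) {
  if (inherits(verdicts, "ScanReport")) verdicts <- verdicts$verdicts
  expression <- .validateExpressionTable(expression)
  if (!is.null(synonyms)) {
    if (is.character(synonyms)) synonyms <- read.delim(synonyms,
                                                       stringsAsFactors = FALSE)
    hit <- match(expression$gene_id, synonyms$old_id)
    expression$gene_id[!is.na(hit)] <-
      synonyms$new_id[hit[!is.na(hit)]]
  }
  psgs <- verdicts$groupId[verdicts$isPsgExclusive]
  joined <- expression[expression$gene_id %in% psgs, , drop = FALSE]
  joined$unobserved <- rep(FALSE, nrow(joined))
  missing <- setdiff(psgs, joined$gene_id)
  if (length(missing))
    joined <- rbind(joined, data.frame(
      gene_id = missing, tissue = NA_character_, expressed = FALSE,
      regulation = NA_character_, contrast = NA_character_,
      unobserved = TRUE, stringsAsFactors = FALSE))
  rownames(joined) <- NULL
  attr(joined, "psgs") <- psgs
  joined
}

#' Per-tissue presence and exclusivity counts
#'
#' A PSG is *expressed in* tissue T when any of its rows for T has
#' `expressed = TRUE`; it is *exclusive to* T when it is expressed in T
#' and in no other tissue present in the table (exclusivity is defined
#' relative to the supplied tissues).  The count of PSGs expressed in
#' at least one organ of `innovationOrgans` is reported when that list
#' is given.
#'
#' @param joined output of [joinPSGExpression()].
#' @param innovationOrgans optional character vector of organ names.
#' @return list with `perTissue` (data.frame `tissue`, `expressed`,
#'   `exclusive`), `nPsgs`, `nExpressedAnywhere`, `nUnobserved` and
#'   (optionally) `nExpressedInInnovationOrgans`.
#' @export
countByTissue <- function(joined, innovationOrgans = NULL) {
  psgs <- attr(joined, "psgs")
  if (is.null(psgs)) psgs <- unique(joined$gene_id)
  obs <- joined[!joined$unobserved & joined$expressed &
                  is.na(joined$contrast), , drop = FALSE]
  tissues <- sort(unique(joined$tissue[!is.na(joined$tissue)]))
  exprIn <- lapply(tissues, function(ts)
    unique(obs$gene_id[obs$tissue == ts]))
  names(exprIn) <- tissues
  nTissuesPerGene <- table(unlist(lapply(exprIn, unique)))
  perTissue <- data.frame(
    tissue = tissues,
    expressed = vapply(exprIn, length, 0L),
    exclusive = vapply(tissues, function(ts) {
      g <- exprIn[[ts]]
      sum(nTissuesPerGene[g] == 1L)
    }, 0L),
    row.names = NULL, stringsAsFactors = FALSE)
  out <- list(perTissue = perTissue,
              nPsgs = length(psgs),
              nExpressedAnywhere = length(unique(obs$gene_id)),
              nUnobserved = sum(joined$unobserved))
  if (!is.null(innovationOrgans))
    out$nExpressedInInnovationOrgans <- length(unique(
      obs$gene_id[obs$tissue %in% innovationOrgans]))
  out
}

#' Regulation overlap of PSGs across contrasts
#'
#' Counts PSGs by regulation status within one contrast, or — when two
#' contrast labels are given — the genes with the same status in both
#' (e.g. "up-regulated in both aposymbiotic and infected flies").
#'
#' @param joined output of [joinPSGExpression()].
#' @param contrast one or two contrast labels present in the table.
#' @return data.frame `regulation`, `count` (and the genes as an
#'   attribute `genes`).
#' @export
regulationOverlap <- function(joined, contrast) {
  have <- unique(joined$contrast[!is.na(joined$contrast)])
  if (!all(contrast %in% have))
    stop("unknown contrast(s): ",
         paste(setdiff(contrast, have), collapse = ", "))
  statuses <- c("up", "down", "unchanged")
  byStatus <- lapply(statuses, function(st) {
    sets <- lapply(contrast, function(ct)
      unique(joined$gene_id[!is.na(joined$contrast) &
                              joined$contrast == ct &
                              !is.na(joined$regulation) &
                              joined$regulation == st]))
    Reduce(intersect, sets)
  })
  names(byStatus) <- statuses
  out <- data.frame(regulation = statuses,
                    count = vapply(byStatus, length, 0L),
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "genes") <- byStatus
  out
}
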