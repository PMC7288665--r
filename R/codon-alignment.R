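# CodonAlignment construction, validation and file readers.

.splitCodons <- function(seq) {
  seq <- toupper(gsub("\\s", "", seq))
  if (nchar(seq) %% 3 != 0)
    stop("sequence length must be a multiple of 3")
  substring(seq, seq(1, nchar(seq), 3), seq(3, nchar(seq), 3))
}

#' Construct a codon alignment
#'
#' Validates frame, alignment width, taxon-name uniqueness and the
#' absence of in-frame stop codons.  Codons made entirely of `-` are
#' gaps; codons containing any character outside `ACGT` (ambiguity codes,
#' partial gaps) are kept verbatim in the sequence matrix but treated as
#' fully missing data in the likelihood.
#'
#' @param sequences named character vector of aligned nucleotide strings
#'   (equal lengths, multiple of 3).
#' @param groupId orthologous-group identifier.
#' @param lineageTags optional named character vector taxon -> role.
#' @return a [CodonAlignment-class].
#' @examples
#' aln <- codonAlignment(c(a = "ATGTTT", b = "ATGTTC"), groupId = "g1")
#' @export
codonAlignment <- function(sequences, groupId = "group",
                           lineageTags = character()) {
  if (is.null(names(sequences)) || any(names(sequences) == ""))
    stop("sequences must be named by taxon")
  lens <- nchar(gsub("\\s", "", sequences))
  if (length(unique(lens)) != 1L)
    stop("all sequences must have the same aligned length")
  codons <- senseCodons()
  rows <- lapply(sequences, .splitCodons)
  seqs <- do.call(rbind, rows)
  rownames(seqs) <- names(sequences)
  states <- matrix(match(seqs, codons), nrow(seqs), ncol(seqs))
  isStop <- is.na(states) & seqs %in% c("TAA", "TAG", "TGA")
  if (any(isStop)) {
    w <- which(isStop, arr.ind = TRUE)[1, ]
    stop("in-frame stop codon in taxon '", names(sequences)[w[1]],
         "' at codon site ", w[2])
  }
  clean <- grepl("^[ACGT]{3}$|^---$", seqs)
  if (!all(clean)) {
    # non-ACGT, non-gap codons: legal input, missing data for the model
    states[!clean] <- NA_integer_
  }
  new("CodonAlignment", taxa = names(sequences), seqs = seqs,
      states = states, groupId = as.character(groupId),
      lineageTags = lineageTags)
}

#' Read a codon alignment from FASTA or PHYLIP
#'
#' FASTA is parsed with \pkg{Biostrings}; PHYLIP is read in relaxed
#' sequential form (header line `ntax nchar`, then whitespace-separated
#' name and sequence, wrapping permitted).
#'
#' @param file path.
#' @param format `"fasta"` (default, autodetected by extension) or
#'   `"phylip"`.
#' @param groupId group identifier; defaults to the file base name.
#' @param lineageTags optional named character vector taxon -> role.
#' @return a [CodonAlignment-class].
#' @export
readCodonAlignment <- function(file, format = c("auto", "fasta", "phylip"),
                               groupId = NULL,
                               lineageTags = character()) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.(phy|phylip)$", file, ignore.case = TRUE))
      "phylip" else "fasta"
  }
  if (is.null(groupId))
    groupId <- sub("\\.[^.]*$", "", basename(file))
  if (format == "fasta") {
    ss <- Biostrings::readBStringSet(file)
    sequences <- setNames(as.character(ss), names(ss))
  } else {
    sequences <- .readRelaxedPhylip(file)
  }
  codonAlignment(sequences, groupId = groupId, lineageTags = lineageTags)
}

.readRelaxedPhylip <- function(file) {
  lines <- readLines(file)
  lines <- lines[nzchar(trimws(lines))]
  hdr <- as.integer(strsplit(trimws(lines[1]), "\\s+")[[1]])
  ntax <- hdr[1]; nsite <- hdr[2]
  seqs <- character(0)
  for (ln in lines[-1]) {
    parts <- strsplit(trimws(ln), "\\s+")[[1]]
    incomplete <- which(nchar(seqs) < nsite)
    if (length(incomplete) == 0L && length(seqs) < ntax) {
      seqs[parts[1]] <- paste(parts[-1], collapse = "")
    } else if (length(incomplete)) {
      seqs[incomplete[1]] <- paste0(seqs[incomplete[1]],
                                    paste(parts, collapse = ""))
    } else stop("unexpected trailing line in PHYLIP file")
  }
  if (length(seqs) != ntax)
    stop("PHYLIP header declares ", ntax, " taxa, found ", length(seqs))
  if (any(nchar(seqs) != nsite))
    stop("PHYLIP sequences do not match declared length ", nsite)
  seqs
}

#' Write a codon alignment to aligned FASTA
#' @param alignment a [CodonAlignment-class].
#' @param file output path.
#' @return `file`, invisibly.
#' @export
writeCodonAlignment <- function(alignment, file) {
  seqs <- apply(alignment@seqs, 1, paste, collapse = "")
  writeLines(paste0(">", alignment@taxa, "\n", seqs), file)
  invisible(file)
}

#' Taxa of a codon alignment
#' @param x a [CodonAlignment-class].
#' @return character vector of taxon names.
#' @export
alignmentTaxa <- function(x) x@taxa

#' Number of codon sites
#' @param x a [CodonAlignment-class].
#' @return integer count of codon columns.
#' @export
nCodonSites <- function(x) ncol(x@seqs)

#' Ungapped nucleotide lengths per sequence
#'
#' Counts non-gap characters (anything but `-`) in each aligned sequence;
#' this is the length used by the short-sequence quality filter.
#'
#' @param x a [CodonAlignment-class].
#' @return named integer vector.
#' @export
ungappedLengths <- function(x) {
  seqs <- apply(x@seqs, 1, paste, collapse = "")
  setNames(nchar(gsub("-", "", seqs)), x@taxa)
}

#' Subset a codon alignment by taxa
#' @param x a [CodonAlignment-class].
#' @param taxa taxon names to keep.
#' @return a [CodonAlignment-class] with the selected rows.
#' @export
subsetTaxa <- function(x, taxa) {
  keep <- match(taxa, x@taxa)
  if (anyNA(keep)) stop("unknown taxa: ",
                        paste(taxa[is.na(keep)], collapse = ", "))
  new("CodonAlignment", taxa = x@taxa[keep],
      seqs = x@seqs[keep, , drop = FALSE],
      states = x@states[keep, , drop = FALSE],
      groupId = x@groupId,
      lineageTags = x@lineageTags[names(x@lineageTags) %in% x@taxa[keep]])
}

setMethod("show", "CodonAlignment", function(object) {
  cat("CodonAlignment '", object@groupId, "': ",
      length(object@taxa), " taxa x ", ncol(object@seqs),
      " codon sites\n", sep = "")
  if (length(object@lineageTags))
    cat("  roles: ", paste(names(object@lineageTags),
                           object@lineageTags, sep = "=",
                           collapse = ", "), "\n", sep = "")
})
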