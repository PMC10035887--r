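#' @importFrom Biostrings pairwiseAlignment alignedPattern alignedSubject
#' @importFrom utils data
NULL

.blosum62 <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      e <- new.env()
      utils::data("BLOSUM62", package = "Biostrings", envir = e)
      cache <<- e$BLOSUM62
    }
    cache
  }
})

.checkAminoSeq <- function(s, what = "sequence") {
  bad <- regmatches(s, regexpr(paste0("[^", paste(.AA_ALPHABET, collapse = ""),
                                      "]"), s))
  if (length(bad) && nchar(bad))
    stop(what, " contains non-amino-acid character '", bad, "'")
  invisible(TRUE)
}

#' Global pairwise alignment similarity and gap percentages
#'
#' Needleman-Wunsch global alignment of two ungapped protein sequences
#' under BLOSUM62 with affine gap penalties (opening 10, extension 0.5,
#' the EMBOSS Needle defaults). Similarity counts aligned pairs that are
#' identical or biochemically conservative (positive BLOSUM62 score);
#' both percentages use the full alignment length, including gap columns,
#' as denominator.
#'
#' @param seqA,seqB ungapped amino-acid strings
#' @param gapOpening,gapExtension affine gap penalties
#' @return named numeric vector \code{c(similarity=, gaps=)}, both in
#'   [0, 100]
#' @examples
#' globalAlignScore("ACDEFGHIKL", "ACDEFGHIKV")  # similarity 100 (L~V +1)
#' @export
globalAlignScore <- function(seqA, seqB, gapOpening = 10,
                             gapExtension = 0.5) {
  if (!nzchar(seqA) || !nzchar(seqB)) stop("sequences must be non-empty")
  .checkAminoSeq(seqA, "seqA"); .checkAminoSeq(seqB, "seqB")
  blo <- .blosum62()
  pa <- Biostrings::pairwiseAlignment(seqA, seqB, type = "global",
                                      substitutionMatrix = blo,
                                      gapOpening = gapOpening,
                                      gapExtension = gapExtension)
  a <- strsplit(as.character(Biostrings::alignedPattern(pa)), "")[[1]]
  b <- strsplit(as.character(Biostrings::alignedSubject(pa)), "")[[1]]
  len <- length(a)
  gap <- a == "-" | b == "-"
  pairScores <- blo[cbind(a[!gap], b[!gap])]
  similar <- sum(pairScores > 0)
  c(similarity = 100 * similar / len, gaps = 100 * sum(gap) / len)
}

#' Check domain match-state alignment consistency per species
#'
#' The annotation transfer assumes that within every domain, each primate
#' residue is aligned to the human match state occupying its column. A
#' species fails the check for an orthogroup when, within any human
#' domain span, it either has the whole span deleted (all gaps) or has an
#' internal gap (a gap at a match-state column with residues on both
#' sides inside the same span) indicating shifted homology. Gaps outside
#' domain spans, and gaps at span edges, are tolerated.
#'
#' @param orthogroup an \linkS4class{Orthogroup}
#' @param matches domain-match table (see
#'   \code{\link{transferAnnotations}}); only rows for this gene are used
#' @return named logical vector, \code{TRUE} = pass, one entry per species
#' @export
matchstateCheck <- function(orthogroup, matches) {
  stopifnot(is(orthogroup, "Orthogroup"))
  aln <- msa(orthogroup)
  chars <- lapply(as.character(aln), function(s) strsplit(s, "")[[1]])
  hchars <- chars[[orthogroup@humanSpecies]]
  hPosToCol <- which(hchars != "-")
  m <- matches[matches$gene == orthogroup@gene, , drop = FALSE]
  ok <- setNames(rep(TRUE, length(aln)), names(aln))
  if (!nrow(m)) return(ok)
  spans <- split(m$human_position, m$domain_id)
  for (sp in names(aln)) {
    if (sp == orthogroup@humanSpecies) next
    cc <- chars[[sp]]
    for (posns in spans) {
      cols <- hPosToCol[sort(posns)]
      cols <- cols[!is.na(cols)]
      if (!length(cols)) next
      isGap <- cc[cols] == "-"
      if (all(isGap)) { ok[sp] <- FALSE; break }
      if (any(isGap)) {
        res <- which(!isGap)
        internal <- isGap & seq_along(cols) > min(res) &
          seq_along(cols) < max(res)
        if (any(internal)) { ok[sp] <- FALSE; break }
      }
    }
  }
  ok
}

#' Quality-control report for one orthogroup
#'
#' Each non-human species is globally aligned to the ungapped human
#' sequence; species are retained when pairwise similarity is at least
#' \code{minSimilarity} percent, gaps are at most \code{maxGaps} percent,
#' and the domain match-state check passes. The human sequence always
#' passes (self-comparison). The orthogroup as a whole is retained when
#' at least \code{minSize} sequences survive.
#'
#' @param orthogroup an \linkS4class{Orthogroup}
#' @param matches domain-match table
#' @param minSimilarity,maxGaps,minSize filtering thresholds (defaults
#'   80, 10 and 10)
#' @return data.frame with one row per species (\code{species},
#'   \code{similarity}, \code{gaps}, \code{matchstate_ok},
#'   \code{retained}, \code{reason}) carrying attributes
#'   \code{orthogroup_retained} and \code{orthogroup_id}
#' @export
qcOrthogroup <- function(orthogroup, matches,
                         minSimilarity = 80, maxGaps = 10, minSize = 10) {
  stopifnot(is(orthogroup, "Orthogroup"))
  aln <- msa(orthogroup)
  human <- orthogroup@humanSpecies
  hun <- gsub("-", "", as.character(aln[[human]]))
  msOk <- matchstateCheck(orthogroup, matches)
  out <- data.frame(species = names(aln),
                    similarity = NA_real_, gaps = NA_real_,
                    matchstate_ok = msOk[names(aln)],
                    retained = NA, reason = "",
                    stringsAsFactors = FALSE)
  for (i in seq_len(nrow(out))) {
    sp <- out$species[i]
    if (sp == human) {
      out$similarity[i] <- 100; out$gaps[i] <- 0
      out$matchstate_ok[i] <- TRUE
      out$retained[i] <- TRUE
      next
    }
    sc <- globalAlignScore(gsub("-", "", as.character(aln[[sp]])), hun)
    out$similarity[i] <- sc[["similarity"]]
    out$gaps[i] <- sc[["gaps"]]
    reasons <- character()
    if (sc[["similarity"]] < minSimilarity) reasons <- c(reasons, "low_similarity")
    if (sc[["gaps"]] > maxGaps) reasons <- c(reasons, "excess_gaps")
    if (!out$matchstate_ok[i]) reasons <- c(reasons, "matchstate_shift")
    out$retained[i] <- length(reasons) == 0L
    out$reason[i] <- paste(reasons, collapse = ";")
  }
  attr(out, "orthogroup_id") <- orthogroupId(orthogroup)
  attr(out, "orthogroup_retained") <- sum(out$retained) >= minSize
  out
}

#' Apply a QC report to an orthogroup
#'
#' Drops failing species and returns the reduced orthogroup when at least
#' \code{minSize} sequences (always including human) remain; otherwise
#' the orthogroup is rejected.
#'
#' @param orthogroup an \linkS4class{Orthogroup}
#' @param qc report from \code{\link{qcOrthogroup}}
#' @param minSize minimum surviving orthogroup size (default 10)
#' @return list with \code{retained} (logical), \code{orthogroup} (the
#'   filtered \linkS4class{Orthogroup}, or NULL on rejection) and
#'   \code{reasons} (per-dropped-species reason codes)
#' @export
filterOrthogroup <- function(orthogroup, qc, minSize = 10) {
  stopifnot(is(orthogroup, "Orthogroup"))
  human <- orthogroup@humanSpecies
  stopifnot(qc$retained[qc$species == human])
  keep <- qc$species[qc$retained]
  dropped <- setNames(qc$reason[!qc$retained], qc$species[!qc$retained])
  if (length(keep) < minSize)
    return(list(retained = FALSE, orthogroup = NULL,
                reasons = c(dropped, orthogroup = "too_few_sequences")))
  og <- orthogroup
  og@alignment <- msa(orthogroup)[keep]
  list(retained = TRUE, orthogroup = og, reasons = dropped)
}
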