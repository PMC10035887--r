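#' Scan ligand-binding columns for lineage-specific fixed residues
#'
#' Examines every ligand-binding column of an orthogroup for residues
#' that distinguish a focal clade from the rest of the retained species.
#' In \code{strict} mode all focal taxa must share one residue X, all
#' non-focal taxa must share a single different residue Y. In
#' \code{relaxed} mode the non-focal species may vary freely as long as
#' the fixed focal residue X appears in none of them. Columns with a gap
#' in any retained species are skipped: a residue cannot be called fixed
#' across species that lack it.
#'
#' @param orthogroup a (QC-filtered) \linkS4class{Orthogroup}
#' @param annotation its \linkS4class{SiteAnnotationTable}
#' @param focalTaxa character vector of focal species (e.g. the
#'   \code{"great_apes"} clade set, or just \code{"Homo_sapiens"})
#' @param mode \code{"strict"} or \code{"relaxed"}
#' @param cladeName label used in the output's \code{mode} column
#'   (e.g. \code{"human"}, \code{"ape"})
#' @return data.frame of candidate calls: \code{gene}, \code{column},
#'   \code{human_position}, \code{ligand_types}, \code{focal_residue},
#'   \code{background_residues} (comma-joined), \code{mode}; zero rows
#'   when the focal taxa are not all retained (with a message)
#' @export
scanLineageSpecific <- function(orthogroup, annotation, focalTaxa,
                                mode = c("strict", "relaxed"),
                                cladeName = if (identical(focalTaxa,
                                                          "Homo_sapiens"))
                                  "human" else "clade") {
  mode <- match.arg(mode)
  stopifnot(is(orthogroup, "Orthogroup"),
            is(annotation, "SiteAnnotationTable"))
  empty <- data.frame(gene = character(), column = integer(),
                      human_position = integer(), ligand_types = character(),
                      focal_residue = character(),
                      background_residues = character(),
                      mode = character(), stringsAsFactors = FALSE)
  sp <- speciesNames(orthogroup)
  if (!all(focalTaxa %in% sp)) {
    message("orthogroup ", orthogroupId(orthogroup),
            " skipped: focal taxa not all retained")
    return(empty)
  }
  charMat <- do.call(rbind, strsplit(as.character(msa(orthogroup)), ""))
  rownames(charMat) <- sp
  atab <- siteTable(annotation)
  cand <- atab[atab$class == "ligand_binding", , drop = FALSE]
  rows <- list()
  bg <- setdiff(sp, focalTaxa)
  for (i in seq_len(nrow(cand))) {
    j <- cand$column[i]
    col <- charMat[, j]
    if (any(col == "-")) next
    fr <- unique(col[focalTaxa])
    if (length(fr) != 1L) next
    br <- unique(col[bg])
    okStrict <- length(br) == 1L && br != fr
    okRelaxed <- !(fr %in% br)
    if (if (mode == "strict") okStrict else okRelaxed)
      rows[[length(rows) + 1L]] <- data.frame(
        gene = humanGene(orthogroup), column = j,
        human_position = cand$human_position[i],
        ligand_types = cand$ligand_types[i],
        focal_residue = fr,
        background_residues = paste(sort(br), collapse = ","),
        mode = paste(cladeName, mode, sep = "_"),
        stringsAsFactors = FALSE)
  }
  if (!length(rows)) return(empty)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Filter candidate fixed sites against human population variation
#'
#' A candidate passes when every population variant overlapping its
#' (gene, human position) has allele frequency at most \code{mafCutoff}
#' and is not disease-flagged; candidates with no overlapping variant
#' pass. Matching is on position only: a site with any common variant is
#' not fixed in the human population regardless of which allele varies.
#'
#' @param candidates data.frame from \code{\link{scanLineageSpecific}}
#' @param variants population-variant table (\code{gene},
#'   \code{position}, \code{allele_frequency}, \code{disease_flag})
#' @param mafCutoff allele-frequency cutoff, inclusive (default 0.01)
#' @return \code{candidates} with added columns \code{population_pass}
#'   and \code{reason} (\code{""}, \code{"common_variant"} or
#'   \code{"disease_variant"})
#' @export
applyPopulationFilter <- function(candidates, variants, mafCutoff = 0.01) {
  if (!nrow(candidates)) {
    candidates$population_pass <- logical(0)
    candidates$reason <- character(0)
    return(candidates)
  }
  pass <- logical(nrow(candidates))
  reason <- character(nrow(candidates))
  for (i in seq_len(nrow(candidates))) {
    v <- variants[variants$gene == candidates$gene[i] &
                    variants$position == candidates$human_position[i], ,
                  drop = FALSE]
    r <- character()
    if (nrow(v)) {
      if (any(v$allele_frequency > mafCutoff)) r <- c(r, "common_variant")
      if (any(v$disease_flag)) r <- c(r, "disease_variant")
    }
    pass[i] <- length(r) == 0L
    reason[i] <- paste(r, collapse = ";")
  }
  candidates$population_pass <- pass
  candidates$reason <- reason
  candidates
}
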