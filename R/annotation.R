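#' Classify a domain position from its binding profile
#'
#' A domain match state is called \code{binding} for a given ligand type
#' when its binding frequency (the fraction of co-complex structures in
#' which the position contacts the ligand) is at least 0.10 and the
#' domain-ligand cross-validation precision reaches 0.50 (0.75 for ions,
#' where coordination distances inflate false positives). Positions with
#' zero frequency are \code{non_binding}; everything in between is
#' \code{excluded} from analysis.
#'
#' @param f binding frequency in [0,1] (vectorised)
#' @param p cross-validation precision in [0,1] (recycled against `f`)
#' @param ligandType one of \code{"DNA"}, \code{"RNA"},
#'   \code{"small_molecule"}, \code{"ion"}, \code{"peptide"} (recycled)
#' @param frequencyCutoff binding-frequency threshold (default 0.10)
#' @param precisionCutoff precision threshold for non-ion ligands
#'   (default 0.50)
#' @param ionPrecisionCutoff precision threshold for ions (default 0.75)
#' @return character vector in \code{{"binding","non_binding","excluded"}}
#' @examples
#' classifyDomainPosition(0.15, 0.6, "DNA")   # binding
#' classifyDomainPosition(0.15, 0.6, "ion")   # excluded
#' classifyDomainPosition(0, 0.9, "peptide")  # non_binding
#' @export
classifyDomainPosition <- function(f, p, ligandType,
                                   frequencyCutoff = 0.10,
                                   precisionCutoff = 0.50,
                                   ionPrecisionCutoff = 0.75) {
  if (any(f < 0 | f > 1, na.rm = TRUE) || any(p < 0 | p > 1, na.rm = TRUE))
    stop("binding frequency and precision must lie in [0, 1]")
  if (!all(ligandType %in% .LIGAND_TYPES))
    stop("unknown ligand type: ",
         paste(setdiff(ligandType, .LIGAND_TYPES), collapse = ", "))
  n <- max(length(f), length(p), length(ligandType))
  f <- rep_len(f, n); p <- rep_len(p, n)
  ligandType <- rep_len(ligandType, n)
  pcut <- ifelse(ligandType == "ion", ionPrecisionCutoff, precisionCutoff)
  out <- rep("excluded", n)
  out[f == 0] <- "non_binding"
  out[f >= frequencyCutoff & p >= pcut] <- "binding"
  out
}

#' Transfer domain-level binding labels onto human sequence positions
#'
#' Every human position covered by at least one domain match receives the
#' per-ligand classification of its match state(s); positions covered by
#' no match are \code{other_outside_domain}. When overlapping matches
#' disagree, precedence is \code{ligand_binding} > \code{excluded} >
#' \code{non_binding}: a position observed in contact with any ligand in
#' any structure counts as a binding site. Ligand types of multi-ligand
#' binding positions are unioned.
#'
#' @param gene human gene identifier (used to subset `matches`)
#' @param seqLength ungapped human sequence length
#' @param matches data.frame with columns \code{gene}, \code{domain_id},
#'   \code{match_state}, \code{human_position} (1-based)
#' @param profiles data.frame with columns \code{domain_id},
#'   \code{ligand_type}, \code{match_state}, \code{binding_frequency},
#'   \code{cv_precision}
#' @param ... threshold overrides passed to
#'   \code{\link{classifyDomainPosition}}
#' @return data.frame with one row per human position: \code{position},
#'   \code{class} (\code{ligand_binding}, \code{other_within_domain},
#'   \code{other_outside_domain} or \code{excluded}), \code{ligand_types}
#'   (comma-joined, empty unless binding)
#' @export
transferAnnotations <- function(gene, seqLength, matches, profiles, ...) {
  m <- matches[matches$gene == gene, , drop = FALSE]
  if (nrow(m) && (any(m$human_position < 1) ||
                  any(m$human_position > seqLength)))
    stop("match positions outside sequence for gene ", gene)

  class <- rep("other_outside_domain", seqLength)
  lig <- vector("list", seqLength)
  rank <- c(other_outside_domain = 0, non_binding = 1,
            excluded = 2, binding = 3)

  if (nrow(m)) {
    for (dom in unique(m$domain_id)) {
      md <- m[m$domain_id == dom, , drop = FALSE]
      pf <- profiles[profiles$domain_id == dom, , drop = FALSE]
      if (!nrow(pf))
        stop("no binding profile for domain ", dom)
      missing <- setdiff(md$match_state, pf$match_state)
      if (length(missing))
        stop("domain ", dom, ": match state(s) ",
             paste(missing, collapse = ", "), " absent from profile")
      for (lt in unique(pf$ligand_type)) {
        pl <- pf[pf$ligand_type == lt, , drop = FALSE]
        idx <- match(md$match_state, pl$match_state)
        hit <- !is.na(idx)
        if (!any(hit)) next
        lab <- classifyDomainPosition(pl$binding_frequency[idx[hit]],
                                      pl$cv_precision[idx[hit]], lt, ...)
        pos <- md$human_position[hit]
        for (k in seq_along(pos)) {
          i <- pos[k]
          if (rank[lab[k]] > rank[class[i]]) class[i] <- lab[k]
          else if (lab[k] == "binding" && class[i] == "binding") {
            # equal-rank binding from another ligand: union below
          }
          if (lab[k] == "binding")
            lig[[i]] <- union(lig[[i]], lt)
        }
      }
    }
  }
  class[class == "binding"] <- "ligand_binding"
  class[class == "non_binding"] <- "other_within_domain"
  ligTypes <- vapply(lig, function(x)
    paste(sort(x), collapse = ","), character(1))
  ligTypes[class != "ligand_binding"] <- ""
  data.frame(position = seq_len(seqLength), class = class,
             ligand_types = ligTypes, stringsAsFactors = FALSE)
}

#' Project per-position labels onto alignment columns
#'
#' Column \code{i} of the human-anchored MSA inherits the label of the
#' human residue occupying it; columns where the human sequence has a gap
#' are \code{unannotated}.
#'
#' @param orthogroup an \linkS4class{Orthogroup}
#' @param humanLabels data.frame from \code{\link{transferAnnotations}}
#'   covering the ungapped human sequence
#' @return a \linkS4class{SiteAnnotationTable}
#' @export
projectToColumns <- function(orthogroup, humanLabels) {
  stopifnot(is(orthogroup, "Orthogroup"))
  hseq <- as.character(msa(orthogroup)[[orthogroup@humanSpecies]])
  hchars <- strsplit(hseq, "")[[1]]
  resCols <- which(hchars != "-")
  if (length(resCols) != nrow(humanLabels))
    stop("label vector length (", nrow(humanLabels),
         ") does not match ungapped human length (", length(resCols), ")")
  n <- length(hchars)
  tab <- data.frame(column = seq_len(n),
                    human_position = NA_integer_,
                    class = "unannotated",
                    ligand_types = "",
                    stringsAsFactors = FALSE)
  tab$human_position[resCols] <- seq_along(resCols)
  tab$class[resCols] <- humanLabels$class
  tab$ligand_types[resCols] <- humanLabels$ligand_types
  new("SiteAnnotationTable", gene = orthogroup@gene, table = tab)
}

#' Annotate an orthogroup end to end
#'
#' Convenience wrapper: transfers domain labels to the human sequence and
#' projects them onto alignment columns.
#'
#' @inheritParams transferAnnotations
#' @param orthogroup an \linkS4class{Orthogroup}
#' @return a \linkS4class{SiteAnnotationTable}
#' @export
annotateOrthogroup <- function(orthogroup, matches, profiles, ...) {
  hseq <- as.character(msa(orthogroup)[[orthogroup@humanSpecies]])
  L <- nchar(gsub("-", "", hseq))
  labels <- transferAnnotations(orthogroup@gene, L, matches, profiles, ...)
  projectToColumns(orthogroup, labels)
}
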