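#' @import methods
#' @importFrom Biostrings AAStringSet readAAStringSet writeXStringSet width
NULL

setOldClass("phylo")

#' PrimatePhylogeny: a fixed species tree with named clade sets
#'
#' Wraps an \code{ape} \code{phylo} object (rooted, with branch lengths in
#' expected amino-acid substitutions per site) together with named clade
#' sets such as \code{"human"} and \code{"great_apes"} used by the
#' lineage-specific site scans.
#'
#' @slot tree a rooted \code{phylo} object with branch lengths
#' @slot cladeSets named list of character vectors, each a subset of the
#'   tip labels
#' @exportClass PrimatePhylogeny
setClass("PrimatePhylogeny",
         slots = c(tree = "phylo", cladeSets = "list"))

setValidity("PrimatePhylogeny", function(object) {
  tr <- object@tree
  msg <- character()
  if (anyDuplicated(tr$tip.label))
    msg <- c(msg, "duplicate tip labels in tree")
  if (is.null(tr$edge.length))
    msg <- c(msg, "tree has no branch lengths")
  else if (any(tr$edge.length <= 0))
    msg <- c(msg, "all branch lengths must be > 0")
  bad <- vapply(object@cladeSets,
                function(s) !all(s %in% tr$tip.label), logical(1))
  if (any(bad))
    msg <- c(msg, paste0("clade set(s) not a subset of tip labels: ",
                         paste(names(object@cladeSets)[bad], collapse = ", ")))
  if (length(msg)) msg else TRUE
})

#' SubstitutionModel: empirical amino-acid replacement model
#'
#' A time-reversible 20-state rate matrix \eqn{Q} built from published
#' exchangeabilities and stationary frequencies \eqn{\pi}, normalised to one
#' expected substitution per unit branch length at stationarity
#' (\eqn{-\sum_i \pi_i Q_{ii} = 1}). The eigendecomposition of the
#' symmetrised matrix is cached so transition matrices
#' \eqn{P(t) = e^{Qt}} are cheap to evaluate for many rate multipliers.
#'
#' @slot name model name ("JTT", "WAG", "LG" or "custom")
#' @slot Q 20x20 rate matrix, rows summing to zero
#' @slot frequencies stationary frequencies, summing to one
#' @slot eigenSystem list with components \code{values}, \code{vectors},
#'   \code{inverse} such that \code{Q = vectors \%*\% diag(values) \%*\% inverse}
#' @exportClass SubstitutionModel
setClass("SubstitutionModel",
         slots = c(name = "character", Q = "matrix",
                   frequencies = "numeric", eigenSystem = "list"))

setValidity("SubstitutionModel", function(object) {
  msg <- character()
  Q <- object@Q; p <- object@frequencies
  if (!all(dim(Q) == c(20L, 20L))) msg <- c(msg, "Q must be 20x20")
  if (length(p) != 20L || abs(sum(p) - 1) > 1e-8)
    msg <- c(msg, "frequencies must be length 20 and sum to 1")
  if (max(abs(rowSums(Q))) > 1e-8) msg <- c(msg, "rows of Q must sum to 0")
  db <- p * Q           # detailed balance: pi_i Q_ij symmetric
  if (max(abs(db - t(db))) > 1e-8)
    msg <- c(msg, "Q violates detailed balance")
  if (length(msg)) msg else TRUE
})

#' Orthogroup: aligned one-to-one orthologous protein sequences
#'
#' An aligned orthogroup keyed by species, anchored on a human sequence.
#' Sequences are uppercase amino acids with \code{-} for gaps, all of equal
#' width.
#'
#' @slot id orthogroup identifier
#' @slot gene human gene identifier
#' @slot alignment \code{AAStringSet} named by species, equal widths
#' @slot humanSpecies name of the human sequence within the alignment
#' @exportClass Orthogroup
setClass("Orthogroup",
         slots = c(id = "character", gene = "character",
                   alignment = "AAStringSet", humanSpecies = "character"))

setValidity("Orthogroup", function(object) {
  aln <- object@alignment
  msg <- character()
  if (length(aln) == 0L) return("empty alignment")
  if (is.null(names(aln)) || anyDuplicated(names(aln)))
    msg <- c(msg, "alignment must have unique species names")
  if (length(unique(Biostrings::width(aln))) != 1L)
    msg <- c(msg, "aligned sequences must all have equal length")
  if (!object@humanSpecies %in% names(aln))
    msg <- c(msg, paste0("human sequence '", object@humanSpecies,
                         "' missing from alignment"))
  if (length(msg)) msg else TRUE
})

#' SiteAnnotationTable: per-column site classes for one orthogroup
#'
#' One row per alignment column of the human-anchored MSA. Columns where
#' the human sequence has a residue are partitioned into
#' \code{ligand_binding}, \code{other_within_domain},
#' \code{other_outside_domain} and \code{excluded}; human-gap columns are
#' \code{unannotated}. Ligand-binding columns carry a non-empty
#' comma-joined set of ligand types.
#'
#' @slot gene human gene identifier
#' @slot table data.frame with columns \code{column},
#'   \code{human_position} (NA at human-gap columns), \code{class},
#'   \code{ligand_types}
#' @exportClass SiteAnnotationTable
setClass("SiteAnnotationTable",
         slots = c(gene = "character", table = "data.frame"))

.SITE_CLASSES <- c("ligand_binding", "other_within_domain",
                   "other_outside_domain", "excluded", "unannotated")

setValidity("SiteAnnotationTable", function(object) {
  tb <- object@table
  need <- c("column", "human_position", "class", "ligand_types")
  if (!all(need %in% names(tb)))
    return(paste("annotation table must have columns:",
                 paste(need, collapse = ", ")))
  if (!all(tb$class %in% .SITE_CLASSES))
    return("unknown site class")
  if (any(tb$class == "unannotated" & !is.na(tb$human_position)))
    return("unannotated rows must have NA human_position")
  lb <- tb$class == "ligand_binding"
  if (any(lb & (is.na(tb$ligand_types) | tb$ligand_types == "")))
    return("ligand_binding rows must carry at least one ligand type")
  TRUE
})

#' SiteMetrics: per-column conservation and rate estimates
#'
#' One row per alignment column with Shannon entropy (nats), the
#' maximum-likelihood evolutionary rate multiplier on the fixed phylogeny,
#' its per-orthogroup mean-one normalisation, and the variable/conserved
#' classification.
#'
#' @slot orthogroupId orthogroup identifier
#' @slot table data.frame with columns \code{column},
#'   \code{human_position}, \code{entropy}, \code{ml_rate},
#'   \code{normalized_rate}, \code{variable}, \code{n_effective} and,
#'   when annotations were supplied, \code{class} and \code{ligand_types}
#' @exportClass SiteMetrics
setClass("SiteMetrics",
         slots = c(orthogroupId = "character", table = "data.frame"))

setValidity("SiteMetrics", function(object) {
  tb <- object@table
  need <- c("column", "entropy", "ml_rate", "normalized_rate",
            "variable", "n_effective")
  if (!all(need %in% names(tb)))
    return(paste("metrics table must have columns:",
                 paste(need, collapse = ", ")))
  H <- tb$entropy[!is.na(tb$entropy)]
  if (length(H) && (min(H) < -1e-12 || max(H) > log(20) + 1e-12))
    return("entropy out of [0, ln 20]")
  r <- tb$ml_rate[!is.na(tb$ml_rate)]
  if (length(r) && min(r) < 0) return("ml_rate must be >= 0")
  TRUE
})

# ---- constructors ---------------------------------------------------------

#' Construct an Orthogroup
#'
#' @param sequences named character vector or \code{AAStringSet} of aligned
#'   sequences (equal lengths, \code{-} for gaps), one per species
#' @param id orthogroup identifier
#' @param gene human gene identifier (defaults to \code{id})
#' @param humanSpecies name of the human entry (default
#'   \code{"Homo_sapiens"})
#' @return an \linkS4class{Orthogroup}
#' @export
Orthogroup <- function(sequences, id, gene = id,
                       humanSpecies = "Homo_sapiens") {
  if (!is(sequences, "AAStringSet"))
    sequences <- Biostrings::AAStringSet(sequences)
  new("Orthogroup", id = as.character(id), gene = as.character(gene),
      alignment = sequences, humanSpecies = humanSpecies)
}

# ---- accessors ------------------------------------------------------------

#' @describeIn Orthogroup alignment as an \code{AAStringSet}
#' @param x object
#' @export
msa <- function(x) x@alignment

#' Species present in an orthogroup alignment
#' @param x an Orthogroup
#' @export
speciesNames <- function(x) names(x@alignment)

#' Orthogroup identifier
#' @param x an Orthogroup
#' @export
orthogroupId <- function(x) x@id

#' Human gene identifier of an orthogroup
#' @param x an Orthogroup
#' @export
humanGene <- function(x) x@gene

#' The underlying ape phylo object
#' @param x a PrimatePhylogeny
#' @export
treePhylo <- function(x) x@tree

#' Taxon labels of a phylogeny
#' @param x a PrimatePhylogeny
#' @export
taxonLabels <- function(x) x@tree$tip.label

#' Retrieve a named clade set
#' @param x a PrimatePhylogeny
#' @param name clade set name, e.g. \code{"great_apes"}
#' @export
cladeSet <- function(x, name) {
  if (!name %in% names(x@cladeSets))
    stop("unknown clade set: ", name)
  x@cladeSets[[name]]
}

#' Extract the annotation or metrics table
#' @param x a SiteAnnotationTable or SiteMetrics object
#' @export
siteTable <- function(x) x@table

#' @export
#' @describeIn SiteMetrics coerce to data.frame (adds an
#'   \code{orthogroup} column)
#' @param x a SiteMetrics object
#' @param ... unused
asMetricsFrame <- function(x, ...) {
  cbind(orthogroup = x@orthogroupId, x@table,
        stringsAsFactors = FALSE)
}

# ---- show methods ---------------------------------------------------------

setMethod("show", "PrimatePhylogeny", function(object) {
  cat("PrimatePhylogeny with", length(object@tree$tip.label), "taxa\n")
  cat("  total tree length:",
      format(sum(object@tree$edge.length), digits = 4), "subst/site\n")
  cat("  clade sets:", paste(names(object@cladeSets), collapse = ", "), "\n")
})

setMethod("show", "SubstitutionModel", function(object) {
  cat("SubstitutionModel:", object@name, "\n")
  cat("  20x20 reversible rate matrix, mean rate 1 at stationarity\n")
})

setMethod("show", "Orthogroup", function(object) {
  cat("Orthogroup", object@id, "(gene", object@gene, ")\n")
  cat(" ", length(object@alignment), "species, alignment width",
      Biostrings::width(object@alignment)[1], "\n")
})

setMethod("show", "SiteAnnotationTable", function(object) {
  cat("SiteAnnotationTable for gene", object@gene, "\n")
  print(table(factor(object@table$class, levels = .SITE_CLASSES)))
})

setMethod("show", "SiteMetrics", function(object) {
  tb <- object@table
  cat("SiteMetrics for orthogroup", object@orthogroupId, ":",
      nrow(tb), "columns\n")
  cat("  conserved:", sum(!tb$variable, na.rm = TRUE),
      " variable:", sum(tb$variable, na.rm = TRUE), "\n")
})
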