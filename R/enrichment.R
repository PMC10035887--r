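#' Genes with population-rare variable ligand-binding sites
#'
#' Returns the genes that contain at least one variable ligand-binding
#' column whose human position carries no common population variant
#' (allele frequency above \code{mafCutoff}). The exclusion is per site:
#' a gene stays in the set if any one of its variable binding sites is
#' population-rare, even when another carries a common variant.
#'
#' @param metrics pooled per-column metrics data.frame (with
#'   \code{gene} or \code{orthogroup}, \code{class}, \code{variable},
#'   \code{human_position} columns)
#' @param variants population-variant table
#' @param mafCutoff common-variant threshold (default 0.01, exclusive:
#'   frequency must exceed it to disqualify a site)
#' @return character vector of gene identifiers
#' @export
variableInterfaceGenes <- function(metrics, variants, mafCutoff = 0.01) {
  geneCol <- if ("gene" %in% names(metrics)) "gene" else "orthogroup"
  m <- metrics[!is.na(metrics$variable) & metrics$variable &
                 metrics$class == "ligand_binding" &
                 !is.na(metrics$human_position), , drop = FALSE]
  if (!nrow(m)) return(character())
  common <- variants[variants$allele_frequency > mafCutoff, , drop = FALSE]
  key <- paste(m[[geneCol]], m$human_position)
  commonKey <- paste(common$gene, common$position)
  ok <- !(key %in% commonKey)
  sort(unique(m[[geneCol]][ok]))
}

#' Per-gene fold enrichment of variable binding sites
#'
#' For each gene, the fraction of its ligand-binding sites that are
#' variable divided by the fraction of its other (non-binding) sites
#' within domains that are variable. A gene qualifies for the
#' variable-interface set when the fold enrichment is at least
#' \code{foldCutoff} and it carries at least \code{minVariable} variable
#' binding sites. When no in-domain background site is variable but
#' binding sites are, the fold is \code{Inf} (which qualifies, given
#' enough variable binding sites); genes without both binding and
#' in-domain background sites are marked not evaluable.
#'
#' @param metrics pooled per-column metrics data.frame
#' @param foldCutoff minimum fold enrichment (default 2)
#' @param minVariable minimum number of variable binding sites
#'   (default 2, the "multiple variable sites" rule)
#' @return data.frame with one row per gene: counts, \code{fold},
#'   \code{evaluable}, \code{qualifies}
#' @export
foldEnrichment <- function(metrics, foldCutoff = 2, minVariable = 2) {
  geneCol <- if ("gene" %in% names(metrics)) "gene" else "orthogroup"
  m <- metrics[!is.na(metrics$variable), , drop = FALSE]
  genes <- sort(unique(m[[geneCol]]))
  out <- data.frame(gene = genes, n_binding = 0L, n_binding_variable = 0L,
                    n_other_domain = 0L, n_other_domain_variable = 0L,
                    fold = NA_real_, evaluable = FALSE, qualifies = FALSE,
                    stringsAsFactors = FALSE)
  for (i in seq_along(genes)) {
    g <- m[m[[geneCol]] == genes[i], , drop = FALSE]
    b <- g$class == "ligand_binding"
    o <- g$class == "other_within_domain"
    out$n_binding[i] <- sum(b)
    out$n_binding_variable[i] <- sum(g$variable[b])
    out$n_other_domain[i] <- sum(o)
    out$n_other_domain_variable[i] <- sum(g$variable[o])
  }
  ev <- out$n_binding > 0 & out$n_other_domain > 0
  out$evaluable <- ev
  fb <- out$n_binding_variable / out$n_binding
  fo <- out$n_other_domain_variable / out$n_other_domain
  out$fold[ev] <- ifelse(fo[ev] > 0, fb[ev] / fo[ev],
                         ifelse(fb[ev] > 0, Inf, NA))
  out$qualifies <- ev & !is.na(out$fold) & out$fold >= foldCutoff &
    out$n_binding_variable >= minVariable
  out
}

#' GO term over-representation by the hypergeometric test
#'
#' One-sided hypergeometric upper-tail test of each term's study-set
#' count against its background count, with Benjamini-Hochberg control
#' of the false discovery rate across all tested terms. Terms with no
#' study hits are skipped. Annotation tables are assumed
#' ancestor-propagated.
#'
#' @param study character vector of study genes (must be a subset of
#'   \code{background})
#' @param background character vector of background genes
#' @param annotations data.frame with columns \code{gene},
#'   \code{term_id}
#' @param fdrCutoff significance threshold recorded in the
#'   \code{significant} column (default 0.05)
#' @return data.frame sorted by p: \code{term_id}, \code{study_k},
#'   \code{study_n}, \code{bg_k}, \code{bg_n}, \code{p}, \code{fdr},
#'   \code{significant}
#' @export
goOverrepresentation <- function(study, background, annotations,
                                 fdrCutoff = 0.05) {
  if (!all(study %in% background))
    stop("study set must be a subset of the background")
  ann <- annotations[annotations$gene %in% background, , drop = FALSE]
  N <- length(unique(background))
  n <- length(unique(study))
  terms <- unique(ann$term_id)
  rows <- list()
  for (tm in terms) {
    hit <- unique(ann$gene[ann$term_id == tm])
    K <- length(hit)
    k <- length(intersect(hit, study))
    if (k == 0L) next
    p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    rows[[length(rows) + 1L]] <- data.frame(
      term_id = tm, study_k = k, study_n = n, bg_k = K, bg_n = N,
      p = p, stringsAsFactors = FALSE)
  }
  if (!length(rows))
    return(data.frame(term_id = character(), study_k = integer(),
                      study_n = integer(), bg_k = integer(),
                      bg_n = integer(), p = numeric(), fdr = numeric(),
                      significant = logical()))
  out <- do.call(rbind, rows)
  out$fdr <- stats::p.adjust(out$p, method = "BH")
  out$significant <- out$fdr < fdrCutoff
  out <- out[order(out$p), ]
  rownames(out) <- NULL
  out
}
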