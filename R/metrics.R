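#' @importFrom stats optimize setNames
NULL

# ---- internal pruning machinery -------------------------------------------
#
# The per-site likelihood is computed by Felsenstein's pruning algorithm.
# For a reversible model with eigendecomposition Q = V L V^-1, the message
# passed up an edge of length t at rate multiplier r is
#   M = V (exp(L t r) * (V^-1 x))
# where x is the child's partial-likelihood vector. Columns of x are
# independent, so a whole vector of candidate rates is evaluated in one
# pass with 20 x K matrices; this is what makes grid-based ML rate
# optimisation affordable in pure R.

.treeStructure <- function(phy) {
  phy <- ape::reorder.phylo(phy, "postorder")
  list(edge = phy$edge, lengths = phy$edge.length,
       nTip = length(phy$tip.label), tipLabels = phy$tip.label,
       root = length(phy$tip.label) + 1L,
       nNode = phy$Nnode)
}

# states: integer vector indexed like struct$tipLabels (1..20, NA = missing)
# rvec:   vector of rate multipliers (> 0)
.pruningLoglik <- function(struct, states, model, rvec) {
  es <- model@eigenSystem
  V <- es$vectors; Vinv <- es$inverse; lam <- es$values
  K <- length(rvec)
  nTip <- struct$nTip
  part <- vector("list", nTip + struct$nNode)
  edge <- struct$edge; len <- struct$lengths
  onesW <- rowSums(Vinv)
  for (e in seq_len(nrow(edge))) {
    parent <- edge[e, 1L]; child <- edge[e, 2L]
    Emat <- exp(lam %o% (len[e] * rvec))         # 20 x K
    if (child <= nTip) {
      s <- states[child]
      W <- if (is.na(s)) onesW else Vinv[, s]    # V^-1 e_s, recycled over K
      M <- V %*% (Emat * W)
    } else {
      M <- V %*% (Emat * (Vinv %*% part[[child]]))
    }
    part[[parent]] <- if (is.null(part[[parent]])) M else part[[parent]] * M
  }
  lik <- colSums(part[[struct$root]] * model@frequencies)
  log(pmax(lik, 1e-320))
}

.statesFromColumn <- function(column) {
  s <- match(toupper(column), .AA_ALPHABET)
  names(s) <- names(column)
  s
}

# ---- exported operations --------------------------------------------------

#' Shannon entropy of an alignment column
#'
#' \eqn{H = -\sum_a q_a \ln q_a} over the amino-acid frequencies among the
#' non-gap residues of the column, in natural-log units (so H lies in
#' [0, ln 20]). Gaps are simply excluded from the frequencies; a column
#' with no residues returns \code{NA}.
#'
#' @param column character vector of single residues (\code{-} for gaps)
#' @return entropy in nats, or \code{NA} for an all-gap column
#' @examples
#' columnEntropy(rep("A", 18))                   # 0
#' columnEntropy(c(rep("A", 9), rep("V", 9)))    # log(2)
#' @export
columnEntropy <- function(column) {
  res <- column[column != "-" & !is.na(column)]
  if (!length(res)) return(NA_real_)
  q <- table(res) / length(res)
  -sum(q * log(q))
}

#' Conserved/variable classification of a column
#'
#' A column is \code{conserved} when exactly one distinct non-gap residue
#' occurs among the retained species, \code{variable} otherwise; gaps are
#' ignored. All-gap columns return \code{NA}.
#'
#' @param column character vector of single residues
#' @return \code{"conserved"}, \code{"variable"} or \code{NA}
#' @export
classifyVariability <- function(column) {
  res <- column[column != "-" & !is.na(column)]
  if (!length(res)) return(NA_character_)
  if (length(unique(res)) == 1L) "conserved" else "variable"
}

#' Per-site log-likelihood on the fixed phylogeny
#'
#' Felsenstein pruning over the tree restricted to the species with a
#' residue at this column, with transition matrices
#' \eqn{P(t) = \exp(Q r t)} and the root weighted by the stationary
#' frequencies. Gap species are removed by pruning the tree, which for a
#' reversible model is equivalent to treating them as missing data.
#'
#' @param column named character vector of residues, names = species
#'   (subset of the tree's tip labels); \code{-} marks gaps
#' @param phylogeny a \linkS4class{PrimatePhylogeny}
#' @param model a \linkS4class{SubstitutionModel}
#' @param r rate multiplier(s), all > 0; vectorised
#' @return numeric vector of log-likelihoods, one per element of \code{r}
#' @export
siteLogLikelihood <- function(column, phylogeny, model, r) {
  stopifnot(is(phylogeny, "PrimatePhylogeny"),
            is(model, "SubstitutionModel"))
  if (any(r <= 0)) stop("rate multiplier r must be > 0")
  keep <- names(column)[column != "-" & !is.na(column)]
  if (!length(keep)) stop("column has no non-gap residues")
  missing <- setdiff(keep, taxonLabels(phylogeny))
  if (length(missing))
    stop("species not in tree: ", paste(missing, collapse = ", "))
  if (length(keep) == 1L) {
    a <- match(toupper(column[[keep]]), .AA_ALPHABET)
    return(rep(log(model@frequencies[[a]]), length(r)))
  }
  phy <- ape::keep.tip(phylogeny@tree, keep)
  struct <- .treeStructure(phy)
  states <- .statesFromColumn(column[struct$tipLabels])
  .pruningLoglik(struct, states, model, r)
}

.RATE_LOWER <- 1e-6
.RATE_UPPER <- 20

# core optimiser shared by estimateSiteRate and computeSiteMetrics;
# assumes struct/states are already restricted to non-gap species
.optimizeRate <- function(struct, states, model,
                          lower = .RATE_LOWER, upper = .RATE_UPPER,
                          gridSize = 17L, tol = 1e-6) {
  grid <- exp(seq(log(lower), log(upper), length.out = gridSize))
  ll <- .pruningLoglik(struct, states, model, grid)
  i <- which.max(ll)
  bracket <- c(grid[max(1L, i - 1L)], grid[min(gridSize, i + 1L)])
  opt <- tryCatch(
    stats::optimize(function(r) .pruningLoglik(struct, states, model, r),
                    interval = bracket, maximum = TRUE, tol = tol),
    error = function(e) NULL)
  if (is.null(opt)) {
    warning("rate optimiser failed to converge; returning best grid point")
    return(grid[i])
  }
  if (opt$objective >= ll[i]) opt$maximum else grid[i]
}

#' Maximum-likelihood per-site evolutionary rate
#'
#' Maximises the pruning likelihood over the rate multiplier
#' \eqn{r \in [10^{-6}, 20]} by a 17-point log-spaced grid search followed
#' by bounded scalar refinement (tolerance 1e-6) inside the bracketing
#' grid interval. Columns with fewer than two distinct non-gap residues
#' return the lower bound by convention (their likelihood is maximised as
#' \eqn{r \to 0}).
#'
#' @inheritParams siteLogLikelihood
#' @param lower,upper rate bounds
#' @return the ML rate multiplier (scalar)
#' @export
estimateSiteRate <- function(column, phylogeny, model,
                             lower = .RATE_LOWER, upper = .RATE_UPPER) {
  keep <- names(column)[column != "-" & !is.na(column)]
  res <- unique(toupper(column[keep]))
  if (length(keep) < 2L || length(res) < 2L) return(lower)
  phy <- ape::keep.tip(phylogeny@tree, keep)
  struct <- .treeStructure(phy)
  states <- .statesFromColumn(column[struct$tipLabels])
  .optimizeRate(struct, states, model, lower = lower, upper = upper)
}

#' Normalise per-orthogroup rates to mean one
#'
#' Divides a vector of per-column rates by its mean (over scored, i.e.
#' non-missing, columns) so that the per-orthogroup mean is exactly one.
#' An all-invariant orthogroup (every rate at the optimiser's lower
#' bound) normalises to all ones, with a warning.
#'
#' @param rates numeric vector of ML rates (NA allowed)
#' @return vector of the same length with mean one over non-NA entries
#' @export
normalizeRates <- function(rates) {
  scored <- !is.na(rates)
  if (!any(scored)) return(rates)
  if (all(rates[scored] <= .RATE_LOWER))
    warning("all columns invariant; normalised rates set to 1")
  rates / mean(rates[scored])
}

#' Per-column conservation metrics for an orthogroup
#'
#' Computes, for every alignment column: Shannon entropy, the
#' conserved/variable classification, the effective number of non-gap
#' residues, the ML evolutionary rate on the fixed phylogeny and its
#' per-orthogroup mean-one normalisation. Pruned-tree structures and
#' per-column-pattern rate estimates are cached, so repeated columns
#' (notably invariant ones) cost almost nothing.
#'
#' @param orthogroup an \linkS4class{Orthogroup}; all species must be
#'   tips of \code{phylogeny}
#' @param phylogeny a \linkS4class{PrimatePhylogeny}
#' @param model a \linkS4class{SubstitutionModel}
#' @param annotation optional \linkS4class{SiteAnnotationTable}; when
#'   given, \code{class} and \code{ligand_types} are joined onto the
#'   result by column index
#' @return a \linkS4class{SiteMetrics}
#' @export
computeSiteMetrics <- function(orthogroup, phylogeny, model,
                               annotation = NULL) {
  stopifnot(is(orthogroup, "Orthogroup"),
            is(phylogeny, "PrimatePhylogeny"),
            is(model, "SubstitutionModel"))
  aln <- msa(orthogroup)
  sp <- names(aln)
  missing <- setdiff(sp, taxonLabels(phylogeny))
  if (length(missing))
    stop("species not in tree: ", paste(missing, collapse = ", "))
  charMat <- do.call(rbind, strsplit(as.character(aln), ""))
  rownames(charMat) <- sp
  stateMat <- matrix(match(charMat, .AA_ALPHABET), nrow = nrow(charMat),
                     dimnames = dimnames(charMat))
  nCol <- ncol(charMat)

  structCache <- new.env(parent = emptyenv())
  rateCache <- new.env(parent = emptyenv())

  entropy <- numeric(nCol); variable <- logical(nCol)
  nEff <- integer(nCol); rate <- numeric(nCol)
  hchars <- charMat[orthogroup@humanSpecies, ]
  humanPos <- rep(NA_integer_, nCol)
  humanPos[hchars != "-"] <- seq_len(sum(hchars != "-"))

  for (j in seq_len(nCol)) {
    idx <- stateMat[, j]
    present <- which(!is.na(idx))
    nEff[j] <- length(present)
    if (!length(present)) {
      entropy[j] <- NA_real_; variable[j] <- NA; rate[j] <- NA_real_
      next
    }
    counts <- tabulate(idx[present], nbins = 20L)
    q <- counts[counts > 0] / length(present)
    entropy[j] <- -sum(q * log(q))
    variable[j] <- sum(counts > 0) > 1L
    if (!variable[j] || length(present) < 2L) {
      rate[j] <- .RATE_LOWER
      next
    }
    key <- paste(idx, collapse = ".")
    hit <- get0(key, envir = rateCache)
    if (!is.null(hit)) { rate[j] <- hit; next }
    skey <- paste(present, collapse = ",")
    struct <- get0(skey, envir = structCache)
    if (is.null(struct)) {
      phy <- ape::keep.tip(phylogeny@tree, sp[present])
      struct <- .treeStructure(phy)
      assign(skey, struct, envir = structCache)
    }
    states <- idx[struct$tipLabels]
    rate[j] <- .optimizeRate(struct, states, model)
    assign(key, rate[j], envir = rateCache)
  }

  tab <- data.frame(column = seq_len(nCol), human_position = humanPos,
                    entropy = entropy, ml_rate = rate,
                    normalized_rate = suppressWarnings(normalizeRates(rate)),
                    variable = variable, n_effective = nEff,
                    stringsAsFactors = FALSE)
  if (!is.null(annotation)) {
    stopifnot(is(annotation, "SiteAnnotationTable"))
    atab <- siteTable(annotation)
    tab$class <- atab$class[match(tab$column, atab$column)]
    tab$ligand_types <- atab$ligand_types[match(tab$column, atab$column)]
  }
  new("SiteMetrics", orthogroupId = orthogroupId(orthogroup), table = tab)
}
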