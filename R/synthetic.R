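#' @importFrom stats rgamma runif rbinom
NULL

#' Simulation configuration for synthetic studies
#'
#' Bundles and validates the parameters of the synthetic-data generator.
#' Defaults define the package's reference simulation conditions: binding
#' sites evolve at half the rate of background sites
#' (\code{rate_multiplier_binding = 0.5}) under unit-mean gamma rate
#' heterogeneity (\code{gamma_shape = 1}), on the packaged primate-like
#' tree.
#'
#' @param n_orthogroups number of orthogroups to simulate
#' @param seq_length_range length-2 integer range of human sequence
#'   lengths (residues)
#' @param domain_density target fraction of each sequence covered by
#'   domain matches
#' @param rate_multiplier_binding rate multiplier applied to planted
#'   binding sites (>= 0; < 1 plants slower binding sites, 1 is the
#'   null, 0 freezes binding columns entirely)
#' @param gamma_shape shape of the unit-mean gamma distribution of
#'   per-site rates (> 0)
#' @param n_planted_human_specific total number of planted human-specific
#'   binding-site substitutions across the study
#' @param variant_maf_mix list with \code{p_variant} (per-position
#'   probability of a population variant), \code{p_common} (probability a
#'   variant is common, allele frequency > 0.01) and \code{p_disease}
#'   (probability a rare variant is disease-flagged)
#' @param n_domains number of domain types in the binding-profile set
#' @param seed RNG seed; together with the other fields it fully
#'   determines every generated dataset
#' @return a validated list of class \code{"ligevol_simconfig"}
#' @export
simulationConfig <- function(n_orthogroups = 12,
                             seq_length_range = c(120L, 240L),
                             domain_density = 0.5,
                             rate_multiplier_binding = 0.5,
                             gamma_shape = 1,
                             n_planted_human_specific = 0,
                             variant_maf_mix = list(p_variant = 0.05,
                                                    p_common = 0.10,
                                                    p_disease = 0.02),
                             n_domains = 15,
                             seed = 1L) {
  stopifnot(n_orthogroups >= 1, length(seq_length_range) == 2,
            seq_length_range[1] >= 30,
            seq_length_range[2] >= seq_length_range[1],
            domain_density > 0, domain_density <= 1,
            rate_multiplier_binding >= 0, gamma_shape > 0,
            n_planted_human_specific >= 0, n_domains >= 1)
  cfg <- list(n_orthogroups = as.integer(n_orthogroups),
              seq_length_range = as.integer(seq_length_range),
              domain_density = domain_density,
              rate_multiplier_binding = rate_multiplier_binding,
              gamma_shape = gamma_shape,
              n_planted_human_specific = as.integer(n_planted_human_specific),
              variant_maf_mix = variant_maf_mix,
              n_domains = as.integer(n_domains),
              seed = as.integer(seed))
  class(cfg) <- "ligevol_simconfig"
  cfg
}

#' Generate synthetic domain binding profiles
#'
#' Emulates a domain-level binding-profile resource: each domain gets one
#' or two ligand types, a per-(domain, ligand) cross-validation precision,
#' and per-match-state binding frequencies. A known fraction
#' \code{pBinding} of match states receives a frequency of at least 0.10
#' (and so classifies as binding under the default thresholds), a
#' fraction \code{pNonBinding} gets frequency exactly 0 (non-binding),
#' and the remainder fall below the frequency cutoff (excluded).
#'
#' @param nDomains number of domains
#' @param lengthRange range of domain lengths in match states
#' @param seed RNG seed (NULL to use the current RNG stream)
#' @param pBinding,pNonBinding per-position class probabilities
#' @param precisionRange range of cross-validation precisions (the
#'   default keeps all profiles above both admission thresholds)
#' @param pSecondLigand probability a domain carries a second ligand type
#' @return data.frame with columns \code{domain_id}, \code{ligand_type},
#'   \code{match_state}, \code{binding_frequency}, \code{cv_precision};
#'   attribute \code{"binding_fraction"} records \code{pBinding}
#' @export
generateBindingProfiles <- function(nDomains, lengthRange = c(25L, 60L),
                                    seed = NULL,
                                    pBinding = 0.25, pNonBinding = 0.55,
                                    precisionRange = c(0.80, 0.99),
                                    pSecondLigand = 0.3) {
  stopifnot(nDomains >= 1, pBinding >= 0, pNonBinding >= 0,
            pBinding + pNonBinding <= 1)
  if (!is.null(seed)) set.seed(seed)
  rows <- list()
  for (d in seq_len(nDomains)) {
    id <- sprintf("DM%04d", d)
    len <- sample(lengthRange[1]:lengthRange[2], 1L)
    nLig <- 1L + stats::rbinom(1L, 1L, pSecondLigand)
    ligs <- sample(.LIGAND_TYPES, nLig)
    for (lt in ligs) {
      u <- stats::runif(len)
      f <- numeric(len)
      isB <- u < pBinding
      isN <- u >= pBinding & u < pBinding + pNonBinding
      f[isB] <- stats::runif(sum(isB), 0.10, 0.95)
      f[!isB & !isN] <- stats::runif(sum(!isB & !isN), 0.005, 0.095)
      rows[[length(rows) + 1L]] <- data.frame(
        domain_id = id, ligand_type = lt, match_state = seq_len(len),
        binding_frequency = f,
        cv_precision = stats::runif(1, precisionRange[1], precisionRange[2]),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "binding_fraction") <- pBinding
  out
}

# place non-overlapping domain matches on a sequence of length L until
# roughly `density` of it is covered; returns a domain-match data.frame
.placeDomains <- function(gene, L, profiles, density) {
  doms <- unique(profiles[, c("domain_id"), drop = FALSE])$domain_id
  domLen <- vapply(doms, function(d)
    max(profiles$match_state[profiles$domain_id == d]), numeric(1))
  target <- density * L
  covered <- 0
  cursor <- 1L + sample.int(6L, 1L)
  rows <- list()
  while (covered < target) {
    d <- sample(doms, 1L)
    len <- domLen[[d]]
    if (cursor + len - 1L > L) break
    rows[[length(rows) + 1L]] <- data.frame(
      gene = gene, domain_id = d, match_state = seq_len(len),
      human_position = cursor:(cursor + len - 1L),
      stringsAsFactors = FALSE)
    covered <- covered + len
    cursor <- cursor + len + sample.int(8L, 1L)
  }
  if (length(rows)) do.call(rbind, rows)
  else data.frame(gene = character(), domain_id = character(),
                  match_state = integer(), human_position = integer())
}

# evolve integer state sequences down the tree; returns tips x L matrix
.evolveSequences <- function(phylogeny, model, rates) {
  es <- model@eigenSystem
  V <- es$vectors; Vinv <- es$inverse; lam <- es$values
  phy <- ape::reorder.phylo(phylogeny@tree, "postorder")
  nTip <- length(phy$tip.label)
  L <- length(rates)
  states <- matrix(NA_integer_, nrow = nTip + phy$Nnode, ncol = L)
  root <- nTip + 1L
  states[root, ] <- sample.int(20L, L, replace = TRUE,
                               prob = model@frequencies)
  edgeOrder <- rev(seq_len(nrow(phy$edge)))  # parent always before child
  for (e in edgeOrder) {
    parent <- phy$edge[e, 1L]; child <- phy$edge[e, 2L]
    t <- phy$edge.length[e]
    Eall <- exp(lam %o% (t * rates))               # 20 x L
    A <- t(V[states[parent, ], , drop = FALSE])    # 20 x L
    probs <- crossprod(A * Eall, Vinv)             # L x 20
    probs[probs < 0] <- 0
    probs <- probs / rowSums(probs)
    cs <- probs
    for (k in 2:20) cs[, k] <- cs[, k - 1] + cs[, k]
    u <- stats::runif(L)
    states[child, ] <- rowSums(cs < u) + 1L
  }
  out <- states[seq_len(nTip), , drop = FALSE]
  rownames(out) <- phy$tip.label
  out
}

#' Simulate one orthogroup along the phylogeny
#'
#' Draws a human sequence length, places domain matches, classifies every
#' position from the binding profiles, assigns each site a true rate
#' (unit-mean gamma draw, multiplied by
#' \code{cfg$rate_multiplier_binding} at binding sites), draws the
#' ancestral sequence from the model's stationary frequencies and evolves
#' it down the fixed tree (indel-free, so alignment columns equal human
#' positions). Planted human-specific substitutions overwrite the human
#' residue at binding columns that evolved invariant, using an amino acid
#' absent from the column, so that the strict lineage scan's definition
#' is met exactly.
#'
#' @param phylogeny a \linkS4class{PrimatePhylogeny}
#' @param profiles binding-profile table from
#'   \code{\link{generateBindingProfiles}}
#' @param cfg a \code{\link{simulationConfig}}
#' @param gene gene/orthogroup identifier
#' @param nPlanted number of human-specific substitutions to plant in
#'   this orthogroup (error if that many eligible binding columns do not
#'   exist)
#' @param model a \linkS4class{SubstitutionModel} used for simulation
#'   (pass a different model than the one used for inference to study
#'   model mismatch)
#' @param seed optional RNG seed (NULL continues the current stream)
#' @return list with \code{orthogroup} (an \linkS4class{Orthogroup}),
#'   \code{matches} (domain-match table) and \code{groundTruth}
#'   (data.frame: \code{gene}, \code{column}, \code{true_rate},
#'   \code{class}, \code{ligand_types}, \code{planted_human_specific})
#' @export
simulateOrthogroup <- function(phylogeny, profiles, cfg,
                               gene = "G0001", nPlanted = 0,
                               model = substitutionModel("JTT"),
                               seed = NULL) {
  stopifnot(is(phylogeny, "PrimatePhylogeny"))
  if (!is.null(seed)) set.seed(seed)
  L <- sample(cfg$seq_length_range[1]:cfg$seq_length_range[2], 1L)
  matches <- .placeDomains(gene, L, profiles, cfg$domain_density)
  labels <- transferAnnotations(gene, L, matches, profiles)
  isBinding <- labels$class == "ligand_binding"

  rates <- stats::rgamma(L, shape = cfg$gamma_shape, rate = cfg$gamma_shape)
  rates[isBinding] <- rates[isBinding] * cfg$rate_multiplier_binding

  tips <- .evolveSequences(phylogeny, model, rates)
  human <- "Homo_sapiens"
  if (!human %in% rownames(tips))
    stop("tree must contain Homo_sapiens")

  planted <- rep(FALSE, L)
  if (nPlanted > 0) {
    colInvariant <- apply(tips, 2, function(s) length(unique(s)) == 1L)
    eligible <- which(isBinding & colInvariant)
    if (length(eligible) < nPlanted)
      stop("requested ", nPlanted, " planted human-specific sites but only ",
           length(eligible), " invariant binding columns are available")
    sel <- if (length(eligible) == 1L) eligible
           else sample(eligible, nPlanted)
    for (j in sel) {
      absent <- setdiff(seq_len(20L), unique(tips[, j]))
      tips[human, j] <- if (length(absent) == 1L) absent
                        else sample(absent, 1L)
    }
    planted[sel] <- TRUE
  }

  seqs <- apply(tips, 1, function(s) paste(.AA_ALPHABET[s], collapse = ""))
  og <- Orthogroup(seqs, id = gene, gene = gene, humanSpecies = human)
  gt <- data.frame(gene = gene, column = seq_len(L),
                   true_rate = rates, class = labels$class,
                   ligand_types = labels$ligand_types,
                   planted_human_specific = planted,
                   stringsAsFactors = FALSE)
  list(orthogroup = og, matches = matches, groundTruth = gt)
}

#' Generate a synthetic population-variant table
#'
#' Emulates a per-protein-position extract of human population variation:
#' each human position carries a variant with probability
#' \code{p_variant}; a variant is common (allele frequency drawn above
#' 0.01) with probability \code{p_common} and otherwise rare (frequency
#' in (0, 0.01]); a small fraction of variants are disease-flagged.
#' Positions carrying planted human-specific substitutions only ever
#' receive rare, non-disease variants, so planted sites always survive
#' the population filter.
#'
#' @param orthogroups list of \linkS4class{Orthogroup}s
#' @param groundTruth pooled ground-truth table from
#'   \code{\link{simulateOrthogroup}}
#' @param cfg a \code{\link{simulationConfig}} (its
#'   \code{variant_maf_mix} is used)
#' @param seed optional RNG seed
#' @return data.frame with columns \code{gene}, \code{position},
#'   \code{ref_aa}, \code{alt_aa}, \code{allele_frequency},
#'   \code{disease_flag}
#' @export
generatePopulationVariants <- function(orthogroups, groundTruth, cfg,
                                       seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  mix <- cfg$variant_maf_mix
  rows <- list()
  for (og in orthogroups) {
    gene <- humanGene(og)
    hseq <- gsub("-", "",
                 as.character(msa(og)[[og@humanSpecies]]))
    L <- nchar(hseq)
    refs <- strsplit(hseq, "")[[1]]
    plantedPos <- groundTruth$column[groundTruth$gene == gene &
                                       groundTruth$planted_human_specific]
    hasVar <- which(stats::runif(L) < mix$p_variant)
    for (i in hasVar) {
      isPlanted <- i %in% plantedPos
      common <- !isPlanted && stats::runif(1) < mix$p_common
      af <- if (common) stats::runif(1, 0.011, 0.5)
            else stats::runif(1, 1e-5, 0.01)
      disease <- !isPlanted && stats::runif(1) < mix$p_disease
      rows[[length(rows) + 1L]] <- data.frame(
        gene = gene, position = i, ref_aa = refs[i],
        alt_aa = sample(setdiff(.AA_ALPHABET, refs[i]), 1L),
        allele_frequency = af, disease_flag = disease,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(rows))
    return(data.frame(gene = character(), position = integer(),
                      ref_aa = character(), alt_aa = character(),
                      allele_frequency = numeric(),
                      disease_flag = logical()))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Generate a synthetic gene-to-GO annotation table
#'
#' Background genes are annotated to each term at a term-specific base
#' rate; an optional planted term is additionally annotated to all
#' \code{plantedGenes}, creating genuine over-representation for study
#' sets that contain them. Annotation tables are treated as already
#' ancestor-propagated (no ontology structure).
#'
#' @param genes character vector of gene identifiers
#' @param nTerms number of background terms
#' @param plantedTerm optional term id to enrich
#' @param plantedGenes genes annotated to the planted term (must be a
#'   subset of \code{genes})
#' @param seed optional RNG seed
#' @param baseRateRange range of per-term background annotation rates
#' @return data.frame with columns \code{gene}, \code{term_id}
#' @export
generateGoAnnotations <- function(genes, nTerms = 20, plantedTerm = NULL,
                                  plantedGenes = character(), seed = NULL,
                                  baseRateRange = c(0.03, 0.12)) {
  if (!all(plantedGenes %in% genes))
    stop("plantedGenes must be a subset of genes")
  if (!is.null(seed)) set.seed(seed)
  rows <- list()
  terms <- sprintf("GO:%07d", seq_len(nTerms))
  for (tm in terms) {
    rate <- stats::runif(1, baseRateRange[1], baseRateRange[2])
    hit <- genes[stats::runif(length(genes)) < rate]
    if (length(hit))
      rows[[length(rows) + 1L]] <- data.frame(gene = hit, term_id = tm,
                                              stringsAsFactors = FALSE)
  }
  if (!is.null(plantedTerm)) {
    rate <- stats::runif(1, baseRateRange[1], baseRateRange[2])
    hit <- union(plantedGenes, genes[stats::runif(length(genes)) < rate])
    rows[[length(rows) + 1L]] <- data.frame(gene = hit,
                                            term_id = plantedTerm,
                                            stringsAsFactors = FALSE)
  }
  if (!length(rows))
    return(data.frame(gene = character(), term_id = character()))
  out <- do.call(rbind, rows)
  out <- out[order(out$term_id, out$gene), ]
  rownames(out) <- NULL
  out
}

#' Simulate a complete synthetic study
#'
#' Generates binding profiles, orthogroups evolved along the tree with
#' known per-site rates, a population-variant table and a GO annotation
#' table (with a term planted on the genes that received human-specific
#' substitutions, when any were requested). Everything is driven by
#' \code{cfg$seed}: identical configurations produce identical studies.
#'
#' @param cfg a \code{\link{simulationConfig}}
#' @param phylogeny the species tree (default: packaged reference tree)
#' @param model substitution model used for simulation
#' @return list with \code{phylogeny}, \code{model}, \code{profiles},
#'   \code{orthogroups} (named list), \code{matches}, \code{groundTruth},
#'   \code{variants}, \code{go}, \code{plantedTerm}, \code{config}
#' @export
simulateStudy <- function(cfg = simulationConfig(),
                          phylogeny = loadReferenceTree(),
                          model = substitutionModel("JTT")) {
  set.seed(cfg$seed)
  profiles <- generateBindingProfiles(cfg$n_domains)
  nOg <- cfg$n_orthogroups
  plantAlloc <- tabulate(rep(seq_len(nOg),
                             length.out = cfg$n_planted_human_specific),
                         nbins = nOg)
  orthogroups <- list(); matches <- list(); gts <- list()
  for (g in seq_len(nOg)) {
    gene <- sprintf("G%04d", g)
    sim <- simulateOrthogroup(phylogeny, profiles, cfg, gene = gene,
                              nPlanted = plantAlloc[g], model = model)
    orthogroups[[gene]] <- sim$orthogroup
    matches[[gene]] <- sim$matches
    gts[[gene]] <- sim$groundTruth
  }
  matches <- do.call(rbind, matches); rownames(matches) <- NULL
  groundTruth <- do.call(rbind, gts); rownames(groundTruth) <- NULL
  variants <- generatePopulationVariants(orthogroups, groundTruth, cfg)
  plantedGenes <- unique(groundTruth$gene[groundTruth$planted_human_specific])
  plantedTerm <- if (length(plantedGenes)) "GO:9999999" else NULL
  go <- generateGoAnnotations(names(orthogroups), nTerms = 20,
                              plantedTerm = plantedTerm,
                              plantedGenes = plantedGenes)
  list(phylogeny = phylogeny, model = model, profiles = profiles,
       orthogroups = orthogroups, matches = matches,
       groundTruth = groundTruth, variants = variants, go = go,
       plantedTerm = plantedTerm, config = cfg)
}
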