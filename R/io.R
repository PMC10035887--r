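#' @importFrom utils read.delim write.table
NULL

.readTsv <- function(path, required = NULL) {
  df <- utils::read.delim(path, comment.char = "#", sep = "\t",
                          stringsAsFactors = FALSE)
  if (!is.null(required) && !all(required %in% names(df)))
    stop("file ", path, " lacks required column(s): ",
         paste(setdiff(required, names(df)), collapse = ", "))
  df
}

.writeTsv <- function(df, path, comment = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(comment)) writeLines(paste0("# ", comment), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a binding-profile table
#' @param path TSV with columns domain_id, ligand_type, match_state,
#'   binding_frequency, cv_precision
#' @export
readBindingProfiles <- function(path)
  .readTsv(path, c("domain_id", "ligand_type", "match_state",
                   "binding_frequency", "cv_precision"))

#' Read a domain-match table
#' @param path TSV with columns gene, domain_id, match_state,
#'   human_position
#' @export
readDomainMatches <- function(path)
  .readTsv(path, c("gene", "domain_id", "match_state", "human_position"))

#' Read a population-variant table
#' @param path TSV with columns gene, position, ref_aa, alt_aa,
#'   allele_frequency, disease_flag
#' @export
readVariants <- function(path) {
  v <- .readTsv(path, c("gene", "position", "allele_frequency",
                        "disease_flag"))
  v$disease_flag <- as.logical(v$disease_flag)
  if (any(v$allele_frequency < 0 | v$allele_frequency > 1))
    stop("allele frequencies must lie in [0, 1]")
  v
}

#' Read a gene-to-GO annotation table
#' @param path TSV with columns gene, term_id
#' @export
readGoAnnotations <- function(path) .readTsv(path, c("gene", "term_id"))

#' Read an aligned orthogroup from FASTA
#'
#' @param path aligned FASTA (\code{-} gaps), record names = species
#' @param id orthogroup identifier (default: file name without extension)
#' @param gene human gene identifier (default \code{id})
#' @param humanSpecies name of the human record
#' @return an \linkS4class{Orthogroup}
#' @export
readOrthogroup <- function(path, id = sub("\\.[^.]*$", "", basename(path)),
                           gene = id, humanSpecies = "Homo_sapiens") {
  aln <- Biostrings::readAAStringSet(path)
  names(aln) <- sub("\\s.*$", "", names(aln))
  Orthogroup(aln, id = id, gene = gene, humanSpecies = humanSpecies)
}

#' Write an orthogroup alignment to FASTA
#' @param orthogroup an \linkS4class{Orthogroup}
#' @param path output file
#' @export
writeOrthogroup <- function(orthogroup, path) {
  Biostrings::writeXStringSet(msa(orthogroup), path)
  invisible(path)
}

#' Write a complete synthetic study to disk
#'
#' Writes one aligned FASTA per orthogroup, the tree as Newick and the
#' profile/match/variant/GO/ground-truth tables as TSV into \code{dir}.
#'
#' @param study result of \code{\link{simulateStudy}}
#' @param dir output directory (created if absent)
#' @return \code{dir}, invisibly
#' @export
writeStudy <- function(study, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  msaDir <- file.path(dir, "msa")
  dir.create(msaDir, showWarnings = FALSE)
  for (og in study$orthogroups)
    writeOrthogroup(og, file.path(msaDir, paste0(orthogroupId(og),
                                                 ".fasta")))
  writePhylogeny(study$phylogeny, file.path(dir, "tree.nwk"))
  .writeTsv(study$profiles, file.path(dir, "binding_profiles.tsv"),
            "synthetic domain binding profiles")
  .writeTsv(study$matches, file.path(dir, "domain_matches.tsv"),
            "synthetic domain matches")
  .writeTsv(study$variants, file.path(dir, "variants.tsv"),
            "synthetic population variants")
  .writeTsv(study$go, file.path(dir, "go_annotations.tsv"),
            "synthetic GO annotations")
  .writeTsv(study$groundTruth, file.path(dir, "ground_truth.tsv"),
            "simulation ground truth")
  invisible(dir)
}

#' Previously reported primate site-conservation summary
#'
#' Dataset-level site counts and percent-conserved values reported for
#' ligand-binding and background sites across 18 primate species,
#' shipped as packaged reference data. Used to reconstruct
#' conserved-versus-variable contingency tables at the published scale,
#' e.g. for \code{\link{conservationFisher}}.
#'
#' @return data.frame with columns \code{class}, \code{n_sites},
#'   \code{percent_conserved} and derived \code{n_conserved}
#' @export
referenceConservationSummary <- function() {
  path <- system.file("extdata", "primate_conservation_summary.tsv",
                      package = "ligevol", mustWork = TRUE)
  df <- .readTsv(path, c("class", "n_sites", "percent_conserved"))
  df$n_conserved <- round(df$n_sites * df$percent_conserved / 100)
  df
}
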