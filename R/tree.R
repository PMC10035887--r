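#' @importFrom ape read.tree write.tree keep.tip reorder.phylo cophenetic.phylo
NULL

.GREAT_APES <- c("Homo_sapiens", "Pan_troglodytes", "Pan_paniscus",
                 "Gorilla_gorilla", "Pongo_abelii")

#' Load the packaged 18-primate reference phylogeny
#'
#' Returns the synthetic 18-taxon primate-like species tree shipped with
#' the package (six apes, eight monkeys, four prosimians; branch lengths
#' in expected amino-acid substitutions per site, total tree length about
#' 1.16). The topology and relative depths are plausible for the primate
#' clade, but the overall scale is set for per-site rate identifiability
#' in simulations rather than to literature divergence estimates; the
#' tree is a synthetic stand-in and the file is labelled accordingly.
#' Clade sets \code{"human"} and \code{"great_apes"} are pre-populated.
#'
#' @param source path to a Newick file; defaults to the packaged tree
#' @return a \linkS4class{PrimatePhylogeny}
#' @examples
#' phy <- loadReferenceTree()
#' taxonLabels(phy)
#' @export
loadReferenceTree <- function(source = NULL) {
  if (is.null(source))
    source <- system.file("extdata", "primate_tree_18taxa_synthetic.nwk",
                          package = "ligevol", mustWork = TRUE)
  readPhylogeny(source,
                cladeSets = list(human = "Homo_sapiens",
                                 great_apes = .GREAT_APES))
}

#' Read a phylogeny from a Newick file
#'
#' @param path Newick file with branch lengths
#' @param cladeSets named list of taxon subsets to attach; clade sets not
#'   fully contained in the tree are dropped with a warning
#' @return a \linkS4class{PrimatePhylogeny}
#' @export
readPhylogeny <- function(path, cladeSets = list()) {
  txt <- paste(readLines(path, warn = FALSE), collapse = "")
  .checkNewickTokens(txt)
  tr <- tryCatch(ape::read.tree(text = txt),
                 error = function(e) stop("Newick parse error in '", path,
                                          "': ", conditionMessage(e)))
  if (is.null(tr)) stop("Newick parse error: no tree found in '", path, "'")
  keep <- vapply(cladeSets, function(s) all(s %in% tr$tip.label), logical(1))
  if (length(cladeSets) && !all(keep)) {
    warning("dropping clade set(s) absent from tree: ",
            paste(names(cladeSets)[!keep], collapse = ", "))
    cladeSets <- cladeSets[keep]
  }
  new("PrimatePhylogeny", tree = tr, cladeSets = cladeSets)
}

# Cheap token-level Newick sanity check so malformed input fails with the
# offending token named, rather than deep inside the parser.
.checkNewickTokens <- function(txt) {
  depth <- 0L
  for (ch in strsplit(txt, "")[[1]]) {
    if (ch == "(") depth <- depth + 1L
    if (ch == ")") {
      depth <- depth - 1L
      if (depth < 0L) stop("Newick parse error: unmatched ')'")
    }
  }
  if (depth != 0L) stop("Newick parse error: unmatched '('")
  bad <- regmatches(txt, regexpr("[^A-Za-z0-9_.:,;()'\\[\\] \t-]", txt,
                                 perl = TRUE))
  if (length(bad) && nchar(bad))
    stop("Newick parse error: unexpected token '", bad, "'")
  invisible(TRUE)
}

#' Write a phylogeny to a Newick file
#'
#' @param x a \linkS4class{PrimatePhylogeny}
#' @param path output file
#' @export
writePhylogeny <- function(x, path) {
  stopifnot(is(x, "PrimatePhylogeny"))
  ape::write.tree(x@tree, file = path)
  invisible(path)
}

#' Construct a PrimatePhylogeny from a phylo object
#'
#' @param tree rooted \code{phylo} with branch lengths
#' @param cladeSets named list of taxon subsets
#' @export
PrimatePhylogeny <- function(tree, cladeSets = list()) {
  new("PrimatePhylogeny", tree = tree, cladeSets = cladeSets)
}

#' Leaf-to-leaf path length matrix
#'
#' Patristic distances between all pairs of tips; used to verify that
#' write/read round trips and leaf pruning preserve the metric structure
#' of the tree.
#'
#' @param x a \linkS4class{PrimatePhylogeny}
#' @export
pathLengthMatrix <- function(x) {
  d <- ape::cophenetic.phylo(x@tree)
  d[order(rownames(d)), order(colnames(d)), drop = FALSE]
}

#' Prune a phylogeny to a subset of taxa
#'
#' @param x a \linkS4class{PrimatePhylogeny}
#' @param taxa tip labels to keep (at least two)
#' @return pruned \linkS4class{PrimatePhylogeny}; clade sets are
#'   intersected with the kept taxa
#' @export
pruneTaxa <- function(x, taxa) {
  stopifnot(is(x, "PrimatePhylogeny"))
  missing <- setdiff(taxa, x@tree$tip.label)
  if (length(missing))
    stop("taxa not in tree: ", paste(missing, collapse = ", "))
  tr <- ape::keep.tip(x@tree, taxa)
  cs <- lapply(x@cladeSets, intersect, taxa)
  new("PrimatePhylogeny", tree = tr, cladeSets = cs[lengths(cs) > 0])
}
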