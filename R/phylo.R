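#' Phylogenetic correlation matrix from topology via Grafen branch lengths
#'
#' Builds the expected trait correlation matrix among species from a Newick
#' topology alone. Branch lengths are assigned following Grafen: each
#' internal node's height is its number of descendant tips minus one, all
#' heights are normalised by the root height (so the tree has depth 1, power
#' parameter rho = 1), and the correlation between two tips is the shared
#' root-to-MRCA path length. Polytomies are accepted.
#'
#' @param tree An `ape::phylo` object, a Newick string, or a path to a
#'   Newick file.
#' @param species Optional character vector of species to keep (and order
#'   by). Names are matched after normalisation (case folded, spaces and
#'   underscores interchangeable). Species absent from the tree are an
#'   error unless `allow_missing = TRUE`, in which case they are attached
#'   conceptually at the root (correlation 0 with everything, 1 with
#'   themselves).
#' @param allow_missing Attach absent species at the root instead of
#'   erroring.
#' @return A symmetric positive semi-definite matrix with unit diagonal and
#'   the (normalised) species names as dimnames.
#' @examples
#' grafen_correlation("((A,B),(C,D));") # cherries at 2/3, across at 0
#' @export
grafen_correlation <- function(tree, species = NULL, allow_missing = FALSE) {
  if (is.character(tree)) {
    tree <- if (length(tree) == 1 && file.exists(tree)) ape::read.tree(tree)
    else ape::read.tree(text = tree)
    if (is.null(tree)) stop("could not parse Newick input", call. = FALSE)
  }
  if (!inherits(tree, "phylo")) stop("'tree' must be a phylo object or Newick",
                                     call. = FALSE)
  norm <- function(x) tolower(gsub("[ _]+", "_", trimws(x)))
  tree$tip.label <- norm(tree$tip.label)

  if (ape::Ntip(tree) == 1) {
    A <- matrix(1, 1, 1, dimnames = list(tree$tip.label, tree$tip.label))
  } else {
    scaled <- ape::compute.brlen(tree, method = "Grafen", power = 1)
    A <- ape::vcv(scaled, corr = TRUE)
  }

  if (is.null(species)) return(A)
  species <- norm(species)
  absent <- setdiff(species, rownames(A))
  if (length(absent) && !allow_missing)
    stop("species not in the tree: ", paste(absent, collapse = ", "),
         call. = FALSE)
  out <- diag(length(species))
  dimnames(out) <- list(species, species)
  present <- intersect(species, rownames(A))
  out[present, present] <- A[present, present]
  out
}
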