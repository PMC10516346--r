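#' Labelled species-by-species distance matrix
#'
#' Light wrapper storing a symmetric, zero-diagonal distance matrix together
#' with its kind (`patristic`, `growth_rate` or `colony_size`) and, for
#' growth-based kinds, the pH level it was computed at.
#'
#' @param values square numeric matrix with dimnames.
#' @param kind one of "patristic", "growth_rate", "colony_size".
#' @param ph pH level the matrix refers to, or NULL for patristic.
#' @return the matrix with class `dist_matrix` and attributes `kind`, `ph`.
#' @export
dist_matrix <- function(values, kind = c("patristic", "growth_rate",
                                         "colony_size"), ph = NULL) {
  kind <- match.arg(kind)
  values <- as.matrix(values)
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stop("distance matrix must carry species labels", call. = FALSE)
  }
  if (!isTRUE(all.equal(values, t(values), tolerance = 1e-12))) {
    stop("distance matrix must be symmetric", call. = FALSE)
  }
  if (any(abs(diag(values)) > 1e-12) || any(values < 0)) {
    stop("distances must be nonnegative with zero diagonal", call. = FALSE)
  }
  structure(values, kind = kind, ph = ph, class = c("dist_matrix", "matrix"))
}

#' Read a rooted phylogeny from a newick file
#'
#' Parses a newick tree with branch lengths. Trees missing branch lengths or
#' carrying duplicate tip labels are rejected; negative branch lengths are an
#' error (zero-length branches are allowed).
#'
#' @param path newick file, or a newick string containing ";".
#' @return an `ape` phylo object.
#' @export
read_newick <- function(path) {
  tree <- if (grepl(";", path, fixed = TRUE)) {
    ape::read.tree(text = path)
  } else {
    ape::read.tree(path)
  }
  if (is.null(tree)) stop("could not parse newick input", call. = FALSE)
  if (is.null(tree$edge.length)) {
    stop("parse error: tree has no branch lengths", call. = FALSE)
  }
  if (length(tree$edge.length) < nrow(tree$edge) ||
      anyNA(tree$edge.length)) {
    bad <- which(is.na(tree$edge.length))
    stop("parse error: missing branch length on edge(s) ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  if (any(tree$edge.length < 0)) {
    stop("parse error: negative branch lengths", call. = FALSE)
  }
  if (anyDuplicated(tree$tip.label)) {
    stop("parse error: duplicate tip labels: ",
         paste(unique(tree$tip.label[duplicated(tree$tip.label)]),
               collapse = ", "), call. = FALSE)
  }
  tree
}

#' Patristic distances between tips of a phylogeny
#'
#' Entry (i, j) is the sum of branch lengths along the unique path between
#' tips i and j. Tips not requested (e.g. an outgroup) are ignored; their
#' presence never changes ingroup distances.
#'
#' @param tree an `ape` phylo object or newick string/path.
#' @param labels tip labels to include, in the desired order; defaults to all
#'   tips.
#' @return a [dist_matrix()] of kind "patristic".
#' @export
patristic_distances <- function(tree, labels = NULL) {
  if (is.character(tree)) tree <- read_newick(tree)
  if (is.null(labels)) labels <- tree$tip.label
  missing <- setdiff(labels, tree$tip.label)
  if (length(missing)) {
    stop("labels absent from tree: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  full <- ape::cophenetic.phylo(tree)
  dist_matrix(full[labels, labels, drop = FALSE], kind = "patristic")
}

#' Write a distance matrix as labelled CSV
#'
#' @param dm a [dist_matrix()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_dist_matrix <- function(dm, path) {
  df <- data.frame(species = rownames(dm), as.data.frame(unclass(dm)),
                   check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
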