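#' Read a rooted phylogeny from a Newick file
#'
#' Parses a single Newick tree (via \pkg{ape}) and validates it for use in
#' trait-evolution likelihoods: unique tip labels, non-negative branch
#' lengths. Missing branch lengths are set to 0 with a warning (common in
#' bootstrap outputs). An unrooted tree (basal multifurcation) is rooted on
#' the first child of the basal node with a zero-length stem, with a warning;
#' under the reversible models used here the likelihood does not depend on
#' this choice.
#'
#' @param path path to a file containing one Newick string ending in `;`,
#'   or a Newick string itself via `text`.
#' @param text optional Newick string (overrides `path`).
#' @return an [ape::read.tree()] `phylo` object, rooted, with `edge.length`.
#' @examples
#' tr <- read_newick(text = "((A:1,B:1):0.5,C:2);")
#' @export
read_newick <- function(path = NULL, text = NULL) {
  if (is.null(text)) {
    stopifnot(!is.null(path))
    text <- paste(readLines(path, warn = FALSE), collapse = "")
  }
  check_newick_syntax(text)
  tree <- ape::read.tree(text = text)
  if (is.null(tree)) stop("could not parse Newick string")
  validate_phylogeny(tree)
}

#' Read a multi-tree Newick file (one tree per line)
#'
#' @param path path to a file with one Newick string per line.
#' @return a list of validated `phylo` objects.
#' @export
read_newick_set <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("no trees in ", path)
  lapply(seq_along(lines), function(i) {
    tryCatch(read_newick(text = lines[[i]]),
             error = function(e) stop("tree ", i, ": ", conditionMessage(e)))
  })
}

#' Write a phylogeny (or list of phylogenies) as Newick
#'
#' @param tree a `phylo` object or list of them (one tree per output line).
#' @param path output path.
#' @export
write_newick <- function(tree, path) {
  trees <- if (inherits(tree, "phylo")) list(tree) else tree
  txt <- vapply(trees, function(tr) ape::write.tree(tr, digits = 12), "")
  writeLines(txt, path)
  invisible(path)
}

check_newick_syntax <- function(text) {
  chars <- strsplit(text, "")[[1L]]
  depth <- 0L
  for (i in seq_along(chars)) {
    if (chars[i] == "(") depth <- depth + 1L
    if (chars[i] == ")") {
      depth <- depth - 1L
      if (depth < 0L) stop("malformed Newick: unmatched ')' at position ", i)
    }
  }
  if (depth != 0L) {
    stop("malformed Newick: ", depth, " unclosed '(' at end of string")
  }
  if (!grepl(";\\s*$", text)) stop("malformed Newick: missing terminal ';'")
  invisible(TRUE)
}

validate_phylogeny <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  if (anyDuplicated(tree$tip.label)) {
    stop("duplicate tip label: ",
         paste(unique(tree$tip.label[duplicated(tree$tip.label)]),
               collapse = ", "))
  }
  if (is.null(tree$edge.length)) {
    warning("tree has no branch lengths; setting all to 0")
    tree$edge.length <- rep(0, nrow(tree$edge))
  }
  if (anyNA(tree$edge.length)) {
    warning(sum(is.na(tree$edge.length)),
            " missing branch length(s) set to 0")
    tree$edge.length[is.na(tree$edge.length)] <- 0
  }
  if (any(tree$edge.length < 0)) {
    stop("negative branch length(s): min = ", min(tree$edge.length))
  }
  if (!ape::is.rooted(tree)) {
    root_node <- ape::Ntip(tree) + 1L
    first_child <- tree$edge[tree$edge[, 1L] == root_node, 2L][1L]
    out_tips <- if (first_child <= ape::Ntip(tree)) {
      tree$tip.label[first_child]
    } else {
      ape::extract.clade(tree, first_child)$tip.label
    }
    warning("unrooted tree: rooting on the basal node's first child ",
            "with a zero-length stem")
    tree <- ape::root(tree, outgroup = out_tips, resolve.root = TRUE)
    tree$edge.length[is.na(tree$edge.length)] <- 0
  }
  tree
}

#' Reconcile the tip set of a tree with the genome set of a trait matrix
#'
#' @param tree a `phylo` object.
#' @param tm a [trait_matrix].
#' @param policy `"strict"` errors unless the tip set equals the genome set;
#'   `"intersect"` restricts both objects to the shared ids, pruning the tree
#'   (degree-2 nodes collapsed, branch lengths summed, so patristic distances
#'   among retained tips are preserved).
#' @return list with elements `tree` and `traits`.
#' @export
reconcile <- function(tree, tm, policy = c("strict", "intersect")) {
  policy <- match.arg(policy)
  stopifnot(inherits(tree, "phylo"), inherits(tm, "trait_matrix"))
  tips <- tree$tip.label
  genomes <- rownames(tm$values)
  if (policy == "strict") {
    if (!setequal(tips, genomes)) {
      stop("strict reconcile: tip set and genome set differ (",
           length(setdiff(tips, genomes)), " tree-only, ",
           length(setdiff(genomes, tips)), " table-only ids)")
    }
    return(list(tree = tree, traits = tm))
  }
  shared <- intersect(tips, genomes)
  if (!length(shared)) stop("reconcile: empty intersection of tips and genomes")
  if (length(shared) < 2L) stop("reconcile: fewer than 2 shared ids")
  message("reconcile: ", length(shared), " shared ids retained")
  pruned <- if (length(shared) < length(tips)) {
    ape::keep.tip(tree, shared)
  } else tree
  list(tree = pruned, traits = subset_traits(tm, genomes = shared))
}
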