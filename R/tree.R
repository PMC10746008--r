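# Tree construction and newick plumbing. Neighbor joining and midpoint
# rooting are delegated to ape/phangorn; demarcation consumes any rooted
# tree whose tip labels match the alignment.

#' Neighbor-joining tree from a corrected distance matrix
#'
#' Standard neighbor joining on a Jukes-Cantor-corrected distance matrix,
#' midpoint-rooted. Negative branch lengths (an NJ artifact) are clamped to
#' zero and the clamped total is reported in a message.
#'
#' @param dm a `dist_matrix` of kind `jc_corrected`.
#' @return a rooted [ape::phylo] tree.
#' @export
nj_tree <- function(dm) {
  stopifnot(inherits(dm, "dist_matrix"))
  if (dm$kind != "jc_corrected")
    stop("nj_tree expects a jc_corrected distance matrix", call. = FALSE)
  n <- length(dm$ids)
  if (n < 2L) stop("need at least two taxa", call. = FALSE)
  if (n == 2L) {
    # two taxa: return a cherry with the distance split evenly
    d <- dm$d[1, 2]
    tr <- list(edge = matrix(c(3L, 1L, 3L, 2L), ncol = 2, byrow = TRUE),
               edge.length = c(d / 2, d / 2), tip.label = dm$ids, Nnode = 1L)
    class(tr) <- "phylo"
    return(tr)
  }
  tr <- ape::nj(stats::as.dist(dm$d))
  neg <- tr$edge.length < 0
  if (any(neg)) {
    message("clamped ", sum(neg), " negative NJ branch length(s); total deficit ",
            signif(-sum(tr$edge.length[neg]), 3))
    tr$edge.length[neg] <- 0
  }
  phangorn::midpoint(tr)
}

#' Parse and write newick trees
#'
#' Thin wrappers around [ape::read.tree()] / [ape::write.tree()] that check
#' for duplicate leaf labels and read missing branch lengths as zero.
#'
#' @param text a newick string, or a file path for `read_newick_file`.
#' @return an [ape::phylo] tree (`parse_newick`) or a newick string
#'   (`write_newick`).
#' @export
parse_newick <- function(text) {
  tr <- tryCatch(ape::read.tree(text = text),
                 error = function(e) NULL, warning = function(w) NULL)
  if (is.null(tr))
    stop("malformed newick: ", substr(text, 1, 60), call. = FALSE)
  if (anyDuplicated(tr$tip.label))
    stop("duplicate leaf label(s): ",
         paste(unique(tr$tip.label[duplicated(tr$tip.label)]), collapse = ", "),
         call. = FALSE)
  if (is.null(tr$edge.length)) tr$edge.length <- rep(0, nrow(tr$edge))
  tr$edge.length[is.na(tr$edge.length)] <- 0
  tr
}

#' @rdname parse_newick
#' @param tree an [ape::phylo] tree.
#' @export
write_newick <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  ape::write.tree(tree)
}

#' Root a tree on a named outgroup
#'
#' @param tree an [ape::phylo] tree.
#' @param outgroup tip label(s) forming the outgroup.
#' @return a rooted tree.
#' @export
root_outgroup <- function(tree, outgroup) {
  missing <- setdiff(outgroup, tree$tip.label)
  if (length(missing))
    stop("outgroup taxa not in tree: ", paste(missing, collapse = ", "),
         call. = FALSE)
  ape::root(tree, outgroup = outgroup, resolve.root = TRUE)
}
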