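#' Codon alignment container
#'
#' A light wrapper around a taxa x columns character matrix holding a
#' codon-aligned nucleotide matrix for one gene. Characters are restricted to
#' `A`, `C`, `G`, `T`, `-` and `?`; `U` is mapped to `T` on construction and
#' everything is uppercased. The reading frame is described by `frame`, the
#' number of leading columns to skip before the first complete codon (0, 1 or
#' 2); after removing the frame offset the remaining length must be divisible
#' by 3.
#'
#' @param x taxa x columns character matrix of single characters, with unique
#'   rownames giving the taxon labels.
#' @param gene gene name.
#' @param frame integer offset in nucleotides before the first codon.
#' @return An object of class `codon_alignment`: the matrix with attributes
#'   `gene` and `frame`.
#' @examples
#' m <- rbind(A = c("A","T","G","C","C","C"), B = c("A","T","G","C","T","C"))
#' aln <- codon_alignment(m, gene = "cob")
#' n_codons(aln)
#' @export
codon_alignment <- function(x, gene = "gene", frame = 0L) {
  stopifnot(is.matrix(x), !is.null(rownames(x)))
  if (anyDuplicated(rownames(x)))
    stop("taxon labels must be unique", call. = FALSE)
  x[] <- toupper(x)
  x[x == "U"] <- "T"
  bad <- setdiff(unique(as.vector(x)), c("A", "C", "G", "T", "-", "?"))
  if (length(bad) > 0)
    x[x %in% bad] <- "?"
  frame <- as.integer(frame)
  if (frame < 0 || frame > 2)
    stop("frame offset must be 0, 1 or 2", call. = FALSE)
  if ((ncol(x) - frame) %% 3 != 0)
    stop("alignment length minus frame offset is not divisible by 3",
         call. = FALSE)
  structure(x, gene = gene, frame = frame, class = c("codon_alignment", "matrix"))
}

#' @export
print.codon_alignment <- function(x, ...) {
  cat(sprintf("<codon_alignment> gene %s: %d taxa x %d columns (%d codons)\n",
              attr(x, "gene"), nrow(x), ncol(x), n_codons(x)))
  invisible(x)
}

#' @rdname codon_alignment
#' @param aln a `codon_alignment`.
#' @export
n_codons <- function(aln) (ncol(aln) - attr(aln, "frame")) %/% 3L

#' Codon position of an alignment column
#'
#' Maps 1-based alignment columns to codon position 1, 2 or 3 given the
#' frame offset of the alignment. Columns inside the frame offset return `NA`.
#'
#' @param column 1-based column index (vectorised).
#' @param frame frame offset in nucleotides.
#' @return Integer vector of codon positions in `{1, 2, 3}`.
#' @export
codon_position <- function(column, frame = 0L) {
  p <- ((column - frame - 1L) %% 3L) + 1L
  p[column <= frame] <- NA_integer_
  as.integer(p)
}

#' Codon index (1-based) of an alignment column
#' @inheritParams codon_position
#' @return Integer vector of 1-based codon indices (`NA` inside the offset).
#' @export
codon_index <- function(column, frame = 0L) {
  i <- ((column - frame - 1L) %/% 3L) + 1L
  i[column <= frame] <- NA_integer_
  as.integer(i)
}

#' Read a codon-aligned FASTA file
#'
#' Reads an aligned nucleotide FASTA into a [codon_alignment()]. All sequences
#' must have equal length; characters are uppercased and `U` mapped to `T`.
#'
#' @param path path to a FASTA file.
#' @param gene gene name recorded on the alignment (defaults to the file
#'   base name).
#' @param frame frame offset in nucleotides before the first codon.
#' @return A [codon_alignment()].
#' @export
read_alignment <- function(path, gene = NULL, frame = 0L) {
  if (is.null(gene))
    gene <- sub("\\.[^.]*$", "", basename(path))
  recs <- seqinr::read.fasta(path, seqtype = "DNA", as.string = FALSE,
                             forceDNAtolower = FALSE, set.attributes = FALSE)
  if (length(recs) == 0) stop("no sequences in ", path, call. = FALSE)
  lens <- lengths(recs)
  if (length(unique(lens)) != 1L)
    stop("alignment error: sequences in ", path, " have unequal lengths (",
         paste(unique(lens), collapse = ", "), ")", call. = FALSE)
  m <- do.call(rbind, recs)
  rownames(m) <- names(recs)
  codon_alignment(m, gene = gene, frame = frame)
}

#' Write a codon alignment to FASTA
#'
#' @param aln a [codon_alignment()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_alignment <- function(aln, path) {
  seqs <- apply(aln, 1L, paste0, collapse = "")
  writeLines(paste0(">", rownames(aln), "\n", seqs), path)
  invisible(path)
}

#' Read a rooted Newick tree
#'
#' Thin wrapper over [ape::read.tree()] that validates the tree is rooted and
#' has branch lengths. Polytomies are allowed and preserved.
#'
#' @param path path to a Newick file.
#' @return An `ape::phylo` object.
#' @export
read_tree <- function(path) {
  tr <- ape::read.tree(path)
  if (is.null(tr)) stop("tree error: could not parse ", path, call. = FALSE)
  if (inherits(tr, "multiPhylo")) {
    if (length(tr) != 1L)
      stop("tree error: expected exactly one tree in ", path, call. = FALSE)
    tr <- tr[[1L]]
  }
  # a basal multifurcation is accepted as a rooted tree with a root
  # polytomy; structurally there must be exactly one node with no parent
  roots <- setdiff(unique(tr$edge[, 1L]), tr$edge[, 2L])
  if (length(roots) != 1L)
    stop("tree error: tree must have exactly one root", call. = FALSE)
  if (is.null(tr$edge.length))
    stop("tree error: tree must carry branch lengths", call. = FALSE)
  if (any(tr$edge.length < 0))
    stop("tree error: negative branch lengths", call. = FALSE)
  tr
}

#' Write a tree to Newick
#' @param tree an `ape::phylo`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_tree <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' Deterministic branch identifiers
#'
#' Names every branch of a rooted tree after its child node: tips keep their
#' labels, internal nodes are named `N<k>` where `k` numbers internal nodes in
#' the tree's postorder traversal. Used in all per-branch output tables so
#' rows can be matched back to the tree.
#'
#' @param tree an `ape::phylo`.
#' @return Character vector of branch ids, one per row of `tree$edge`,
#'   in `tree$edge` order.
#' @export
branch_ids <- function(tree) {
  labs <- node_labels(tree)
  labs[tree$edge[, 2L]]
}

#' @rdname branch_ids
#' @return `node_labels()`: character vector over all node numbers
#'   (tips then internals).
#' @export
node_labels <- function(tree) {
  n_tip <- length(tree$tip.label)
  n_node <- tree$Nnode
  labs <- c(tree$tip.label, rep(NA_character_, n_node))
  post <- postorder_nodes(tree)
  k <- 0L
  for (v in post) {
    if (v > n_tip) {
      k <- k + 1L
      labs[v] <- paste0("N", k)
    }
  }
  labs
}

# Internal node traversal orders on an ape phylo ---------------------------

# children list indexed by node number
child_list <- function(tree) {
  n <- length(tree$tip.label) + tree$Nnode
  kids <- vector("list", n)
  e <- tree$edge
  for (i in seq_len(nrow(e))) kids[[e[i, 1L]]] <- c(kids[[e[i, 1L]]], e[i, 2L])
  # deterministic child order: sort by subtree's smallest tip label
  key <- subtree_min_label(tree)
  lapply(kids, function(k) k[order(key[k])])
}

subtree_min_label <- function(tree) {
  n_tip <- length(tree$tip.label)
  n <- n_tip + tree$Nnode
  key <- rep(NA_character_, n)
  key[seq_len(n_tip)] <- tree$tip.label
  for (v in postorder_nodes(tree)) {
    if (v > n_tip) {
      e <- tree$edge[tree$edge[, 1L] == v, 2L]
      key[v] <- min(key[e])
    }
  }
  key
}

postorder_nodes <- function(tree) {
  # children before parents; every node is a child of exactly one edge
  # except the root, appended last
  e <- ape::reorder.phylo(tree, "postorder")$edge
  c(e[, 2L], root_node(tree))
}

root_node <- function(tree) {
  setdiff(unique(tree$edge[, 1L]), tree$edge[, 2L])[1L]
}

parent_vec <- function(tree) {
  n <- length(tree$tip.label) + tree$Nnode
  par <- rep(NA_integer_, n)
  par[tree$edge[, 2L]] <- tree$edge[, 1L]
  par
}

# edge index (row of tree$edge) by child node
edge_index_by_child <- function(tree) {
  n <- length(tree$tip.label) + tree$Nnode
  idx <- rep(NA_integer_, n)
  idx[tree$edge[, 2L]] <- seq_len(nrow(tree$edge))
  idx
}

# all tip numbers below each node (list)
tips_below <- function(tree) {
  n_tip <- length(tree$tip.label)
  n <- n_tip + tree$Nnode
  out <- vector("list", n)
  for (i in seq_len(n_tip)) out[[i]] <- i
  for (v in postorder_nodes(tree)) {
    if (v > n_tip) {
      kids <- tree$edge[tree$edge[, 1L] == v, 2L]
      out[[v]] <- sort(unlist(out[kids]))
    }
  }
  out
}
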