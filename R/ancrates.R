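#' Ancestral codon sequence reconstruction
#'
#' Reconstructs nucleotide states at every internal node of a fixed rooted
#' tree, column by column. Only gap-free columns enter the reconstruction;
#' columns containing `-` or `?` in any taxon are masked (`NA` at all nodes).
#' The parsimony method runs a per-nucleotide Fitch pass resolved by DELTRAN
#' (ambiguous positions carry their full most-parsimonious state set, exposed
#' through `ambiguous_sets`). The ML method performs marginal reconstruction
#' under an HKY model via \pkg{phangorn} and takes the highest-probability
#' state.
#'
#' @param tree rooted `ape::phylo` with branch lengths.
#' @param aln a [codon_alignment()].
#' @param method `"parsimony"` (default) or `"ML"`.
#' @return An object of class `ancestral_seqs`: list with `states` (node x
#'   column matrix of characters, rownames from [node_labels()]; tips hold the
#'   observed data), `masked` (logical per column), `codon_position`, `tree`,
#'   `method`, and for the parsimony method the DP `cost` array over unmasked
#'   columns plus their indices (`unmasked`).
#' @export
reconstruct_ancestral_sequences <- function(tree, aln,
                                            method = c("parsimony", "ML")) {
  method <- match.arg(method)
  miss <- setdiff(tree$tip.label, rownames(aln))
  if (length(miss) > 0)
    stop("tips absent from alignment: ", paste(miss, collapse = ", "),
         call. = FALSE)
  m <- aln[tree$tip.label, , drop = FALSE]
  frame <- attr(aln, "frame")
  masked <- apply(m, 2L, function(col) any(!col %in% c("A", "C", "G", "T")))
  masked[seq_len(frame)] <- TRUE
  unmasked <- which(!masked)
  n_tip <- length(tree$tip.label)
  n_node <- n_tip + tree$Nnode
  states <- matrix(NA_character_, n_node, ncol(m))
  rownames(states) <- node_labels(tree)
  states[seq_len(n_tip), ] <- m
  cost <- NULL
  if (length(unmasked) > 0) {
    if (method == "parsimony") {
      rec <- fitch_reconstruct(tree, m[, unmasked, drop = FALSE],
                               states = c("A", "C", "G", "T"))
      resolved <- resolve_states(tree, rec$cost, mode = "deltran",
                                 root_tie = "first")
      states[, unmasked] <- c("A", "C", "G", "T")[resolved]
      states[seq_len(n_tip), ] <- m  # tips stay observed
      cost <- rec$cost
    } else {
      if (!requireNamespace("phangorn", quietly = TRUE))
        stop("method 'ML' requires the phangorn package", call. = FALSE)
      sub <- m[, unmasked, drop = FALSE]
      pd <- phangorn::phyDat(sub, type = "DNA")
      tr <- tree
      # branch lengths are re-estimated on the substitution scale; the
      # input lengths (possibly time units) only seed the optimisation
      tr$edge.length <- rep(0.05, nrow(tr$edge))
      fit <- phangorn::pml(tr, pd, model = "HKY")
      fit <- suppressWarnings(
        phangorn::optim.pml(fit, optEdge = TRUE, optBf = TRUE, optQ = TRUE,
                            control = phangorn::pml.control(trace = 0)))
      anc <- phangorn::ancestral.pml(fit, type = "marginal")
      states[, unmasked] <- ml_states_from_ancestral(anc, tree, unmasked,
                                                     ncol(m))
      states[seq_len(n_tip), ] <- m
    }
  }
  structure(list(states = states, masked = masked,
                 codon_position = codon_position(seq_len(ncol(m)), frame),
                 unmasked = unmasked, cost = cost, tree = tree,
                 method = method, frame = frame),
            class = "ancestral_seqs")
}

#' @export
print.ancestral_seqs <- function(x, ...) {
  cat(sprintf("<ancestral_seqs> %s reconstruction, %d columns (%d masked)\n",
              x$method, length(x$masked), sum(x$masked)))
  invisible(x)
}

# expand phangorn marginal probabilities into a node x column state matrix
ml_states_from_ancestral <- function(anc, tree, unmasked, n_cols) {
  n_tip <- length(tree$tip.label)
  n_node <- n_tip + tree$Nnode
  idx <- attr(anc, "index")
  out <- matrix(NA_character_, n_node, n_cols)
  nt <- c("A", "C", "G", "T")
  for (v in seq_len(n_node)) {
    nm <- if (v <= n_tip) tree$tip.label[v] else paste0("Node", v - n_tip)
    pm <- anc[[nm]]
    if (is.null(pm)) next
    pick <- nt[max.col(pm[, 1:4, drop = FALSE], ties.method = "first")]
    out[v, unmasked] <- pick[idx]
  }
  out
}

# --- Nei-Gojobori-style counting ------------------------------------------

ng_env <- new.env(parent = emptyenv())

# per-codon synonymous site fraction at each position, and path classification
ng_tables <- function() {
  if (!is.null(ng_env$sites)) return(ng_env)
  nts <- c("A", "C", "G", "T")
  codons <- as.vector(outer(outer(nts, nts, paste0), nts, paste0))
  tab <- codon_table()
  sites <- matrix(0, length(codons), 3, dimnames = list(codons, NULL))
  for (cd in codons) {
    aa <- tab[[cd]]
    for (p in 1:3) {
      alt <- vapply(setdiff(nts, substr(cd, p, p)), function(n) {
        x <- cd
        substr(x, p, p) <- n
        x
      }, character(1))
      # mutations to stop codons count as nonsynonymous
      syn <- vapply(alt, function(x) tab[[x]] == aa && tab[[x]] != "*",
                    logical(1))
      if (aa == "*") syn[] <- FALSE
      sites[cd, p] <- mean(syn)
    }
  }
  ng_env$sites <- sites
  ng_env$aa <- tab
  ng_env
}

# syn/nonsyn difference counts between two codons, averaging over all
# orderings of the single-nucleotide steps; orderings passing through a stop
# codon are dropped when at least one stop-free ordering exists
codon_path_counts <- function(c1, c2) {
  if (c1 == c2) return(c(syn = 0, nonsyn = 0))
  tabs <- ng_tables()
  diffpos <- which(strsplit(c1, "")[[1]] != strsplit(c2, "")[[1]])
  perms <- if (length(diffpos) == 1L) list(diffpos) else
    if (length(diffpos) == 2L) list(diffpos, rev(diffpos)) else
      lapply(list(c(1,2,3), c(1,3,2), c(2,1,3), c(2,3,1), c(3,1,2), c(3,2,1)),
             function(o) diffpos[o])
  paths <- lapply(perms, function(ord) {
    cur <- c1
    sy <- 0; ns <- 0; stop_hit <- FALSE
    for (p in ord) {
      nxt <- cur
      substr(nxt, p, p) <- substr(c2, p, p)
      if (tabs$aa[[nxt]] == "*") stop_hit <- TRUE
      if (tabs$aa[[nxt]] == tabs$aa[[cur]]) sy <- sy + 1 else ns <- ns + 1
      cur <- nxt
    }
    list(syn = sy, nonsyn = ns, stop = stop_hit)
  })
  ok <- !vapply(paths, `[[`, logical(1), "stop")
  if (any(ok)) paths <- paths[ok]
  c(syn = mean(vapply(paths, `[[`, numeric(1), "syn")),
    nonsyn = mean(vapply(paths, `[[`, numeric(1), "nonsyn")))
}

#' Counting-based synonymous divergence between two codon sequences
#'
#' Nei-Gojobori-style estimation: synonymous site counts are the per-position
#' fractions of one-step changes that are synonymous (averaged between the
#' two sequences), observed differences are classified by averaging over all
#' shortest mutational paths between differing codons, and the synonymous
#' proportion is corrected for multiple hits with the Jukes-Cantor formula
#' `dS = -3/4 log(1 - 4/3 p_s)`. Codon pairs containing gaps or ambiguity are
#' skipped. The statistic is symmetric in its arguments.
#'
#' @param anc,desc codon sequences: character vectors of single nucleotides
#'   (equal length, divisible by 3) or single strings.
#' @return One-row tibble: `syn_count`, `nonsyn_count`, `S`, `N`, `ps`, `ds`,
#'   `codons_used`, and list-column `ct3_positions` (1-based nucleotide
#'   positions of ancestor-C to descendant-T changes at third codon
#'   positions).
#' @export
branch_ds <- function(anc, desc) {
  to_vec <- function(x) if (length(x) == 1L && nchar(x[1]) > 1L)
    strsplit(toupper(x), "")[[1]] else toupper(x)
  a <- to_vec(anc); d <- to_vec(desc)
  if (length(a) != length(d) || length(a) %% 3L != 0L)
    stop("sequences must be equal length and divisible by 3", call. = FALSE)
  tabs <- ng_tables()
  n_cod <- length(a) %/% 3L
  syn <- 0; nonsyn <- 0; S <- 0; used <- 0L
  ct3 <- integer()
  for (i in seq_len(n_cod)) {
    idx <- (3L * i - 2L):(3L * i)
    ca <- paste0(a[idx], collapse = "")
    cd <- paste0(d[idx], collapse = "")
    if (!grepl("^[ACGT]{3}$", ca) || !grepl("^[ACGT]{3}$", cd)) next
    used <- used + 1L
    S <- S + (sum(tabs$sites[ca, ]) + sum(tabs$sites[cd, ])) / 2
    cnt <- codon_path_counts(ca, cd)
    syn <- syn + cnt[["syn"]]
    nonsyn <- nonsyn + cnt[["nonsyn"]]
    if (substr(ca, 3, 3) == "C" && substr(cd, 3, 3) == "T")
      ct3 <- c(ct3, idx[3L])
  }
  N <- 3 * used - S
  ps <- if (S > 0) syn / S else 0
  if (ps >= 0.75)
    stop("saturation error: synonymous proportion ", signif(ps, 3),
         " >= 3/4", call. = FALSE)
  ds <- -0.75 * log(1 - 4 * ps / 3)
  tibble::tibble(syn_count = syn, nonsyn_count = nonsyn, S = S, N = N,
                 ps = ps, ds = ds, codons_used = used,
                 ct3_positions = list(ct3))
}

#' Per-branch synonymous divergence over a tree
#'
#' Applies [branch_ds()] to every branch, comparing the reconstructed
#' ancestral sequence at the parent node with the sequence at the child
#' (observed at tips). Masked columns never enter.
#'
#' @param anc an [reconstruct_ancestral_sequences()] result.
#' @return Tibble with one row per branch in `tree$edge` order: `branch_id`
#'   plus the [branch_ds()] columns.
#' @export
tree_branch_ds <- function(anc) {
  tree <- anc$tree
  ids <- branch_ids(tree)
  st <- anc$states
  st[, anc$masked] <- "-"  # masked columns skipped codon-wise
  purrr::map_dfr(seq_len(nrow(tree$edge)), function(i) {
    p <- tree$edge[i, 1L]; ch <- tree$edge[i, 2L]
    dplyr::bind_cols(tibble::tibble(branch_id = ids[i]),
                     branch_ds(st[p, ], st[ch, ]))
  })
}

#' Pairwise relative rate test at third codon positions
#'
#' Tajima-style one-degree test restricted to third codon positions: with an
#' outgroup O, count sites where A alone differs (`m_A`: A differs from both
#' B and O while B equals O) and where B alone differs (`m_B`); under rate
#' equality each configuration is equally likely, giving a two-sided exact
#' binomial test of `m_A` against `m_B` with probability 1/2.
#'
#' @param aln a [codon_alignment()] containing all three taxa.
#' @param taxon_a,taxon_b,outgroup taxon labels.
#' @return One-row tibble: `m_a`, `m_b`, `p_value`.
#' @export
relative_rate_test <- function(aln, taxon_a, taxon_b, outgroup) {
  for (tx in c(taxon_a, taxon_b, outgroup))
    if (!tx %in% rownames(aln)) stop("taxon not in alignment: ", tx,
                                     call. = FALSE)
  frame <- attr(aln, "frame")
  third <- which(codon_position(seq_len(ncol(aln)), frame) == 3L)
  A <- aln[taxon_a, third]; B <- aln[taxon_b, third]; O <- aln[outgroup, third]
  ok <- A %in% c("A","C","G","T") & B %in% c("A","C","G","T") &
    O %in% c("A","C","G","T")
  m_a <- sum(ok & A != B & A != O & B == O)
  m_b <- sum(ok & B != A & B != O & A == O)
  if (m_a + m_b == 0) {
    warning("no informative third-position sites; p = 1")
    return(tibble::tibble(m_a = m_a, m_b = m_b, p_value = 1))
  }
  p <- stats::binom.test(m_a, m_a + m_b, p = 0.5)$p.value
  tibble::tibble(m_a = m_a, m_b = m_b, p_value = p)
}

#' C-to-T changes at third codon positions, mapped per branch
#'
#' Extracts, for every branch, the third-codon-position columns whose state
#' changes from `C` in the ancestor to `T` in the descendant. Edited-site
#' columns can be excluded (they are tracked as editing losses instead), and
#' events can be restricted to columns carrying `C` in a focal ancestral
#' node. Under `mode = "resolved"` events come from the single DELTRAN
#' resolution; under `mode = "fractional"` ambiguous positions contribute the
#' expected event count under uniform random resolution of ties in the
#' parsimony dynamic programme (every realisation of which is a most
#' parsimonious reconstruction).
#'
#' @param anc a parsimony [reconstruct_ancestral_sequences()] result.
#' @param exclude_positions 1-based columns to exclude (edited sites).
#' @param focal_node optional node label; restrict to columns whose state at
#'   this node is `C`.
#' @param mode `"resolved"` (default) or `"fractional"`.
#' @return Tibble `branch_id`, `position`, `weight` (1 for resolved events).
#' @export
third_position_ct_events <- function(anc, exclude_positions = integer(),
                                     focal_node = NULL,
                                     mode = c("resolved", "fractional")) {
  mode <- match.arg(mode)
  tree <- anc$tree
  cols <- which(anc$codon_position == 3L & !anc$masked &
                  !(seq_along(anc$masked) %in% exclude_positions))
  if (!is.null(focal_node)) {
    v <- node_by_label(tree, focal_node)
    cols <- cols[anc$states[v, cols] == "C"]
  }
  ids <- branch_ids(tree)
  if (length(cols) == 0)
    return(tibble::tibble(branch_id = character(), position = integer(),
                          weight = numeric()))
  if (mode == "resolved") {
    out <- purrr::map_dfr(seq_len(nrow(tree$edge)), function(i) {
      p <- tree$edge[i, 1L]; ch <- tree$edge[i, 2L]
      hit <- cols[anc$states[p, cols] == "C" & anc$states[ch, cols] == "T"]
      tibble::tibble(branch_id = ids[i], position = hit, weight = 1)
    })
    return(out)
  }
  # fractional: propagate a state distribution down the tree; ties in the
  # preorder DP are split uniformly
  fractional_ct_events(anc, cols)
}

fractional_ct_events <- function(anc, cols) {
  tree <- anc$tree
  D <- anc$cost
  if (is.null(D))
    stop("fractional mode requires a parsimony reconstruction", call. = FALSE)
  col_in_unmasked <- match(cols, anc$unmasked)
  stopifnot(!anyNA(col_in_unmasked))
  n_states <- 4L
  nm <- length(col_in_unmasked)
  n_tip <- length(tree$tip.label)
  n_node <- n_tip + tree$Nnode
  root <- root_node(tree)
  ids <- node_labels(tree)
  C_IDX <- 2L; T_IDX <- 4L  # A C G T order
  pi_mat <- vector("list", n_node)
  droot <- matrix(D[, col_in_unmasked, root], n_states, nm)
  best <- col_mins(droot)
  elig <- droot == rep(best, each = n_states)
  pr <- t(t(elig * 1) / colSums(elig))
  pi_mat[[root]] <- pr
  par <- parent_vec(tree)
  rows <- list()
  for (v in rev(postorder_nodes(tree))) {
    if (v == root) next
    dv <- matrix(D[, col_in_unmasked, v], n_states, nm)
    pi_p <- pi_mat[[par[v]]]
    pi_v <- matrix(0, n_states, nm)
    w_ct <- numeric(nm)
    for (a in seq_len(n_states)) {
      cost <- dv + 1
      cost[a, ] <- cost[a, ] - 1
      b <- col_mins(cost)
      el <- cost == rep(b, each = n_states)
      w <- t(t(el * 1) / colSums(el))
      pi_v <- pi_v + rep(pi_p[a, ], each = n_states) * w
      if (a == C_IDX) w_ct <- pi_p[a, ] * w[T_IDX, ]
    }
    pi_mat[[v]] <- pi_v
    hit <- which(w_ct > 0)
    if (length(hit) > 0)
      rows[[length(rows) + 1L]] <- tibble::tibble(
        branch_id = ids[v], position = cols[hit], weight = w_ct[hit])
  }
  if (length(rows) == 0)
    tibble::tibble(branch_id = character(), position = integer(),
                   weight = numeric())
  else dplyr::bind_rows(rows)
}
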