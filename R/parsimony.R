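# Unit-cost Sankoff/Fitch machinery shared by the character-mapping and
# ancestral-sequence modules. All passes are vectorised across characters:
# the dynamic-programming table is an array [state, character, node].

# minimal per-subtree cost table; tip_allowed is a list (by node number 1..n_tip)
# of S x C logical matrices of permitted states (missing data = all TRUE)
sankoff_down <- function(tree, tip_allowed, n_states, n_chars) {
  n_tip <- length(tree$tip.label)
  n_node <- n_tip + tree$Nnode
  D <- array(Inf, dim = c(n_states, n_chars, n_node))
  for (i in seq_len(n_tip)) {
    d <- matrix(Inf, n_states, n_chars)
    d[tip_allowed[[i]]] <- 0
    D[, , i] <- d
  }
  kids <- child_list(tree)
  for (v in postorder_nodes(tree)) {
    if (v <= n_tip) next
    acc <- matrix(0, n_states, n_chars)
    for (k in kids[[v]]) {
      m <- matrix(D[, , k], n_states, n_chars)
      mmin <- m[1L, ]
      if (n_states > 1L)
        for (s in 2:n_states) mmin <- pmin(mmin, m[s, ])
      acc <- acc + pmin(m, rep(mmin + 1, each = n_states))
    }
    D[, , v] <- acc
  }
  D
}

col_mins <- function(m) {
  out <- m[1L, ]
  if (nrow(m) > 1L) for (s in 2:nrow(m)) out <- pmin(out, m[s, ])
  out
}

# first TRUE index per column of a logical matrix
first_true <- function(m) max.col(t(m), ties.method = "first")
last_true <- function(m) max.col(t(m), ties.method = "last")

# Resolve one preorder step: given parent state indices fp (length C) and the
# down-cost matrix at the child, pick child states achieving the DP minimum.
# mode "deltran" keeps the parent state whenever it is optimal (delays
# changes tipward); "acctran" switches away from the parent state whenever an
# optimal alternative exists (pulls changes rootward).
resolve_step <- function(down_v, fp, mode) {
  n_states <- nrow(down_v)
  n_chars <- ncol(down_v)
  cost <- down_v + 1
  cost[cbind(fp, seq_len(n_chars))] <- cost[cbind(fp, seq_len(n_chars))] - 1
  best <- col_mins(cost)
  elig <- cost == rep(best, each = n_states)
  parent_ok <- elig[cbind(fp, seq_len(n_chars))]
  if (mode == "deltran") {
    idx <- first_true(elig)
    idx[parent_ok] <- fp[parent_ok]
  } else {
    elig2 <- elig
    elig2[cbind(fp, seq_len(n_chars))] <- FALSE
    has_alt <- colSums(elig2) > 0
    idx <- fp
    idx[!parent_ok | has_alt] <- first_true(elig2)[!parent_ok | has_alt]
    idx[!parent_ok & !has_alt] <- first_true(elig)[!parent_ok & !has_alt]
  }
  idx
}

# Full preorder resolution. root_tie: which root state to take when several
# are equally parsimonious ("first" or "last" in state order).
resolve_states <- function(tree, D, mode = c("deltran", "acctran"),
                           root_tie = c("last", "first")) {
  mode <- match.arg(mode)
  root_tie <- match.arg(root_tie)
  n_states <- dim(D)[1L]
  n_chars <- dim(D)[2L]
  n_tip <- length(tree$tip.label)
  n_node <- n_tip + tree$Nnode
  Fst <- matrix(NA_integer_, n_node, n_chars)
  root <- root_node(tree)
  droot <- matrix(D[, , root], n_states, n_chars)
  best <- col_mins(droot)
  elig <- droot == rep(best, each = n_states)
  Fst[root, ] <- if (root_tie == "last") last_true(elig) else first_true(elig)
  pre <- rev(postorder_nodes(tree))
  par <- parent_vec(tree)
  for (v in pre) {
    if (v == root) next
    Fst[v, ] <- resolve_step(matrix(D[, , v], n_states, n_chars),
                             Fst[par[v], ], mode)
  }
  Fst
}

#' Fitch parsimony reconstruction of discrete characters
#'
#' Computes, for each character, the minimum number of state changes on a
#' rooted tree (Fitch/Sankoff with unit costs) together with the downpass
#' state sets. Polytomies are handled natively by the dynamic programme
#' (equivalent to iterative pairwise intersection). Missing states (`NA` or
#' `"?"`) are treated as fully ambiguous at the tip.
#'
#' @param tree rooted `ape::phylo`.
#' @param x taxa x characters matrix of states (character or integer;
#'   rownames must match tip labels), or a vector for a single character.
#' @param states optional explicit state alphabet (character vector); by
#'   default the sorted set of observed states.
#' @return An object of class `fitch_recon`: a list with `tree`, `states`,
#'   `lengths` (per-character minimum change counts), the DP cost array, and
#'   `state_sets` (downpass sets per node as a logical array).
#' @examples
#' tr <- ape::read.tree(text = "((A:1,B:1):1,(C:1,D:1):1);")
#' x <- matrix(c(1, 1, 0, 0), 4, 1, dimnames = list(c("A", "B", "C", "D")))
#' fitch_reconstruct(tr, x)$lengths
#' @export
fitch_reconstruct <- function(tree, x, states = NULL) {
  if (!is.matrix(x)) x <- matrix(x, ncol = 1L, dimnames = list(names(x)))
  if (is.null(rownames(x)))
    stop("character matrix must have taxon rownames", call. = FALSE)
  miss <- setdiff(tree$tip.label, rownames(x))
  if (length(miss) > 0)
    stop("tips absent from character matrix: ", paste(miss, collapse = ", "),
         call. = FALSE)
  x <- x[tree$tip.label, , drop = FALSE]
  xc <- matrix(as.character(x), nrow(x), ncol(x), dimnames = dimnames(x))
  xc[xc %in% c("?", "-")] <- NA_character_
  if (is.null(states)) states <- sort(unique(as.vector(xc[!is.na(xc)])))
  if (length(states) == 0L)
    stop("undefined-length error: no observed states", call. = FALSE)
  n_chars <- ncol(xc)
  n_tip <- length(tree$tip.label)
  all_missing <- colSums(!is.na(xc)) == 0L
  if (any(all_missing))
    stop("undefined-length error: character(s) with all states missing: ",
         paste(which(all_missing), collapse = ", "), call. = FALSE)
  tip_allowed <- lapply(seq_len(n_tip), function(i) {
    m <- matrix(FALSE, length(states), n_chars)
    obs <- xc[i, ]
    known <- !is.na(obs)
    m[cbind(match(obs[known], states), which(known))] <- TRUE
    m[, !known] <- TRUE
    m
  })
  D <- sankoff_down(tree, tip_allowed, length(states), n_chars)
  root <- root_node(tree)
  lengths <- col_mins(matrix(D[, , root], length(states), n_chars))
  sets <- array(FALSE, dim = dim(D))
  n_node <- n_tip + tree$Nnode
  for (v in seq_len(n_node)) {
    dv <- matrix(D[, , v], length(states), n_chars)
    sets[, , v] <- dv == rep(col_mins(dv), each = length(states))
  }
  structure(list(tree = tree, states = states, lengths = unname(lengths),
                 cost = D, state_sets = sets, characters = colnames(xc)),
            class = "fitch_recon")
}

#' @export
print.fitch_recon <- function(x, ...) {
  cat(sprintf("<fitch_recon> %d character(s) on %d tips; total length %d\n",
              length(x$lengths), length(x$tree$tip.label), sum(x$lengths)))
  invisible(x)
}

#' Resolve ambiguous reconstructions and list per-branch events
#'
#' Resolves each character's most-parsimonious reconstruction into a single
#' state per node under ACCTRAN (changes accelerated toward the root,
#' favouring early loss plus reversal) or DELTRAN (changes delayed toward the
#' tips, favouring parallel changes; the default, following common practice
#' for editing-site mapping where parallel loss is the favoured explanation).
#' Either resolution realises exactly the Fitch minimum number of changes for
#' every character.
#'
#' @param recon a [fitch_reconstruct()] result.
#' @param mode `"deltran"` (default) or `"acctran"`.
#' @param root_tie when the root state is ambiguous, take the `"last"`
#'   (default) or `"first"` state in alphabet order. With the conventional
#'   `0/1` coding of editing presence, `"last"` keeps the site ancestrally
#'   edited so that losses are mapped below the root.
#' @return A tibble with one row per change: `character` (index), `branch_id`,
#'   `from`, `to`, `event` (`"gain"` if to > from in state order, else
#'   `"loss"`), and `mode`. The resolved node states are attached as the
#'   `"node_states"` attribute (node x character matrix of states).
#' @export
resolve_optimization <- function(recon, mode = c("deltran", "acctran"),
                                 root_tie = c("last", "first")) {
  stopifnot(inherits(recon, "fitch_recon"))
  mode <- match.arg(mode)
  root_tie <- match.arg(root_tie)
  tree <- recon$tree
  Fst <- resolve_states(tree, recon$cost, mode = mode, root_tie = root_tie)
  ids <- branch_ids(tree)
  e <- tree$edge
  rows <- list()
  for (i in seq_len(nrow(e))) {
    p <- Fst[e[i, 1L], ]
    c_ <- Fst[e[i, 2L], ]
    chg <- which(p != c_)
    if (length(chg) > 0)
      rows[[length(rows) + 1L]] <- tibble::tibble(
        character = chg,
        branch_id = ids[i],
        from = recon$states[p[chg]],
        to = recon$states[c_[chg]])
  }
  out <- if (length(rows) > 0) dplyr::bind_rows(rows) else
    tibble::tibble(character = integer(), branch_id = character(),
                   from = character(), to = character())
  out$event <- ifelse(match(out$to, recon$states) >
                        match(out$from, recon$states), "gain", "loss")
  out$mode <- mode
  st <- matrix(recon$states[Fst], nrow(Fst), ncol(Fst))
  rownames(st) <- node_labels(tree)
  attr(out, "node_states") <- st
  out
}

#' Per-branch totals of gains and losses
#'
#' Sums resolved per-character events into per-branch gain and loss counts.
#' The totals conserve parsimony length: summed over branches they equal the
#' summed Fitch lengths of the characters.
#'
#' @param events event tibble from [resolve_optimization()] (optionally
#'   row-bound across genes, with a `gene` column).
#' @param tree the tree the events were mapped on.
#' @return A tibble with one row per branch (`branch_id`, in `tree$edge`
#'   order): `gains`, `losses`, `changes`.
#' @export
count_branch_changes <- function(events, tree) {
  ids <- branch_ids(tree)
  base <- tibble::tibble(branch_id = ids)
  if (nrow(events) == 0)
    return(dplyr::mutate(base, gains = 0L, losses = 0L, changes = 0L))
  tab <- events |>
    dplyr::count(.data$branch_id, .data$event) |>
    tidyr::pivot_wider(names_from = "event", values_from = "n",
                       values_fill = 0L)
  if (is.null(tab[["gain"]])) tab$gain <- 0L
  if (is.null(tab[["loss"]])) tab$loss <- 0L
  base |>
    dplyr::left_join(tab, by = "branch_id") |>
    dplyr::mutate(gains = dplyr::coalesce(.data$gain, 0L),
                  losses = dplyr::coalesce(.data$loss, 0L),
                  changes = .data$gains + .data$losses) |>
    dplyr::select("branch_id", "gains", "losses", "changes")
}

# node number by branch id / label
node_by_label <- function(tree, label) {
  labs <- node_labels(tree)
  v <- match(label, labs)
  if (is.na(v)) stop("unknown node label: ", label, call. = FALSE)
  v
}

# vector of node numbers on the path ancestor -> tip (excluding ancestor,
# including tip); errors if tip does not descend from ancestor
path_nodes <- function(tree, ancestor, tip) {
  par <- parent_vec(tree)
  v <- tip
  path <- integer()
  while (!is.na(v) && v != ancestor) {
    path <- c(v, path)
    v <- par[v]
  }
  if (is.na(v))
    stop("lineage error: tip is not a descendant of the ancestor node",
         call. = FALSE)
  path
}

#' Cumulative changes from an ancestor node to a tip
#'
#' Sums mapped gains and losses over the branches on the path from an
#' internal node down to a tip — the "changes from the ancestor" statistic
#' used when comparing lineages of equal age.
#'
#' @param tree `ape::phylo`.
#' @param events per-branch event counts from [count_branch_changes()], or a
#'   raw event tibble from [resolve_optimization()].
#' @param ancestor node label (e.g. `"N3"`) or node number of the ancestor.
#' @param tip tip label or number.
#' @param losses_only if `TRUE`, count losses only.
#' @return Integer count.
#' @export
cumulative_changes <- function(tree, events, ancestor, tip,
                               losses_only = FALSE) {
  if (!"gains" %in% names(events)) events <- count_branch_changes(events, tree)
  anc <- if (is.character(ancestor)) node_by_label(tree, ancestor) else ancestor
  tp <- if (is.character(tip)) node_by_label(tree, tip) else tip
  nodes <- path_nodes(tree, anc, tp)
  ids <- node_labels(tree)[nodes]
  sel <- events$branch_id %in% ids
  if (losses_only) sum(events$losses[sel]) else sum(events$changes[sel])
}

#' Parsimony tree statistics
#'
#' Tree length, consistency index and retention index for a discrete
#' character matrix on a fixed tree. `L` is the summed Fitch length over all
#' characters; `CI` (excluding autapomorphies) and `RI` are computed over
#' parsimony-informative characters only, with per-character minimum steps
#' (observed states - 1) and maximum steps (non-missing tips minus the
#' largest state class).
#'
#' @inheritParams fitch_reconstruct
#' @return A tibble with one row: `L`, `CI`, `RI`, `n_characters`,
#'   `n_informative`.
#' @export
parsimony_stats <- function(tree, x, states = NULL) {
  if (!is.matrix(x)) x <- matrix(x, ncol = 1L, dimnames = list(names(x)))
  rec <- fitch_reconstruct(tree, x, states = states)
  xc <- matrix(as.character(x[tree$tip.label, , drop = FALSE]),
               length(tree$tip.label), ncol(x))
  xc[xc %in% c("?", "-")] <- NA_character_
  per_char <- lapply(seq_len(ncol(xc)), function(j) {
    tab <- table(xc[, j])
    list(min = length(tab) - 1L,
         max = sum(tab) - max(tab),
         informative = sum(tab >= 2L) >= 2L)
  })
  mins <- vapply(per_char, `[[`, integer(1), "min")
  maxs <- vapply(per_char, `[[`, integer(1), "max")
  info <- vapply(per_char, `[[`, logical(1), "informative")
  L <- sum(rec$lengths)
  if (!any(info))
    stop("RI undefined error: no parsimony-informative characters",
         call. = FALSE)
  Li <- sum(rec$lengths[info])
  CI <- sum(mins[info]) / Li
  RI <- (sum(maxs[info]) - Li) / (sum(maxs[info]) - sum(mins[info]))
  tibble::tibble(L = L, CI = CI, RI = RI,
                 n_characters = ncol(xc), n_informative = sum(info))
}
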