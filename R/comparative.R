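#' Exact two-sided Fisher test for a 2x2 table
#'
#' Exact hypergeometric test with the standard two-sided rule: the p-value is
#' the sum of probabilities of all tables (with the observed margins) whose
#' probability does not exceed the observed table's.
#'
#' @param a,b,c,d non-negative integer cell counts, rows = class
#'   (e.g. edited site / third position), columns = changed / unchanged.
#' @return The two-sided p-value.
#' @export
fisher_exact_2x2 <- function(a, b, c, d) {
  stopifnot(a >= 0, b >= 0, c >= 0, d >= 0)
  m <- a + b          # row 1 total
  n <- c + d          # row 2 total
  k <- a + c          # column 1 total
  if (m + n == 0 || k == 0 || k == m + n) return(1)
  lo <- max(0L, k - n)
  hi <- min(k, m)
  x <- lo:hi
  probs <- dhyper(x, m, n, k)
  p_obs <- dhyper(a, m, n, k)
  min(1, sum(probs[probs <= p_obs * (1 + 1e-7)]))
}

#' Averaged node-to-tip distance
#'
#' Propagates per-branch values into per-node node-to-tip distances: a tip's
#' value is its own branch value; an internal node's value is its own branch
#' value plus the mean of its daughters' node-to-tip values, recursively.
#' The root (which has no subtending branch) gets the mean of its daughters.
#'
#' @param tree rooted `ape::phylo`.
#' @param values per-branch values: tibble with `branch_id` and a value
#'   column (second column used), or named numeric vector by branch id.
#' @param node optional node label/number; if given, that node's value is
#'   returned as a scalar.
#' @return Named numeric vector over all nodes (by [node_labels()]), or a
#'   scalar if `node` is given.
#' @export
node_to_tip_value <- function(tree, values, node = NULL) {
  if (is.data.frame(values)) values <- setNames(values[[2]], values$branch_id)
  ids <- node_labels(tree)
  n_tip <- length(tree$tip.label)
  n_node <- n_tip + tree$Nnode
  root <- root_node(tree)
  bv <- numeric(n_node)
  present <- ids %in% names(values)
  bv[present] <- values[ids[present]]
  if (!all(present | seq_len(n_node) == root))
    stop("missing branch values for: ",
         paste(ids[!present & seq_len(n_node) != root], collapse = ", "),
         call. = FALSE)
  out <- numeric(n_node)
  kids <- child_list(tree)
  for (v in postorder_nodes(tree)) {
    own <- if (v == root) 0 else bv[v]
    out[v] <- if (v <= n_tip) own else own + mean(out[kids[[v]]])
  }
  names(out) <- ids
  if (!is.null(node)) {
    v <- if (is.character(node)) node_by_label(tree, node) else node
    return(unname(out[v]))
  }
  out
}

#' Sister-clade contrasts of two branch variables
#'
#' For every binary internal node, computes the difference between its two
#' daughters' averaged node-to-tip values ([node_to_tip_value()]) for an x
#' and a y variable. Sister clades are of equal age, so these differences
#' directly reflect rate differences. Each pair is oriented so that the x
#' contrast is non-negative, with the y contrast signed accordingly.
#' Polytomies contribute no contrast.
#'
#' @param tree rooted `ape::phylo`.
#' @param x,y per-branch values (tibble `branch_id` + value, or named
#'   vector), e.g. dS per branch and editing changes per branch.
#' @return A `contrast_set` tibble: `node`, `delta_x`, `delta_y`.
#' @export
sister_contrasts <- function(tree, x, y) {
  xv <- node_to_tip_value(tree, x)
  yv <- node_to_tip_value(tree, y)
  ids <- node_labels(tree)
  n_tip <- length(tree$tip.label)
  kids <- child_list(tree)
  rows <- purrr::map_dfr(
    (n_tip + 1):(n_tip + tree$Nnode), function(v) {
      k <- kids[[v]]
      if (length(k) != 2L) return(NULL)
      dx <- xv[k[1L]] - xv[k[2L]]
      dy <- yv[k[1L]] - yv[k[2L]]
      if (dx < 0) { dx <- -dx; dy <- -dy }
      tibble::tibble(node = ids[v], delta_x = unname(dx),
                     delta_y = unname(dy))
    })
  if (nrow(rows) == 0)
    rows <- tibble::tibble(node = character(), delta_x = numeric(),
                           delta_y = numeric())
  structure(rows, class = c("contrast_set", class(tibble::tibble())),
            standardization = "sister-difference")
}

#' Correlation and regression through the origin for contrasts
#'
#' Contrasts have expectation zero, so the regression is forced through the
#' origin: slope `= sum(xy)/sum(x^2)`, correlation
#' `r = sum(xy)/sqrt(sum(x^2) sum(y^2))`, and the t statistic
#' `r sqrt((n-1)/(1-r^2))` is referred to a t distribution with `n - 1`
#' degrees of freedom.
#'
#' @param contrasts a `contrast_set` (or any data frame whose first two
#'   numeric columns after `node` are the x and y contrasts), or a numeric
#'   vector `x` with `y` supplied.
#' @param y optional y vector when `contrasts` is a numeric vector.
#' @return An `rto_fit` one-row tibble: `slope`, `r`, `df`, `statistic`,
#'   `p_value`, `n`.
#' @export
regression_through_origin <- function(contrasts, y = NULL) {
  if (is.data.frame(contrasts)) {
    x <- contrasts$delta_x %||% contrasts[[2]]
    y <- contrasts$delta_y %||% contrasts[[3]]
  } else {
    x <- contrasts
  }
  stopifnot(length(x) == length(y))
  n <- length(x)
  if (n < 3) stop("need at least 3 contrasts", call. = FALSE)
  sxx <- sum(x^2)
  if (sxx == 0) stop("undefined error: sum of squared x contrasts is zero",
                     call. = FALSE)
  syy <- sum(y^2)
  sxy <- sum(x * y)
  slope <- sxy / sxx
  r <- if (syy == 0) 0 else sxy / sqrt(sxx * syy)
  df <- n - 1
  tstat <- if (abs(r) >= 1) Inf * sign(r) else r * sqrt(df / (1 - r^2))
  p <- 2 * pt(-abs(tstat), df)
  structure(tibble::tibble(slope = slope, r = r, df = df,
                           statistic = tstat, p_value = p, n = n),
            class = c("rto_fit", class(tibble::tibble())))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @method tidy rto_fit
#' @export
tidy.rto_fit <- function(x, ...) {
  tibble::tibble(term = "x", estimate = x$slope, statistic = x$statistic,
                 p.value = x$p_value)
}

#' @method glance rto_fit
#' @export
glance.rto_fit <- function(x, ...) {
  tibble::tibble(r = x$r, statistic = x$statistic, p.value = x$p_value,
                 df = x$df, nobs = x$n)
}

#' Phylogenetically independent contrasts on a dated tree
#'
#' Felsenstein contrasts standardised by branch durations (the
#' age-of-the-split standardisation): each contrast is the difference between
#' daughter values divided by the square root of the summed daughter branch
#' durations, with the usual pruning-wise variance augmentation
#' `v' = v + v1 v2/(v1 + v2)`. Computed via [ape::pic()]; polytomies are
#' resolved into zero-length dichotomies first.
#'
#' @param tree an ultrametric `phylo` with branch lengths in time units, or a
#'   `dated_tree` (its chronogram is used).
#' @param x named tip values (names = tip labels). Optionally a second trait
#'   `y` for paired contrasts.
#' @param y optional second trait.
#' @return A `contrast_set` tibble: `node`, `delta_x` (and `delta_y` when `y`
#'   given), standardised contrasts.
#' @export
pic_contrasts <- function(tree, x, y = NULL) {
  if (inherits(tree, "dated_tree")) tree <- tree$chronogram
  if (!ape::is.binary(tree) || !ape::is.rooted(tree))
    tree <- ape::multi2di(tree, random = FALSE)
  if (is.null(names(x))) stop("tip values must be named", call. = FALSE)
  x <- x[tree$tip.label]
  cx <- ape::pic(x, tree)
  ids <- node_labels(tree)
  n_tip <- length(tree$tip.label)
  nodes <- ids[as.integer(names(cx))]
  out <- tibble::tibble(node = nodes, delta_x = unname(cx))
  if (!is.null(y)) {
    y <- y[tree$tip.label]
    cy <- ape::pic(y, tree)
    out$delta_y <- unname(cy)
  }
  structure(out, class = c("contrast_set", class(tibble::tibble())),
            standardization = "pic")
}

#' Prune zero-editing clades to a single representative
#'
#' Within every maximal clade whose tips all have zero edited sites, retains
#' exactly one tip — the one with the longest (or shortest) terminal branch —
#' and drops the rest, collapsing degree-2 nodes. Tips with non-zero counts
#' are never removed. Used to counter the attenuation of rate/editing
#' correlations caused by lineages that cannot lose any more sites.
#'
#' @param tree rooted `ape::phylo`.
#' @param counts named per-tip edited-site counts (names = tip labels).
#' @param keep `"longest"` (default) or `"shortest"` terminal branch.
#' @return The pruned `phylo` (unchanged if no zero-count tips).
#' @export
prune_zero_edit <- function(tree, counts, keep = c("longest", "shortest")) {
  keep <- match.arg(keep)
  miss <- setdiff(tree$tip.label, names(counts))
  if (length(miss) > 0)
    stop("missing edited-site counts for: ", paste(miss, collapse = ", "),
         call. = FALSE)
  n_tip <- length(tree$tip.label)
  tb <- tips_below(tree)
  zero_tip <- counts[tree$tip.label] == 0
  all_zero <- vapply(seq_along(tb), function(v) all(zero_tip[tb[[v]]]),
                     logical(1))
  par <- parent_vec(tree)
  maximal <- which(vapply(seq_along(tb), function(v)
    all_zero[v] && (is.na(par[v]) || !all_zero[par[v]]), logical(1)))
  drop <- character()
  eidx <- edge_index_by_child(tree)
  for (v in maximal) {
    tips <- tb[[v]]
    if (length(tips) < 2L) next
    tl <- tree$edge.length[eidx[tips]]
    ord <- order(if (keep == "longest") -tl else tl, tree$tip.label[tips])
    drop <- c(drop, tree$tip.label[tips[ord[-1L]]])
  }
  if (length(drop) == 0) return(tree)
  ape::drop.tip(tree, drop, collapse.singles = TRUE)
}

#' Per-taxon C-to-T change rates at edited sites vs third positions
#'
#' For each tip descending from a focal ancestral node, compares the fraction
#' of ancestrally edited sites that have changed to `T` in that tip (`es`)
#' with the fraction of ancestrally-C third codon positions that read `T` in
#' the tip (`third`), with a per-taxon two-sided Fisher exact test.
#' Denominators are counts of eligible sites in the reconstructed focal-node
#' states; sites missing in the tip are excluded from both counts.
#'
#' @param history an `edit_history` from [map_editing()].
#' @param anc a parsimony [reconstruct_ancestral_sequences()] result on the
#'   same tree.
#' @param focal_node node label (e.g. `"N2"`) or number of the focal
#'   ancestor.
#' @param gene gene name stamped on the rows.
#' @return A `rate_summary` tibble: `taxon`, `gene`, `es_changed`,
#'   `es_total`, `es_rate`, `third_changed`, `third_total`, `third_rate`,
#'   `fisher_p`.
#' @export
rate_summary <- function(history, anc, focal_node, gene = "gene") {
  tree <- history$tree
  v <- if (is.character(focal_node)) node_by_label(tree, focal_node)
       else focal_node
  n_tip <- length(tree$tip.label)
  tb <- tips_below(tree)
  tips <- tb[[v]]
  es_states <- history$node_states      # node x char (resolved)
  m <- history$matrix                   # taxa x char (observed, may be NA)
  es_cols <- which(es_states[v, ] == "1")
  ed_pos <- as.integer(colnames(m))
  third_cols <- which(anc$codon_position == 3L & !anc$masked &
                        !(seq_along(anc$masked) %in% ed_pos))
  third_cols <- third_cols[anc$states[v, third_cols] == "C"]
  rows <- purrr::map_dfr(tips, function(tp) {
    tx <- tree$tip.label[tp]
    es_obs <- m[tx, es_cols]
    es_tot <- sum(!is.na(es_obs))
    es_chg <- sum(es_obs == "0", na.rm = TRUE)
    t_obs <- anc$states[tx, third_cols]
    keep <- t_obs %in% c("C", "T")
    th_tot <- sum(keep)
    th_chg <- sum(t_obs[keep] == "T")
    p <- if (es_tot > 0 && th_tot > 0)
      fisher_exact_2x2(es_chg, es_tot - es_chg, th_chg, th_tot - th_chg)
    else NA_real_
    tibble::tibble(
      taxon = tx, gene = gene,
      es_changed = es_chg, es_total = es_tot,
      es_rate = if (es_tot > 0) es_chg / es_tot else NA_real_,
      third_changed = th_chg, third_total = th_tot,
      third_rate = if (th_tot > 0) th_chg / th_tot else NA_real_,
      fisher_p = p)
  })
  structure(rows, class = c("rate_summary", class(tibble::tibble())))
}

#' Map editing presence/absence characters on a tree
#'
#' Bundles the Fitch pass, the ACCTRAN/DELTRAN resolution and the per-branch
#' event extraction for a binary editing character matrix.
#'
#' @param tree rooted `ape::phylo`.
#' @param m taxa x characters matrix from [build_character_matrix()]
#'   (`"1"`/`"0"`/`NA`).
#' @param mode optimisation mode passed to [resolve_optimization()].
#' @return An object of class `edit_history`: list with `tree`, `matrix`,
#'   `recon` ([fitch_reconstruct()]), `events`, `node_states`,
#'   `branch_events` ([count_branch_changes()]) and `mode`.
#' @export
map_editing <- function(tree, m, mode = c("deltran", "acctran")) {
  mode <- match.arg(mode)
  recon <- fitch_reconstruct(tree, m, states = c("0", "1"))
  events <- resolve_optimization(recon, mode = mode)
  structure(list(tree = tree, matrix = m[tree$tip.label, , drop = FALSE],
                 recon = recon, events = events,
                 node_states = attr(events, "node_states"),
                 branch_events = count_branch_changes(events, tree),
                 mode = mode),
            class = "edit_history")
}

#' @export
print.edit_history <- function(x, ...) {
  cat(sprintf(
    "<edit_history> %d characters, %s resolution: %d gains, %d losses\n",
    ncol(x$matrix), x$mode, sum(x$branch_events$gains),
    sum(x$branch_events$losses)))
  invisible(x)
}
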