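#' Non-parametric rate smoothing (NPRS) dating
#'
#' Converts a rooted tree with branch lengths (substitutions/site) into a
#' chronogram by minimising the rate-smoothing objective: the sum over
#' branches of the squared difference between each branch's implied rate
#' (length divided by duration) and the rate of its parent branch; at the
#' root, where no parent branch exists, the squared deviations of the root's
#' child rates from their mean are used. The root age is fixed by
#' calibration; tip ages are 0. Internal ages are parameterised as fractions
#' of their parent's age (keeping the age order valid by construction) and
#' optimised numerically with BFGS; the search is restarted `restarts` times
#' from perturbed starting points and the best objective kept. A duration
#' floor of `1e-6 * root_age` guards against zero-duration branches.
#'
#' @param tree rooted `ape::phylo` with non-negative branch lengths.
#' @param root_age calibration age of the root (Ma).
#' @param restarts number of perturbed restarts after the deterministic
#'   start (default 5). Restart perturbations draw from the current RNG
#'   stream, so results are reproducible under `set.seed()`.
#' @param perturb_sd standard deviation of the logit-scale perturbation.
#' @return An object of class `dated_tree`: list with `tree` (the input),
#'   `chronogram` (`phylo` with branch lengths in Ma), `ages` (named by
#'   [node_labels()]), `objective`, `root_age`, `converged`.
#' @export
nprs_date <- function(tree, root_age, restarts = 5L, perturb_sd = 0.5) {
  stopifnot(root_age > 0)
  if (any(tree$edge.length < 0))
    stop("dating error: negative branch lengths", call. = FALSE)
  n_tip <- length(tree$tip.label)
  n_node <- n_tip + tree$Nnode
  root <- root_node(tree)
  par <- parent_vec(tree)
  eidx <- edge_index_by_child(tree)
  free <- setdiff((n_tip + 1):n_node, root)
  eps <- 1e-6 * root_age

  # preorder list of free internal nodes (parents before children)
  pre <- rev(postorder_nodes(tree))
  pre_free <- pre[pre %in% free]

  ages_from_u <- function(u) {
    ages <- numeric(n_node)
    ages[root] <- root_age
    for (k in seq_along(pre_free)) {
      v <- pre_free[k]
      ages[v] <- ages[par[v]] * u[k]
    }
    ages
  }

  internal_edges <- which(tree$edge[, 2L] > n_tip)
  kids_e <- lapply(internal_edges,
                   function(i) which(tree$edge[, 1L] == tree$edge[i, 2L]))
  root_edges <- which(tree$edge[, 1L] == root)
  objective <- function(ages) {
    dur <- pmax(ages[tree$edge[, 1L]] - ages[tree$edge[, 2L]], eps)
    r <- tree$edge.length / dur
    w <- 0
    for (k in seq_along(internal_edges)) {
      i <- internal_edges[k]
      w <- w + sum((r[i] - r[kids_e[[k]]])^2)
    }
    rk <- r[root_edges]
    w + sum((rk - mean(rk))^2)
  }

  # deterministic start: ages proportional to maximum tip distance below
  h <- numeric(n_node)
  for (v in postorder_nodes(tree)) {
    if (v <= n_tip) next
    kids <- which(tree$edge[, 1L] == v)
    h[v] <- max(tree$edge.length[kids] + h[tree$edge[, 2L][kids]])
  }
  if (length(free) == 0L) {
    ages <- numeric(n_node)
    ages[root] <- root_age
    obj <- objective(ages)
    return(new_dated_tree(tree, ages, obj, root_age, TRUE))
  }
  u0 <- vapply(pre_free, function(v) {
    hp <- h[par[v]]
    if (hp <= 0) 0.5 else min(max(h[v] / hp, 1e-4), 1 - 1e-4)
  }, numeric(1))
  theta0 <- qlogis(u0)

  fn <- function(theta) objective(ages_from_u(plogis(theta)))
  best <- NULL
  starts <- c(list(theta0),
              lapply(seq_len(restarts), function(i)
                theta0 + rnorm(length(theta0), sd = perturb_sd)))
  for (st in starts) {
    fit <- tryCatch(
      optim(st, fn, method = "BFGS",
            control = list(maxit = 500, reltol = 1e-12)),
      error = function(e) NULL)
    if (is.null(fit)) next
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  if (is.null(best))
    stop("dating error: optimisation failed in all restarts", call. = FALSE)
  ages <- ages_from_u(plogis(best$par))
  new_dated_tree(tree, ages, best$value, root_age,
                 best$convergence %in% c(0L, 1L))
}

new_dated_tree <- function(tree, ages, objective, root_age, converged) {
  chron <- tree
  chron$edge.length <- ages[tree$edge[, 1L]] - ages[tree$edge[, 2L]]
  names(ages) <- node_labels(tree)
  structure(list(tree = tree, chronogram = chron, ages = ages,
                 objective = objective, root_age = root_age,
                 converged = converged),
            class = "dated_tree")
}

#' @export
print.dated_tree <- function(x, ...) {
  cat(sprintf(
    "<dated_tree> root age %.4g Ma, smoothing objective %.6g\n",
    x$root_age, x$objective))
  invisible(x)
}

#' Node ages of a dated tree as a tibble
#' @param x a `dated_tree`.
#' @param ... unused.
#' @method tidy dated_tree
#' @export
tidy.dated_tree <- function(x, ...) {
  tibble::tibble(node = names(x$ages), age = unname(x$ages),
                 is_tip = names(x$ages) %in% x$tree$tip.label)
}

#' @method glance dated_tree
#' @export
glance.dated_tree <- function(x, ...) {
  tibble::tibble(root_age = x$root_age, objective = x$objective,
                 n_tips = length(x$tree$tip.label), converged = x$converged)
}

#' Absolute synonymous substitution rate for a taxon
#'
#' The per-taxon rate `R_S` is the synonymous path length from a focal
#' ancestral node down to the tip, divided by the focal node's age in years —
#' the per-lineage workaround for trees where many individual branches carry
#' zero synonymous length.
#'
#' @param tree rooted `ape::phylo` (topology source for the path).
#' @param ds per-branch synonymous lengths: a tibble with `branch_id` and
#'   `ds` (e.g. from [tree_branch_ds()]) or a named numeric vector.
#' @param focal_node node label (e.g. `"N2"`) or number of the focal
#'   ancestor.
#' @param taxon tip label; must descend from the focal node.
#' @param focal_age_ma age of the focal node in Ma.
#' @return `R_S` in substitutions per site per year.
#' @export
absolute_rate <- function(tree, ds, focal_node, taxon, focal_age_ma) {
  stopifnot(focal_age_ma > 0)
  if (is.data.frame(ds)) ds <- setNames(ds$ds, ds$branch_id)
  anc <- if (is.character(focal_node)) node_by_label(tree, focal_node)
         else focal_node
  tp <- if (is.character(taxon)) node_by_label(tree, taxon) else taxon
  nodes <- path_nodes(tree, anc, tp)
  ids <- node_labels(tree)[nodes]
  miss <- setdiff(ids, names(ds))
  if (length(miss) > 0)
    stop("no dS value for branch(es): ", paste(miss, collapse = ", "),
         call. = FALSE)
  sum(ds[ids]) / (focal_age_ma * 1e6)
}
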