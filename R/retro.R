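# minimal window width (nt) containing any k of the sorted positions
min_window <- function(pos, k) {
  m <- length(pos)
  if (k > m) return(NA_real_)
  pos <- sort(pos)
  min(pos[k:m] - pos[1:(m - k + 1L)]) + 1
}

#' Scan branches for clustered losses of edited sites (retroprocessing)
#'
#' Gene conversion with a reverse-transcribed (edited) cDNA copy removes many
#' edited sites in one event, leaving a run of losses packed into a short
#' stretch of the gene. For each branch carrying losses this scan asks, for
#' every cluster size `k` from 3 up to the number of losses, how unusually
#' tight the tightest k-loss window is compared with losses redrawn uniformly
#' from the branch's at-risk edited-site positions. Per-window p-values come
#' from the permutation distribution of the minimal k-window width; the
#' branch-level p calibrates the smallest per-k p against its own permutation
#' distribution (so testing several k on one branch does not inflate the
#' branch-level false-positive rate). A branch that loses every at-risk
#' edited site is additionally flagged as a whole-gene conversion candidate.
#'
#' @param losses tibble with `branch_id` and `position` (1-based nt) of
#'   edited-site losses, e.g. [resolve_optimization()] events with
#'   `event == "loss"` joined to character positions.
#' @param at_risk at-risk edited-site positions per branch: either a numeric
#'   vector (same for all branches) or a tibble `branch_id`, `position`.
#' @param n_perm number of permutations (>= 100).
#' @param alpha significance level for reporting candidate segments.
#' @return A `retro_scan` tibble, one row per branch with >= 2 losses:
#'   `branch_id`, `n_losses`, `n_at_risk`, `whole_gene`, `branch_p`,
#'   `candidate`, and list-column `segments` (tibbles `k`, `start`, `end`,
#'   `width`, `p_value`).
#' @export
retro_scan <- function(losses, at_risk, n_perm = 10000L, alpha = 0.05) {
  if (n_perm < 100L)
    stop("config error: n_perm must be at least 100", call. = FALSE)
  if (!is.data.frame(at_risk))
    at_risk <- tidyr::expand_grid(branch_id = unique(losses$branch_id),
                                  position = at_risk)
  branches <- losses |>
    dplyr::count(.data$branch_id, name = "n_losses") |>
    dplyr::filter(.data$n_losses >= 2L)
  rows <- purrr::map_dfr(branches$branch_id, function(b) {
    pos <- sort(losses$position[losses$branch_id == b])
    risk <- sort(unique(at_risk$position[at_risk$branch_id == b]))
    m <- length(pos)
    whole <- length(risk) > 0 && all(risk %in% pos)
    ks <- if (m >= 3L) 3:m else integer()
    if (length(ks) == 0L || length(risk) <= m) {
      seg <- tibble::tibble(k = integer(), start = integer(),
                            end = integer(), width = numeric(),
                            p_value = numeric())
      return(tibble::tibble(branch_id = b, n_losses = m,
                            n_at_risk = length(risk), whole_gene = whole,
                            branch_p = NA_real_,
                            candidate = whole, segments = list(seg)))
    }
    obs_w <- vapply(ks, function(k) min_window(pos, k), numeric(1))
    perm_w <- matrix(NA_real_, n_perm, length(ks))
    for (bb in seq_len(n_perm)) {
      draw <- sort(sample(risk, m))
      perm_w[bb, ] <- vapply(ks, function(k) min_window(draw, k), numeric(1))
    }
    p_k <- vapply(seq_along(ks), function(j)
      (1 + sum(perm_w[, j] <= obs_w[j])) / (n_perm + 1), numeric(1))
    # branch-level calibration of min-k p via permutation ranks
    perm_p <- matrix(NA_real_, n_perm, length(ks))
    for (j in seq_along(ks)) {
      sw <- sort(perm_w[, j])
      perm_p[, j] <- findInterval(perm_w[, j], sw) / n_perm
    }
    t_obs <- min(p_k)
    t_perm <- apply(perm_p, 1L, min)
    branch_p <- (1 + sum(t_perm <= t_obs)) / (n_perm + 1)
    seg <- purrr::map_dfr(seq_along(ks), function(j) {
      k <- ks[j]
      d <- pos[k:m] - pos[1:(m - k + 1L)]
      i <- which.min(d)
      tibble::tibble(k = k, start = pos[i], end = pos[i + k - 1L],
                     width = obs_w[j], p_value = p_k[j])
    }) |>
      dplyr::filter(.data$p_value < alpha)
    tibble::tibble(branch_id = b, n_losses = m, n_at_risk = length(risk),
                   whole_gene = whole, branch_p = branch_p,
                   candidate = whole | branch_p < alpha,
                   segments = list(seg))
  })
  if (nrow(rows) == 0)
    rows <- tibble::tibble(branch_id = character(), n_losses = integer(),
                           n_at_risk = integer(), whole_gene = logical(),
                           branch_p = numeric(), candidate = logical(),
                           segments = list())
  structure(rows, class = c("retro_scan", class(tibble::tibble())),
            alpha = alpha, n_perm = n_perm)
}
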