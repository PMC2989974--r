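# Independent oracles used across the suite. These deliberately share no
# code with the package internals: parsimony by exhaustive enumeration of
# ancestral assignments, Fisher by direct hypergeometric enumeration with
# lchoose, regression by the closed formulas.

# exhaustive minimum-change count for one character on a rooted ape tree;
# tip_states: named vector over tips ("?"/NA = free)
oracle_fitch <- function(tree, tip_states) {
  n_tip <- length(tree$tip.label)
  n_node <- n_tip + tree$Nnode
  obs <- tip_states[tree$tip.label]
  alphabet <- sort(unique(obs[!is.na(obs) & obs != "?"]))
  free <- which(is.na(obs) | obs == "?")
  vary <- c(free, (n_tip + 1):n_node)
  grid <- do.call(expand.grid,
                  c(rep(list(alphabet), length(vary)),
                    list(stringsAsFactors = FALSE)))
  best <- Inf
  best_assigns <- list()
  for (g in seq_len(nrow(grid))) {
    st <- character(n_node)
    st[seq_len(n_tip)] <- obs
    st[vary] <- unlist(grid[g, ])
    cost <- sum(st[tree$edge[, 1L]] != st[tree$edge[, 2L]])
    if (cost < best) {
      best <- cost
      best_assigns <- list(st)
    } else if (cost == best) {
      best_assigns[[length(best_assigns) + 1L]] <- st
    }
  }
  list(length = best, assignments = best_assigns)
}

# event set (branch_id/from/to strings) implied by one full assignment
oracle_events <- function(tree, st) {
  ids <- editevol::branch_ids(tree)
  e <- tree$edge
  chg <- which(st[e[, 1L]] != st[e[, 2L]])
  sort(paste(ids[chg], st[e[chg, 1L]], st[e[chg, 2L]], sep = ">"))
}

# direct hypergeometric enumeration for the two-sided Fisher p
oracle_fisher <- function(a, b, c, d) {
  m <- a + b; n <- c + d; k <- a + c
  if (m + n == 0 || k == 0 || k == m + n) return(1)
  xs <- max(0, k - n):min(k, m)
  logp <- lchoose(m, xs) + lchoose(n, k - xs) - lchoose(m + n, k)
  p <- exp(logp)
  p_obs <- exp(lchoose(m, a) + lchoose(n, k - a) - lchoose(m + n, k))
  min(1, sum(p[p <= p_obs * (1 + 1e-7)]))
}

# random rooted binary tree with given tips and unit branch lengths
random_tree <- function(n_tip, labels = paste0("t", seq_len(n_tip))) {
  tr <- ape::rtree(n_tip, tip.label = sample(labels))
  tr$edge.length <- rep(1, nrow(tr$edge))
  tr
}

# tiny codon alignment from named sequences (strings)
aln_from_strings <- function(seqs, gene = "g", frame = 0L) {
  m <- do.call(rbind, lapply(seqs, function(s) strsplit(s, "")[[1]]))
  rownames(m) <- names(seqs)
  editevol::codon_alignment(m, gene = gene, frame = frame)
}
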