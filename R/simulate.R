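#' Simulation parameters
#'
#' Default parameters emulate the shape of the Alismatales five-gene
#' mitochondrial data set: 46 taxa, five genes totalling ~4356 aligned
#' positions, edited-site counts of 5/44/25/30/25 concentrated at 1st/2nd
#' codon positions, a 130 Ma root, shallow synonymous divergence, and a
#' moderately elevated C-to-T rate at edited sites.
#'
#' @param n_taxa number of tips.
#' @param birth Yule birth rate (shape only; the tree is rescaled to
#'   `root_age`).
#' @param root_age root age in Ma.
#' @param genes tibble with columns `gene`, `n_codons`, `n_edited`.
#' @param edited_pos_mix probabilities of an edited site sitting at codon
#'   position 1/2/3.
#' @param subst_scale expected substitutions per site from root to tip at
#'   the baseline rate.
#' @param rel_rates relative substitution rates of codon positions 1-3.
#' @param kappa transition/transversion rate ratio of the HKY-like process.
#' @param lambda_es multiplier applied to the C-to-T rate at edited sites
#'   (1 = neutral-equivalent dynamics).
#' @param es_rate_mult overall substitution-rate multiplier at edited sites
#'   (default 1); 0 freezes edited sites so that they change only through
#'   conversion events (the conversion-only regime).
#' @param clade_rates list of `list(tips = c(...), mult = )` rate
#'   multipliers applied to branches wholly inside the tip set.
#' @param conversions list of `list(gene =, branch =, window = c(lo, hi) or
#'   NULL, completeness = )` retroprocessing events; `branch` is a branch id
#'   ([branch_ids()]) on the simulated tree.
#' @param cdna_coverage fraction of taxa with cDNA evidence.
#' @return A list of class `sim_params`.
#' @export
sim_params <- function(n_taxa = 46L,
                       birth = 1,
                       root_age = 130,
                       genes = tibble::tibble(
                         gene = c("atp1", "ccmB", "cob", "mtt2", "nad5"),
                         n_codons = c(380L, 207L, 393L, 259L, 213L),
                         n_edited = c(5L, 44L, 25L, 30L, 25L)),
                       edited_pos_mix = c(0.465, 0.512, 0.023),
                       subst_scale = 0.08,
                       rel_rates = c(1, 1, 1),
                       kappa = 2,
                       lambda_es = 3,
                       es_rate_mult = 1,
                       clade_rates = list(),
                       conversions = list(),
                       cdna_coverage = 1) {
  stopifnot(n_taxa >= 2, root_age > 0, all(genes$n_codons > 0),
            all(genes$n_edited >= 0), subst_scale >= 0, kappa > 0,
            lambda_es >= 0, es_rate_mult >= 0, cdna_coverage >= 0,
            cdna_coverage <= 1)
  structure(list(n_taxa = as.integer(n_taxa), birth = birth,
                 root_age = root_age, genes = genes,
                 edited_pos_mix = edited_pos_mix / sum(edited_pos_mix),
                 subst_scale = subst_scale, rel_rates = rel_rates,
                 kappa = kappa, lambda_es = lambda_es,
                 es_rate_mult = es_rate_mult,
                 clade_rates = clade_rates, conversions = conversions,
                 cdna_coverage = cdna_coverage),
            class = "sim_params")
}

#' Simulate a dated Yule tree
#'
#' Forward birth-process simulation starting from the two daughters of the
#' root. With `n_taxa` set, growth stops when that many lineages exist and
#' tips are extended by one further exponential waiting time before the tree
#' is rescaled so the root sits at `root_age`. With `t_max` set instead, the
#' process simply runs for that much time and is returned unscaled (tip
#' count is then random).
#'
#' @param n_taxa target number of tips (ignored when `t_max` is given).
#' @param birth per-lineage birth rate.
#' @param root_age root age for rescaling (Ma).
#' @param t_max optional fixed duration for forward simulation.
#' @return Ultrametric `ape::phylo` with branch lengths in Ma (or raw time
#'   units under `t_max`).
#' @export
simulate_tree <- function(n_taxa = 46L, birth = 1, root_age = 130,
                          t_max = NULL) {
  stopifnot(is.null(t_max) || t_max > 0, n_taxa >= 2)
  # lineages: parent internal-node key and start time; splits create keys
  nxt <- 1L
  new_key <- function() {
    k <- nxt
    nxt <<- nxt + 1L
    k
  }
  root_key <- new_key()
  lineages <- list(list(parent = root_key, start = 0),
                   list(parent = root_key, start = 0))
  # children by key: child keys (internal, numeric) or tip labels (character)
  children <- list(list())
  times <- c(0)        # by key: split time
  t <- 0
  repeat {
    k <- length(lineages)
    if (is.null(t_max) && k >= n_taxa) break
    wait <- rexp(1, birth * k)
    if (!is.null(t_max) && t + wait > t_max) break
    t <- t + wait
    i <- sample.int(k, 1L)
    key <- new_key()
    times[key] <- t
    children[[key]] <- list()
    parent <- lineages[[i]]$parent
    children[[parent]] <- c(children[[parent]], key)
    lineages[[i]] <- list(parent = key, start = t)
    lineages[[k + 1L]] <- list(parent = key, start = t)
  }
  t_end <- if (is.null(t_max)) t + rexp(1, birth * length(lineages)) else t_max
  for (i in seq_along(lineages)) {
    lab <- paste0("t", i)
    parent <- lineages[[i]]$parent
    children[[parent]] <- c(children[[parent]], lab)
  }
  scale <- if (is.null(t_max)) root_age / t_end else 1
  to_newick <- function(key, parent_time) {
    if (is.character(key))
      return(sprintf("%s:%.10g", key, (t_end - parent_time) * scale))
    kids <- children[[key]]
    inner <- paste(vapply(kids, to_newick, character(1),
                          parent_time = times[key]), collapse = ",")
    sprintf("(%s):%.10g", inner, (times[key] - parent_time) * scale)
  }
  kids <- children[[root_key]]
  txt <- paste0("(", paste(vapply(kids, to_newick, character(1),
                                  parent_time = 0), collapse = ","), ");")
  ape::read.tree(text = txt)
}

# HKY-like per-site jump simulation along one branch.
# state: integer vector (1..4 = A C G T); returns new states and event log.
NTS <- c("A", "C", "G", "T")
transition_partner <- c(3L, 4L, 1L, 2L)  # A<->G, C<->T

simulate_branch <- function(state, site_rate, kappa, es_ct_mult, duration) {
  n <- length(state)
  # per-state relative flows: kappa to the transition partner, 1 to each
  # transversion; at edited sites the C->T flow is multiplied
  ct_mult <- es_ct_mult
  events <- list()
  rem <- rep(duration, n)
  active <- which(site_rate > 0 & rem > 0)
  while (length(active) > 0) {
    st <- state[active]
    flow_tot <- (kappa + 2) + (st == 2L) * kappa * (ct_mult[active] - 1)
    out_rate <- site_rate[active] * flow_tot / (kappa + 2)
    wait <- rexp(length(active), out_rate)
    hit <- wait < rem[active]
    if (!any(hit)) break
    idx <- active[hit]
    rem[idx] <- rem[idx] - wait[hit]
    rem[active[!hit]] <- 0
    # choose targets
    for (s in idx) {
      cur <- state[s]
      w <- rep(1, 4)
      w[transition_partner[cur]] <- kappa
      if (cur == 2L) w[4L] <- kappa * ct_mult[s]
      w[cur] <- 0
      nxt <- sample.int(4L, 1L, prob = w)
      events[[length(events) + 1L]] <- c(s, cur, nxt)
      state[s] <- nxt
    }
    active <- idx
  }
  log <- if (length(events) > 0) {
    ev <- do.call(rbind, events)
    tibble::tibble(position = ev[, 1L], from = NTS[ev[, 2L]],
                   to = NTS[ev[, 3L]])
  } else tibble::tibble(position = integer(), from = character(),
                        to = character())
  list(state = state, log = log)
}

# expand clade_rates into a per-branch multiplier vector (tree$edge order)
branch_rate_mult <- function(tree, clade_rates) {
  mult <- rep(1, nrow(tree$edge))
  if (length(clade_rates) == 0) return(mult)
  tb <- tips_below(tree)
  for (cr in clade_rates) {
    tipset <- match(cr$tips, tree$tip.label)
    inside <- vapply(tree$edge[, 2L], function(v)
      all(tb[[v]] %in% tipset), logical(1))
    mult[inside] <- mult[inside] * cr$mult
  }
  mult
}

#' Simulate codon alignments with edited sites along a dated tree
#'
#' Evolves one gene down the tree under a per-position HKY-like process.
#' Designated edited sites start as `C` at the root and experience a C-to-T
#' rate multiplied by `lambda_es`; retroprocessing events convert remaining
#' edited `C`s to `T` on a branch (optionally only inside a window, each site
#' independently with probability `completeness`). The cDNA alignment equals
#' the genomic DNA with every remaining edited-site `C` rendered as `T`. A
#' complete mutation log and all internal node sequences are recorded so any
#' downstream inference can be checked against truth.
#'
#' @param tree ultrametric `phylo` with branch lengths in Ma.
#' @param params a [sim_params()] object.
#' @param gene row of `params$genes` to simulate (name); defaults to the
#'   first.
#' @param root_seq optional explicit root sequence (character vector).
#' @param edited_positions optional explicit 1-based edited-site positions.
#' @return A list of class `sim_gene`: `dna` and `cdna`
#'   ([codon_alignment()]s), `truth` (list: `tree`, `root_seq`,
#'   `edited_positions`, `node_seqs` node x position matrix, `mutation_log`
#'   tibble with `branch_id`, `position`, `from`, `to`, `type`,
#'   `conversions`).
#' @export
simulate_sequences <- function(tree, params, gene = NULL, root_seq = NULL,
                               edited_positions = NULL) {
  if (is.null(gene)) gene <- params$genes$gene[1L]
  g <- params$genes[params$genes$gene == gene, ]
  if (nrow(g) != 1L) stop("unknown gene: ", gene, call. = FALSE)
  n_nt <- 3L * g$n_codons
  root_depth <- max(ape::node.depth.edgelength(tree))

  if (is.null(root_seq)) {
    root_seq <- character(0)
    for (i in seq_len(g$n_codons)) {
      repeat {
        cd <- sample(NTS, 3L, replace = TRUE)
        if (!paste0(cd, collapse = "") %in% c("TAA", "TAG", "TGA")) break
      }
      root_seq <- c(root_seq, cd)
    }
  }
  stopifnot(length(root_seq) == n_nt)
  if (is.null(edited_positions) && g$n_edited > 0) {
    cods <- sample.int(g$n_codons, g$n_edited)
    offs <- sample(1:3, g$n_edited, replace = TRUE,
                   prob = params$edited_pos_mix)
    edited_positions <- sort(3L * (cods - 1L) + offs)
  }
  edited_positions <- sort(unique(edited_positions))
  root_seq[edited_positions] <- "C"

  site_rate <- (params$subst_scale / root_depth) *
    params$rel_rates[codon_position(seq_len(n_nt), 0L)]
  site_rate[edited_positions] <- site_rate[edited_positions] *
    (params$es_rate_mult %||% 1)
  es_mult <- rep(1, n_nt)
  es_mult[edited_positions] <- params$lambda_es

  ids <- branch_ids(tree)
  mult <- branch_rate_mult(tree, params$clade_rates)
  n_tip <- length(tree$tip.label)
  n_node <- n_tip + tree$Nnode
  node_seqs <- matrix(NA_character_, n_node, n_nt)
  rownames(node_seqs) <- node_labels(tree)
  root <- root_node(tree)
  state <- vector("list", n_node)
  state[[root]] <- match(root_seq, NTS)
  node_seqs[root, ] <- root_seq
  logs <- list()
  convs <- purrr::keep(params$conversions,
                       function(cv) is.null(cv$gene) || cv$gene == gene)
  conv_log <- list()
  pre <- rev(postorder_nodes(tree))
  eidx <- edge_index_by_child(tree)
  for (v in pre) {
    if (v == root) next
    i <- eidx[v]
    p <- tree$edge[i, 1L]
    res <- simulate_branch(state[[p]], site_rate * mult[i], params$kappa,
                           es_mult, tree$edge.length[i])
    st <- res$state
    if (nrow(res$log) > 0) {
      res$log$branch_id <- ids[i]
      res$log$type <- "substitution"
      logs[[length(logs) + 1L]] <- res$log
    }
    for (cv in convs) {
      if (!identical(cv$branch, ids[i])) next
      win <- cv$window %||% c(1L, n_nt)
      comp <- cv$completeness %||% 1
      targ <- edited_positions[edited_positions >= win[1L] &
                                 edited_positions <= win[2L]]
      targ <- targ[st[targ] == 2L]
      targ <- targ[runif(length(targ)) <= comp]
      if (length(targ) > 0) {
        st[targ] <- 4L
        logs[[length(logs) + 1L]] <- tibble::tibble(
          position = targ, from = "C", to = "T", branch_id = ids[i],
          type = "conversion")
      }
      conv_log[[length(conv_log) + 1L]] <- tibble::tibble(
        gene = gene, branch_id = ids[i], start = win[1L], end = win[2L],
        completeness = comp, n_converted = length(targ))
    }
    state[[v]] <- st
    node_seqs[v, ] <- NTS[st]
  }
  dna_m <- node_seqs[seq_len(n_tip), , drop = FALSE]
  rownames(dna_m) <- tree$tip.label
  dna <- codon_alignment(dna_m, gene = gene, frame = 0L)
  n_cov <- max(1L, round(params$cdna_coverage * n_tip))
  cov_taxa <- sort(sample(tree$tip.label, n_cov))
  cdna_m <- dna_m[cov_taxa, , drop = FALSE]
  if (length(edited_positions) > 0)
    for (tx in cov_taxa) {
      cc <- edited_positions[cdna_m[tx, edited_positions] == "C"]
      cdna_m[tx, cc] <- "T"
    }
  cdna <- codon_alignment(cdna_m, gene = gene, frame = 0L)
  mlog <- if (length(logs) > 0) dplyr::bind_rows(logs) else
    tibble::tibble(position = integer(), from = character(),
                   to = character(), branch_id = character(),
                   type = character())
  mlog$gene <- gene
  structure(list(
    dna = dna, cdna = cdna,
    truth = list(tree = tree, root_seq = root_seq,
                 edited_positions = edited_positions,
                 node_seqs = node_seqs, mutation_log = mlog,
                 conversions = if (length(conv_log) > 0)
                   dplyr::bind_rows(conv_log) else NULL)),
    class = "sim_gene")
}

#' Simulate a full multi-gene data set
#'
#' Draws one dated Yule tree and simulates every gene in
#' `params$genes` along it.
#'
#' @param params a [sim_params()] object.
#' @param tree optional user tree (ultrametric, branch lengths in Ma);
#'   simulated when absent.
#' @return List of class `sim_dataset`: `tree` plus one [simulate_sequences()]
#'   result per gene (named).
#' @export
simulate_dataset <- function(params, tree = NULL) {
  if (is.null(tree))
    tree <- simulate_tree(params$n_taxa, params$birth, params$root_age)
  genes <- lapply(params$genes$gene, function(gn)
    simulate_sequences(tree, params, gene = gn))
  names(genes) <- params$genes$gene
  structure(list(tree = tree, genes = genes, params = params),
            class = "sim_dataset")
}
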