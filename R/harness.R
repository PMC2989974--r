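#' Pooled C-to-T rate ratio between edited sites and third positions
#'
#' Tree-wide estimator of how much faster edited sites change C-to-T than
#' non-edited third-codon-position Cs. Edit calling and heterogeneity
#' filtering give the edited columns; third-position columns ancestrally `C`
#' are found by parsimony root reconstruction. For each class the per-lineage
#' change fraction `p` (tip reads `T` where the ancestor had `C`, averaged
#' over sites x tips) is turned into a cumulative hazard `-log(1 - p)`; the
#' ratio of hazards estimates the rate ratio. A site-level Fisher exact test
#' (site changed in at least one tip, edited vs third class) accompanies the
#' estimate; sites are independent, so under equal rates its type-I error is
#' nominal.
#'
#' @param dna genomic [codon_alignment()].
#' @param cdna cDNA [codon_alignment()].
#' @param tree rooted `ape::phylo` over the DNA taxa.
#' @return One-row tibble: `ratio`, `p_es`, `p_third`, `n_es`, `n_third`,
#'   `fisher_p`.
#' @export
estimate_ct_ratio <- function(dna, cdna, tree) {
  et <- filter_heterogeneous(call_edited_sites(dna, cdna))
  m <- build_character_matrix(et, dna)
  m <- m[tree$tip.label, , drop = FALSE]
  anc <- reconstruct_ancestral_sequences(tree, dna, method = "parsimony")
  root_lab <- node_labels(tree)[root_node(tree)]
  ed_pos <- as.integer(colnames(m))
  third <- which(anc$codon_position == 3L & !anc$masked &
                   !(seq_along(anc$masked) %in% ed_pos))
  third <- third[anc$states[root_lab, third] == "C"]
  tm <- dna[tree$tip.label, third, drop = FALSE]
  keep3 <- tm %in% c("C", "T")
  p_es <- mean(m == "0", na.rm = TRUE)
  p_th <- if (length(third) > 0) mean(tm[keep3] == "T") else NA_real_
  ratio <- if (!is.na(p_th) && p_th > 0 && p_es < 1 && p_th < 1)
    log(1 - p_es) / log(1 - p_th) else NA_real_
  a <- sum(apply(m == "0", 2L, any, na.rm = TRUE))
  b <- ncol(m) - a
  cc <- if (length(third) > 0)
    sum(apply(tm == "T", 2L, function(z) any(z, na.rm = TRUE))) else 0L
  d <- length(third) - cc
  fp <- fisher_exact_2x2(a, b, cc, d)
  tibble::tibble(ratio = ratio, p_es = p_es, p_third = p_th,
                 n_es = ncol(m), n_third = length(third), fisher_p = fp)
}

# study-shaped single-gene parameters used by the recovery harness:
# n_es edited sites (codon positions 1/2) and n_third third-position Cs in
# the root sequence, equal baseline rates across codon positions
harness_gene <- function(n_es = 40L, n_third = 200L, lambda_es = 1,
                         depth = 0.1, n_taxa = 30L) {
  n_codons <- n_es + n_third
  root_seq <- character(0)
  for (i in seq_len(n_es))
    root_seq <- c(root_seq, if (i %% 2L == 0L) c("C", "A", "T")
                  else c("A", "C", "A"))
  root_seq <- c(root_seq, rep(c("G", "G", "C"), n_third))
  edited <- vapply(seq_len(n_es), function(i)
    3L * (i - 1L) + (if (i %% 2L == 0L) 1L else 2L), integer(1))
  params <- sim_params(
    n_taxa = n_taxa, root_age = 100,
    genes = tibble::tibble(gene = "simgene", n_codons = n_codons,
                           n_edited = n_es),
    subst_scale = depth, rel_rates = c(1, 1, 1), lambda_es = lambda_es)
  list(params = params, root_seq = root_seq, edited = edited)
}

#' Recovery of the edited-site / third-position rate ratio
#'
#' Simulates replicate data sets at given true rate ratios and re-estimates
#' the ratio with [estimate_ct_ratio()]; under ratio 1 the Fisher rejection
#' rate estimates the test's type-I error.
#'
#' @param ratios true `lambda_ES / lambda_3rd` values.
#' @param n_rep replicates per ratio.
#' @param n_taxa,n_es,n_third,depth study-shape settings: tips, edited
#'   sites, third-position Cs, root-to-tip expected substitutions per site.
#' @param alpha significance level for the rejection-rate column.
#' @return Tibble per ratio: `true_ratio`, `median_ratio`, `rel_error`
#'   (of the median), `rejection_rate`, `n_rep`.
#' @export
harness_ratio_recovery <- function(ratios = c(1, 3, 5, 10), n_rep = 200L,
                                   n_taxa = 30L, n_es = 40L, n_third = 200L,
                                   depth = 0.1, alpha = 0.05) {
  purrr::map_dfr(ratios, function(rt) {
    est <- numeric(n_rep)
    rej <- logical(n_rep)
    for (i in seq_len(n_rep)) {
      hg <- harness_gene(n_es, n_third, lambda_es = rt, depth = depth,
                         n_taxa = n_taxa)
      tree <- simulate_tree(n_taxa, root_age = 100)
      sim <- simulate_sequences(tree, hg$params, root_seq = hg$root_seq,
                                edited_positions = hg$edited)
      r <- estimate_ct_ratio(sim$dna, sim$cdna, tree)
      est[i] <- r$ratio
      rej[i] <- !is.na(r$fisher_p) && r$fisher_p < alpha
    }
    med <- median(est, na.rm = TRUE)
    tibble::tibble(true_ratio = rt, median_ratio = med,
                   rel_error = abs(med - rt) / rt,
                   rejection_rate = mean(rej), n_rep = n_rep)
  })
}

#' Node-age recovery of NPRS dating under smoothly varying rates
#'
#' Simulates dated Yule trees, evolves branch rates as an autocorrelated
#' lognormal random walk (child rate = parent rate times
#' `exp(N(-sigma^2/2, sigma))`), converts durations to branch lengths, and
#' re-dates with [nprs_date()]. Reports the median relative node-age error.
#'
#' @param n_rep replicates.
#' @param n_taxa tips per tree.
#' @param sigma per-branch log-rate standard deviation.
#' @param root_age true root age.
#' @param restarts restarts passed to [nprs_date()].
#' @return Tibble: `median_rel_error`, `n_rep`, plus per-replicate errors in
#'   the `errors` list-column.
#' @export
harness_dating <- function(n_rep = 50L, n_taxa = 20L, sigma = 0.15,
                           root_age = 100, restarts = 5L) {
  errs <- purrr::map(seq_len(n_rep), function(i) {
    tree <- simulate_tree(n_taxa, root_age = root_age)
    n_tip <- length(tree$tip.label)
    root <- root_node(tree)
    par <- parent_vec(tree)
    rate <- rep(NA_real_, n_tip + tree$Nnode)
    rate[root] <- 1
    eidx <- edge_index_by_child(tree)
    bl <- tree$edge.length
    for (v in rev(postorder_nodes(tree))) {
      if (v == root) next
      rate[v] <- rate[par[v]] * exp(rnorm(1, -sigma^2 / 2, sigma))
      bl[eidx[v]] <- tree$edge.length[eidx[v]] * rate[v]
    }
    true_ages <- root_age - ape::node.depth.edgelength(tree)
    rt <- tree
    rt$edge.length <- bl
    dt <- nprs_date(rt, root_age = root_age, restarts = restarts)
    internal <- setdiff((n_tip + 1):(n_tip + tree$Nnode), root)
    abs(dt$ages[internal] - true_ages[internal]) /
      pmax(true_ages[internal], 1e-9)
  })
  tibble::tibble(median_rel_error = median(unlist(errs)),
                 n_rep = n_rep, errors = list(errs))
}

#' Recovery of a trait correlation through independent contrasts
#'
#' Simulates two correlated Brownian traits on dated Yule trees, computes
#' PIC contrasts and the correlation through the origin, and reports the
#' median absolute error of the recovered correlation, together with
#' moment checks of the standardised contrasts.
#'
#' @param n_rep replicates.
#' @param n_taxa tips.
#' @param rho generating trait correlation.
#' @param root_age root age of the simulated chronograms.
#' @return Tibble: `median_abs_error`, `mean_contrast`, `var_contrast`
#'   (pooled first-trait contrasts under unit-variance Brownian motion),
#'   `n_rep`, with per-replicate estimates in `r_hat`.
#' @export
harness_pic <- function(n_rep = 500L, n_taxa = 30L, rho = 0.5,
                        root_age = 100) {
  r_hat <- numeric(n_rep)
  pooled <- list()
  for (i in seq_len(n_rep)) {
    tree <- simulate_tree(n_taxa, root_age = root_age)
    xy <- sim_brownian_pair(tree, rho, sigma = 1 / sqrt(root_age))
    cs <- pic_contrasts(tree, xy$x, xy$y)
    fit <- regression_through_origin(cs)
    r_hat[i] <- fit$r
    pooled[[i]] <- cs$delta_x * sqrt(root_age)  # rescale to unit variance
  }
  z <- unlist(pooled)
  tibble::tibble(median_abs_error = median(abs(r_hat - rho)),
                 mean_contrast = mean(z), var_contrast = var(z),
                 n_rep = n_rep, r_hat = list(r_hat),
                 contrasts = list(z))
}

# two correlated Brownian traits on a chronogram; sigma = per-sqrt(Ma) sd
sim_brownian_pair <- function(tree, rho, sigma = 1) {
  n_tip <- length(tree$tip.label)
  n_node <- n_tip + tree$Nnode
  root <- root_node(tree)
  par <- parent_vec(tree)
  eidx <- edge_index_by_child(tree)
  x <- numeric(n_node)
  y <- numeric(n_node)
  for (v in rev(postorder_nodes(tree))) {
    if (v == root) next
    s <- sigma * sqrt(tree$edge.length[eidx[v]])
    e1 <- rnorm(1, 0, s)
    e2 <- rho * e1 + sqrt(1 - rho^2) * rnorm(1, 0, s)
    x[v] <- x[par[v]] + e1
    y[v] <- y[par[v]] + e2
  }
  list(x = setNames(x[seq_len(n_tip)], tree$tip.label),
       y = setNames(y[seq_len(n_tip)], tree$tip.label))
}

#' Operating characteristics of the retroprocessing scan
#'
#' `harness_retro_null()` draws branch loss sets uniformly from the at-risk
#' positions (the scan's null) and reports the branch-level rejection rate.
#' `harness_retro_sensitivity()` simulates whole-gene conversion events on a
#' random internal branch, runs edit calling and DELTRAN mapping, scans, and
#' reports the fraction of replicates where the scan flags the true branch
#' as a whole-gene candidate.
#'
#' @param n_rep replicates.
#' @param n_losses losses per null branch.
#' @param n_sites number of at-risk edited-site positions.
#' @param gene_nt gene length in nt over which positions are spread.
#' @param n_perm permutations per scan.
#' @param alpha significance level.
#' @return `harness_retro_null()`: tibble `fpr`, `n_rep`.
#' @export
harness_retro_null <- function(n_rep = 500L, n_losses = 8L, n_sites = 25L,
                               gene_nt = 600L, n_perm = 300L, alpha = 0.05) {
  hits <- logical(n_rep)
  for (i in seq_len(n_rep)) {
    risk <- sort(sample.int(gene_nt, n_sites))
    pos <- sort(sample(risk, n_losses))
    sc <- retro_scan(tibble::tibble(branch_id = "b", position = pos),
                     risk, n_perm = n_perm, alpha = alpha)
    hits[i] <- !sc$whole_gene[1L] && !is.na(sc$branch_p[1L]) &&
      sc$branch_p[1L] < alpha
  }
  tibble::tibble(fpr = mean(hits), n_rep = n_rep)
}

#' @rdname harness_retro_null
#' @param n_taxa tips in the sensitivity simulations.
#' @param n_es edited sites per gene.
#' @details The sensitivity simulations use a conversion-only grid: edited
#'   sites are frozen against background substitution (`es_rate_mult = 0`)
#'   so that every change at an edited site stems from the planted
#'   conversion event, isolating the detector's behaviour on the signal it
#'   targets. Specificity under background-only dynamics is measured by
#'   `harness_retro_null()`.
#' @return `harness_retro_sensitivity()`: tibble `sensitivity`, `n_rep`.
#' @export
harness_retro_sensitivity <- function(n_rep = 500L, n_taxa = 20L,
                                      n_es = 25L, alpha = 0.05) {
  hit <- logical(n_rep)
  for (i in seq_len(n_rep)) {
    tree <- simulate_tree(n_taxa, root_age = 100)
    ids <- branch_ids(tree)
    internal <- which(tree$edge[, 2L] > length(tree$tip.label))
    b <- ids[sample(internal, 1L)]
    params <- sim_params(
      n_taxa = n_taxa, root_age = 100,
      genes = tibble::tibble(gene = "g", n_codons = 100L, n_edited = n_es),
      subst_scale = 0.05, lambda_es = 0, es_rate_mult = 0,
      conversions = list(list(gene = "g", branch = b, window = NULL,
                              completeness = 1)))
    sim <- simulate_sequences(tree, params, gene = "g")
    et <- filter_heterogeneous(call_edited_sites(sim$dna, sim$cdna))
    m <- build_character_matrix(et, sim$dna)
    if (ncol(m) == 0) next
    hist <- map_editing(tree, m, mode = "deltran")
    loss <- dplyr::filter(hist$events, .data$event == "loss")
    loss$position <- as.integer(colnames(m))[loss$character]
    # at-risk positions per branch: sites edited in the branch's parent node
    par <- parent_vec(tree)
    labs <- node_labels(tree)
    risk <- purrr::map_dfr(unique(loss$branch_id), function(bid) {
      v <- node_by_label(tree, bid)
      anc_states <- hist$node_states[labs[par[v]], ]
      tibble::tibble(branch_id = bid,
                     position = as.integer(colnames(m))[anc_states == "1"])
    })
    sc <- retro_scan(loss, risk, n_perm = 100L, alpha = alpha)
    hit[i] <- b %in% sc$branch_id[sc$whole_gene]
  }
  tibble::tibble(sensitivity = mean(hit), n_rep = n_rep)
}

#' Full recovery report
#'
#' Runs all simulation-based operating-characteristic harnesses at reduced
#' or full sizes and binds their headline numbers into one report.
#'
#' @param n_rep_ratio,n_rep_dating,n_rep_pic,n_rep_retro replicate counts.
#' @param seed random seed applied before each block.
#' @return Tibble with `metric` and `value` rows.
#' @export
recovery_harness <- function(n_rep_ratio = 200L, n_rep_dating = 50L,
                             n_rep_pic = 500L, n_rep_retro = 500L,
                             seed = 1L) {
  set.seed(seed)
  rr <- harness_ratio_recovery(n_rep = n_rep_ratio)
  set.seed(seed + 1L)
  dt <- harness_dating(n_rep = n_rep_dating)
  set.seed(seed + 2L)
  pc <- harness_pic(n_rep = n_rep_pic)
  set.seed(seed + 3L)
  rn <- harness_retro_null(n_rep = n_rep_retro)
  set.seed(seed + 4L)
  rs <- harness_retro_sensitivity(n_rep = n_rep_retro)
  dplyr::bind_rows(
    tibble::tibble(metric = paste0("ratio_median_", rr$true_ratio),
                   value = rr$median_ratio),
    tibble::tibble(metric = "fisher_type1", value = rr$rejection_rate[1L]),
    tibble::tibble(metric = "dating_median_rel_error",
                   value = dt$median_rel_error),
    tibble::tibble(metric = "pic_median_abs_error",
                   value = pc$median_abs_error),
    tibble::tibble(metric = "retro_null_fpr", value = rn$fpr),
    tibble::tibble(metric = "retro_sensitivity", value = rs$sensitivity))
}
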