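test_that("ancestral reconstruction handles identity and ambiguity", {
  tr <- ape::read.tree(text = "((A:1,B:1):1,C:1);")
  aln <- aln_from_strings(c(A = "TTC", B = "TTC", C = "TTC"))
  anc <- reconstruct_ancestral_sequences(tr, aln)
  expect_true(all(anc$states[, 3] == "C"))

  # A=B=TTC, C=TTT: both root states are most parsimonious at position 3
  aln2 <- aln_from_strings(c(A = "TTC", B = "TTC", C = "TTT"))
  anc2 <- reconstruct_ancestral_sequences(tr, aln2)
  orc <- oracle_fitch(tr, c(A = "C", B = "C", C = "T"))
  expect_equal(orc$length, 1)
  root_states <- unique(vapply(orc$assignments, function(st)
    st[root_node(tr)], character(1)))
  expect_setequal(root_states, c("C", "T"))  # genuinely ambiguous
  # DELTRAN resolution still implies exactly one change
  labs <- node_labels(tr)
  n_changes <- sum(anc2$states[labs[tr$edge[, 1]], 3] !=
                     anc2$states[labs[tr$edge[, 2]], 3])
  expect_equal(n_changes, 1)

  # gapped columns are masked at internal nodes
  aln3 <- aln_from_strings(c(A = "T-C", B = "TTC", C = "TTC"))
  anc3 <- reconstruct_ancestral_sequences(tr, aln3)
  expect_true(anc3$masked[2])
  expect_true(is.na(anc3$states["N1", 2]))
})

test_that("low-divergence simulation: ancestral states mostly recovered", {
  set.seed(401)
  ok <- 0; tot <- 0
  for (rep in 1:3) {
    tr <- simulate_tree(6, root_age = 100)
    p <- sim_params(n_taxa = 6,
                    genes = tibble::tibble(gene = "g", n_codons = 120L,
                                           n_edited = 0L),
                    subst_scale = 0.05)
    sim <- simulate_sequences(tr, p, gene = "g")
    anc <- reconstruct_ancestral_sequences(tr, sim$dna)
    internal <- setdiff(rownames(anc$states), tr$tip.label)
    est <- anc$states[internal, , drop = FALSE]
    tru <- sim$truth$node_seqs[internal, , drop = FALSE]
    ok <- ok + sum(est == tru, na.rm = TRUE)
    tot <- tot + sum(!is.na(est))
  }
  expect_gte(ok / tot, 0.95)
})

test_that("ML ancestral reconstruction recovers true states at low
           divergence", {
  skip_if_not_installed("phangorn")
  set.seed(402)
  tr <- simulate_tree(6, root_age = 100)
  p <- sim_params(n_taxa = 6,
                  genes = tibble::tibble(gene = "g", n_codons = 60L,
                                         n_edited = 0L),
                  subst_scale = 0.04)
  sim <- simulate_sequences(tr, p, gene = "g")
  ml <- reconstruct_ancestral_sequences(tr, sim$dna, "ML")
  internal <- setdiff(rownames(ml$states), tr$tip.label)
  acc <- mean(ml$states[internal, ] ==
                sim$truth$node_seqs[internal, ], na.rm = TRUE)
  expect_gte(acc, 0.95)
})

test_that("branch_ds counts synonymous divergence Nei-Gojobori style", {
  # identical sequences
  expect_equal(branch_ds("TTCTTC", "TTCTTC")$ds, 0)

  # purely nonsynonymous difference: dS stays 0
  r <- branch_ds("TTC", "TGC")  # Phe -> Cys, position 2
  expect_equal(r$syn_count, 0)
  expect_equal(r$nonsyn_count, 1)
  expect_equal(r$ds, 0)

  # 100 TTC codons, one third-position synonymous difference:
  # each TTC/TTT codon has 1/3 synonymous site at position 3 and none
  # elsewhere, so S = 100/3 and p_s = 3/100
  anc <- strrep("TTC", 100)
  des <- paste0(strrep("TTC", 99), "TTT")
  r2 <- branch_ds(anc, des)
  expect_equal(r2$S, 100 / 3, tolerance = 1e-12)
  expect_equal(r2$ps, 1 / (100 / 3), tolerance = 1e-12)
  expect_equal(r2$ds, -0.75 * log(1 - 4 * r2$ps / 3), tolerance = 1e-12)
  expect_equal(r2$ct3_positions[[1]], 300L)

  # symmetry
  f <- branch_ds("GGAGGAGGAGGAGGAGGA", "GGGGGAGGAGGAGGAGGC")
  b <- branch_ds("GGGGGAGGAGGAGGAGGC", "GGAGGAGGAGGAGGAGGA")
  expect_equal(f$ds, b$ds)
  expect_equal(f$syn_count, b$syn_count)

  # ambiguous codons are skipped
  r3 <- branch_ds("TT-TTC", "TTCTTC")
  expect_equal(r3$codons_used, 1L)
})

test_that("dS is near-additive and approximately unbiased at low
           divergence", {
  set.seed(403)
  # additivity over a 3-node chain simulated at low divergence
  chain <- ape::read.tree(text = "(A:1,(B:1,C:1):1);")
  p <- sim_params(n_taxa = 3,
                  genes = tibble::tibble(gene = "g", n_codons = 400L,
                                         n_edited = 0L),
                  subst_scale = 0.03)
  for (rep in 1:5) {
    tr <- simulate_tree(4, root_age = 100)
    sim <- simulate_sequences(
      tr, sim_params(n_taxa = 4,
                     genes = tibble::tibble(gene = "g", n_codons = 400L,
                                            n_edited = 0L),
                     subst_scale = 0.03), gene = "g")
    labs <- rownames(sim$truth$node_seqs)
    root_lab <- node_labels(tr)[root_node(tr)]
    for (tip in tr$tip.label[1:2]) {
      par <- parent_vec(tr)
      v <- node_by_label(tr, tip)
      mid <- labs[par[v]]
      d_ac <- branch_ds(sim$truth$node_seqs[root_lab, ],
                        sim$truth$node_seqs[tip, ])$ds
      d_ab <- branch_ds(sim$truth$node_seqs[root_lab, ],
                        sim$truth$node_seqs[mid, ])$ds
      d_bc <- branch_ds(sim$truth$node_seqs[mid, ],
                        sim$truth$node_seqs[tip, ])$ds
      expect_lt(abs(d_ac - d_ab - d_bc), 0.005)
    }
  }
})

test_that("relative rate test follows the exact binomial", {
  # A identical to B
  aln <- aln_from_strings(c(A = "TTCGGA", B = "TTCGGA", O = "TTTGGG"))
  expect_warning(r_same <- relative_rate_test(aln, "A", "B", "O"))
  expect_equal(r_same$p_value, 1)

  # m_A = 10, m_B = 0 at third positions
  a <- strrep("GGA", 10)
  b <- strrep("GGC", 10)
  o <- strrep("GGC", 10)
  aln2 <- aln_from_strings(c(A = a, B = b, O = o))
  r <- relative_rate_test(aln2, "A", "B", "O")
  expect_equal(r$m_a, 10)
  expect_equal(r$m_b, 0)
  expect_equal(r$p_value, 2 * 0.5^10, tolerance = 1e-12)

  # no informative sites: warning and p = 1
  same <- aln_from_strings(c(A = "GGA", B = "GGA", O = "GGA"))
  expect_warning(r0 <- relative_rate_test(same, "A", "B", "O"))
  expect_equal(r0$p_value, 1)
})

test_that("relative rate test holds its size on clock-like data", {
  set.seed(404)
  n_rep <- 120
  rej <- logical(n_rep)
  pvals <- numeric(n_rep)
  for (i in seq_len(n_rep)) {
    tr <- ape::read.tree(text = "((A:40,B:40):40,O:80);")
    p <- sim_params(n_taxa = 3,
                    genes = tibble::tibble(gene = "g", n_codons = 250L,
                                           n_edited = 0L),
                    subst_scale = 0.15)
    sim <- simulate_sequences(tr, p, gene = "g")
    r <- suppressWarnings(relative_rate_test(sim$dna, "A", "B", "O"))
    rej[i] <- r$p_value < 0.05
    pvals[i] <- r$p_value
  }
  # binomial 99% envelope around 0.05 at 120 replicates (exact test is
  # conservative, so the lower edge is 0)
  expect_lte(mean(rej), 0.05 + 2.58 * sqrt(0.05 * 0.95 / n_rep))
  # p-values roughly uniform (coarse KS sanity check; discrete p-values
  # make the test conservative)
  ks <- suppressWarnings(stats::ks.test(pvals, "punif"))
  expect_gt(ks$p.value, 1e-4)
})

test_that("third-position C-to-T events are extracted per branch and are
           synonymous", {
  tr <- ape::read.tree(text = "((A:1,B:1):1,C:1);")
  # one third-position C->T on the terminal branch to A
  aln <- aln_from_strings(c(A = "TTT", B = "TTC", C = "TTC"))
  anc <- reconstruct_ancestral_sequences(tr, aln)
  ev <- third_position_ct_events(anc)
  expect_equal(nrow(ev), 1L)
  expect_equal(ev$branch_id, "A")
  expect_equal(ev$position, 3L)

  # the reverse direction (T->C) is a gain, not counted here
  aln2 <- aln_from_strings(c(A = "TTC", B = "TTT", C = "TTT"))
  anc2 <- reconstruct_ancestral_sequences(tr, aln2)
  ev2 <- third_position_ct_events(anc2)
  expect_equal(nrow(ev2), 0L)

  # excluded edited columns never appear
  ev3 <- third_position_ct_events(anc, exclude_positions = 3L)
  expect_equal(nrow(ev3), 0L)

  # every event is ancestor C -> descendant T at a third position, hence
  # synonymous under the standard code
  set.seed(405)
  tr4 <- simulate_tree(8, root_age = 100)
  sim <- simulate_sequences(
    tr4, sim_params(n_taxa = 8,
                    genes = tibble::tibble(gene = "g", n_codons = 100L,
                                           n_edited = 0L),
                    subst_scale = 0.1), gene = "g")
  anc4 <- reconstruct_ancestral_sequences(tr4, sim$dna)
  ev4 <- third_position_ct_events(anc4)
  labs <- node_labels(tr4)
  par <- parent_vec(tr4)
  for (j in seq_len(nrow(ev4))) {
    v <- node_by_label(tr4, ev4$branch_id[j])
    pos <- ev4$position[j]
    expect_equal(unname(anc4$states[labs[par[v]], pos]), "C")
    expect_equal(unname(anc4$states[v, pos]), "T")
    expect_equal(codon_position(pos, 0L), 3L)
    anc_codon <- anc4$states[labs[par[v]], (pos - 2):pos]
    des_codon <- c(anc_codon[1:2], "T")
    expect_identical(translate_codon(paste0(anc_codon, collapse = "")),
                     translate_codon(paste0(des_codon, collapse = "")))
  }

  # events match the simulator's logged C->T third-position substitutions
  truth <- dplyr::filter(sim$truth$mutation_log, from == "C", to == "T",
                         codon_position(position, 0L) == 3L)
  # compare on branches where reconstruction is certain: every truth event
  # should be recovered somewhere, net of multiple hits
  got_keys <- paste(ev4$branch_id, ev4$position)
  true_keys <- paste(truth$branch_id, truth$position)
  expect_gte(mean(true_keys %in% got_keys), 0.85)
})

test_that("fractional mode spreads ambiguous events without changing the
           total by much", {
  tr <- ape::read.tree(text = "((A:1,B:1):1,C:1);")
  aln <- aln_from_strings(c(A = "TTC", B = "TTT", C = "TTC"))
  anc <- reconstruct_ancestral_sequences(tr, aln)
  res <- third_position_ct_events(anc, mode = "resolved")
  fr <- third_position_ct_events(anc, mode = "fractional")
  expect_equal(sum(res$weight), 1)
  expect_equal(sum(fr$weight), 1, tolerance = 1e-12)
  expect_true(all(fr$weight > 0 & fr$weight <= 1))
})
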