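test_that("Fisher exact p matches hypergeometric enumeration exactly", {
  expect_equal(fisher_exact_2x2(5, 5, 5, 5), 1.0)
  expect_equal(fisher_exact_2x2(10, 0, 0, 10), oracle_fisher(10, 0, 0, 10),
               tolerance = 1e-12)
  expect_equal(fisher_exact_2x2(10, 0, 0, 10), 1.082509e-5,
               tolerance = 1e-4)
  expect_equal(fisher_exact_2x2(0, 0, 0, 0), 1)

  set.seed(601)
  for (i in 1:100) {
    tab <- as.integer(sample(0:15, 4, replace = TRUE))
    got <- fisher_exact_2x2(tab[1], tab[2], tab[3], tab[4])
    expect_equal(got, oracle_fisher(tab[1], tab[2], tab[3], tab[4]),
                 tolerance = 1e-12)
    # cross-check against the reference implementation
    expect_equal(got,
                 stats::fisher.test(matrix(tab, 2, byrow = TRUE))$p.value,
                 tolerance = 1e-9)
  }
})

test_that("node-to-tip averaging follows the daughter-mean recursion", {
  tr <- ape::read.tree(text = "((A:1,B:1):1,C:1);")
  ids <- branch_ids(tr)
  # tip branch value is its own value
  vals <- setNames(c(2, 4, 1, 7), c("A", "B", "N1", "C"))
  out <- node_to_tip_value(tr, vals[ids])
  expect_equal(unname(out[node_by_label(tr, "A")]), 2)
  # internal: own branch + mean of daughters: 1 + (2+4)/2 = 4
  expect_equal(unname(out[node_by_label(tr, "N1")]), 4)
  # root: mean of daughters (no subtending branch)
  expect_equal(unname(out[root_node(tr)]), (4 + 7) / 2)

  # hand-worked nested six-tip example
  tr6 <- ape::read.tree(
    text = "(((a:1,b:1):1,(c:1,d:1):1):1,(e:1,f:1):1);")
  ids6 <- branch_ids(tr6)
  v6 <- setNames(seq_along(ids6), ids6)
  out6 <- node_to_tip_value(tr6, v6)
  hand <- function(lab) {
    v <- node_by_label(tr6, lab)
    kids <- which(tr6$edge[, 1] == v)
    own <- if (v == root_node(tr6)) 0 else unname(v6[lab])
    if (length(kids) == 0) return(own)
    own + mean(vapply(node_labels(tr6)[tr6$edge[kids, 2]], hand,
                      numeric(1)))
  }
  for (lab in node_labels(tr6))
    expect_equal(unname(out6[node_by_label(tr6, lab)]), hand(lab))
})

test_that("sister contrasts orient x non-negative and skip polytomies", {
  tr <- ape::read.tree(text = "(A:1,B:1);")
  x <- setNames(c(1, 3), c("A", "B"))
  y <- setNames(c(0, 4), c("A", "B"))
  cs <- sister_contrasts(tr, x, y)
  expect_equal(nrow(cs), 1L)
  expect_equal(cs$delta_x, 2)
  expect_equal(cs$delta_y, 4)

  # identical daughters give the zero contrast
  cs0 <- sister_contrasts(tr, setNames(c(2, 2), c("A", "B")),
                          setNames(c(5, 5), c("A", "B")))
  expect_equal(cs0$delta_x, 0)
  expect_equal(cs0$delta_y, 0)

  # number of contrasts equals number of binary internal nodes
  set.seed(602)
  for (i in 1:10) {
    tr2 <- random_tree(7)
    tr2 <- ape::di2multi({
      t2 <- tr2
      internal <- which(t2$edge[, 2] > 7)
      t2$edge.length[sample(internal, 1)] <- 0
      t2
    })
    ids <- branch_ids(tr2)
    xs <- setNames(runif(length(ids)), ids)
    ys <- setNames(runif(length(ids)), ids)
    cs2 <- sister_contrasts(tr2, xs, ys)
    kids <- table(tr2$edge[, 1])
    expect_equal(nrow(cs2), sum(kids == 2))
    expect_true(all(cs2$delta_x >= 0))
  }
})

test_that("regression through the origin matches the closed formulas", {
  x <- c(1, 2, 3, 4)
  fit <- regression_through_origin(x, 2 * x)
  expect_equal(fit$slope, 2)
  expect_equal(fit$r, 1)

  # orthogonal construction: r = 0
  x2 <- c(1, -1, 1, -1)
  y2 <- c(1, 1, -1, -1)
  expect_equal(regression_through_origin(x2, y2)$r, 0)

  set.seed(603)
  for (i in 1:50) {
    n <- sample(4:30, 1)
    xs <- rnorm(n); ys <- rnorm(n)
    fit <- regression_through_origin(xs, ys)
    expect_equal(fit$slope, sum(xs * ys) / sum(xs^2), tolerance = 1e-12)
    r <- sum(xs * ys) / sqrt(sum(xs^2) * sum(ys^2))
    expect_equal(fit$r, r, tolerance = 1e-12)
    tstat <- r * sqrt((n - 1) / (1 - r^2))
    expect_equal(fit$p_value, 2 * pt(-abs(tstat), n - 1),
                 tolerance = 1e-12)
  }
  expect_error(regression_through_origin(c(1, 2), c(1, 2)), "at least 3")
  expect_error(regression_through_origin(rep(0, 5), rnorm(5)), "undefined")

  # invariance under relabeling of sister pairs and x rescaling
  set.seed(604)
  xs <- abs(rnorm(10)); ys <- rnorm(10)
  base <- regression_through_origin(xs, ys)$r
  flip <- sample(c(-1, 1), 10, replace = TRUE)
  expect_equal(regression_through_origin(xs * flip, ys * flip)$r, base)
  expect_equal(regression_through_origin(xs * 3.7, ys)$r, base)
})

test_that("PIC contrasts standardise by branch duration", {
  # two tips, durations 4 and 4: contrast (3-7)/sqrt(8)
  tr <- ape::read.tree(text = "(A:4,B:4);")
  cs <- pic_contrasts(tr, c(A = 3, B = 7))
  expect_equal(abs(cs$delta_x), abs(3 - 7) / sqrt(8))

  # constant tip values give all-zero contrasts
  tr2 <- ape::read.tree(text = "((A:1,B:1):1,(C:1,D:1):1);")
  cs2 <- pic_contrasts(tr2, c(A = 2, B = 2, C = 2, D = 2))
  expect_true(all(cs2$delta_x == 0))

  # star phylogeny: contrasts reduce to scaled pairwise differences
  star <- ape::read.tree(text = "(A:2,B:2,C:2);")
  vals <- c(A = 1, B = 5, C = 9)
  cs3 <- pic_contrasts(star, vals)
  expect_equal(nrow(cs3), 2L)
  # the first contrast (between two zero-length-joined tips) is the pair
  # difference over sqrt(2v)
  expect_true(any(abs(abs(cs3$delta_x) - abs(1 - 5) / sqrt(4)) < 1e-9 |
                    abs(abs(cs3$delta_x) - abs(5 - 9) / sqrt(4)) < 1e-9 |
                    abs(abs(cs3$delta_x) - abs(1 - 9) / sqrt(4)) < 1e-9))
})

test_that("Brownian simulations: PIC recovers the generating correlation", {
  set.seed(605)
  hp <- harness_pic(n_rep = 60, n_taxa = 30, rho = 0.5)
  expect_lt(hp$median_abs_error, 0.15)
  expect_lt(abs(hp$mean_contrast), 0.1)
  expect_lt(abs(hp$var_contrast - 1), 0.2)
})

test_that("zero-edit clades prune to a single representative", {
  tr <- ape::read.tree(
    text = "(((z1:1,(z2:2,z3:3):1):1,e1:1):1,(e2:1,z4:1):1);")
  counts <- c(z1 = 0, z2 = 0, z3 = 0, z4 = 0, e1 = 2, e2 = 1)
  keep_long <- prune_zero_edit(tr, counts, keep = "longest")
  expect_true("z3" %in% keep_long$tip.label)
  expect_false(any(c("z1", "z2") %in% keep_long$tip.label))
  expect_true(all(c("e1", "e2", "z4") %in% keep_long$tip.label))

  keep_short <- prune_zero_edit(tr, counts, keep = "shortest")
  expect_true("z1" %in% keep_short$tip.label)
  expect_false(any(c("z2", "z3") %in% keep_short$tip.label))

  # never removes a tip with a nonzero count; identity without zero tips
  all_pos <- setNames(rep(1, 6), names(counts))
  expect_identical(prune_zero_edit(tr, all_pos), tr)
})

test_that("rate summary reproduces definitional anchors", {
  set.seed(606)
  tr <- simulate_tree(8, root_age = 100)
  b_all <- branch_ids(tr)
  internal <- which(tr$edge[, 2] > 8)
  conv_b <- b_all[internal[which.max(
    vapply(tr$edge[internal, 2], function(v)
      length(tips_below(tr)[[v]]), numeric(1)))]]
  p <- sim_params(n_taxa = 8, root_age = 100,
                  genes = tibble::tibble(gene = "g", n_codons = 80L,
                                         n_edited = 20L),
                  subst_scale = 0.05, lambda_es = 0, es_rate_mult = 0,
                  conversions = list(list(gene = "g", branch = conv_b,
                                          window = NULL, completeness = 1)))
  sim <- simulate_sequences(tr, p, gene = "g")
  et <- filter_heterogeneous(call_edited_sites(sim$dna, sim$cdna))
  m <- build_character_matrix(et, sim$dna)
  h <- map_editing(tr, m)
  anc <- reconstruct_ancestral_sequences(tr, sim$dna)
  root_lab <- node_labels(tr)[root_node(tr)]
  rs <- rate_summary(h, anc, root_lab, gene = "g")
  conv_tips <- tr$tip.label[tips_below(tr)[[node_by_label(tr, conv_b)]]]
  # taxa below the conversion lost every ancestral edited site
  expect_true(all(rs$es_rate[rs$taxon %in% conv_tips] == 1))
  # rates bounded, totals positive
  expect_true(all(rs$es_rate >= 0 & rs$es_rate <= 1, na.rm = TRUE))
  expect_true(all(rs$third_rate >= 0 & rs$third_rate <= 1, na.rm = TRUE))
  # a taxon with no changes at either class: es_rate 0 and Fisher p 1
  quiet <- rs$taxon[rs$es_changed == 0 & rs$third_changed == 0]
  if (length(quiet) > 0)
    expect_true(all(rs$fisher_p[rs$taxon %in% quiet] == 1))
})

test_that("Fisher comparison of ES vs third positions holds its size under
           equal rates", {
  set.seed(607)
  n_rep <- 60
  rej <- logical(n_rep)
  for (i in seq_len(n_rep)) {
    hg <- editevol:::harness_gene(n_es = 30, n_third = 120, lambda_es = 1,
                                  depth = 0.1, n_taxa = 15)
    tr <- simulate_tree(15, root_age = 100)
    sim <- simulate_sequences(tr, hg$params, root_seq = hg$root_seq,
                              edited_positions = hg$edited)
    r <- estimate_ct_ratio(sim$dna, sim$cdna, tr)
    rej[i] <- r$fisher_p < 0.05
  }
  expect_lte(mean(rej), 0.05 + 2.58 * sqrt(0.05 * 0.95 / n_rep))
})
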