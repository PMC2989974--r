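test_that("Fitch lengths match definitional cases", {
  tr <- ape::read.tree(text = "((A:1,B:1):1,(C:1,D:1):1);")
  x <- matrix(c("1", "1", "0", "0"), 4, 1,
              dimnames = list(c("A", "B", "C", "D")))
  expect_equal(fitch_reconstruct(tr, x)$lengths, 1L)

  all1 <- matrix("1", 4, 1, dimnames = list(c("A", "B", "C", "D")))
  expect_equal(fitch_reconstruct(tr, all1, states = c("0", "1"))$lengths, 0L)

  expect_error(
    fitch_reconstruct(tr, matrix(NA_character_, 4, 1,
                                 dimnames = list(c("A", "B", "C", "D")))),
    "undefined-length")
})

test_that("Fitch equals exhaustive enumeration on random small trees", {
  set.seed(301)
  for (i in 1:60) {
    n <- sample(4:6, 1)
    tr <- random_tree(n)
    st <- sample(c("0", "1", NA), n, replace = TRUE,
                 prob = c(0.45, 0.45, 0.1))
    if (all(is.na(st))) st[1] <- "1"
    names(st) <- tr$tip.label
    orc <- oracle_fitch(tr, st)
    got <- fitch_reconstruct(tr, matrix(st, ncol = 1,
                                        dimnames = list(names(st))),
                             states = c("0", "1"))
    expect_equal(got$lengths, orc$length)
    expect_lte(got$lengths, n - 1)
  }
})

test_that("polytomies are handled and lengths stay exact", {
  set.seed(302)
  for (i in 1:20) {
    tr <- random_tree(6)
    # collapse one internal branch into a polytomy
    tr_poly <- ape::di2multi(
      {
        t2 <- tr
        internal <- which(t2$edge[, 2] > 6)
        if (length(internal) > 0)
          t2$edge.length[sample(internal, 1)] <- 0
        t2
      })
    st <- setNames(sample(c("0", "1"), 6, replace = TRUE), tr$tip.label)
    if (length(unique(st)) == 1) st[1] <- setdiff(c("0", "1"), st[1])
    orc <- oracle_fitch(tr_poly, st)
    got <- fitch_reconstruct(tr_poly,
                             matrix(st, ncol = 1,
                                    dimnames = list(names(st))),
                             states = c("0", "1"))
    expect_equal(got$lengths, orc$length)
  }
})

test_that("ACCTRAN and DELTRAN resolutions are most-parsimonious and differ
           as accelerated vs delayed change placement", {
  # outgroup 1; clade ((X:0, (Y:1, Z:0)), S:1): ambiguous history
  tr <- ape::read.tree(text = "(O:1,(S:1,(X:1,(Y:1,Z:1):1):1):1);")
  st <- c(O = "1", S = "1", X = "0", Y = "1", Z = "0")
  rec <- fitch_reconstruct(tr, matrix(st, ncol = 1,
                                      dimnames = list(names(st))),
                           states = c("0", "1"))
  orc <- oracle_fitch(tr, st)
  expect_equal(rec$lengths, orc$length)
  mpr_event_sets <- unique(lapply(orc$assignments, oracle_events,
                                  tree = tr))
  for (mode in c("deltran", "acctran")) {
    ev <- resolve_optimization(rec, mode = mode)
    expect_equal(nrow(ev), rec$lengths)
    key <- sort(paste(ev$branch_id, ev$from, ev$to, sep = ">"))
    expect_true(list(key) %in% mpr_event_sets)
  }
  # DELTRAN: two parallel losses on terminal branches; ACCTRAN: one loss
  # deeper plus a regain
  dl <- resolve_optimization(rec, mode = "deltran")
  expect_setequal(dl$branch_id[dl$event == "loss"], c("X", "Z"))
  ac <- resolve_optimization(rec, mode = "acctran")
  expect_true(any(ac$event == "gain"))
  expect_equal(nrow(ac), nrow(dl))
})

test_that("random characters: both resolutions are members of the MPR set", {
  set.seed(303)
  for (i in 1:40) {
    n <- sample(4:6, 1)
    tr <- random_tree(n)
    st <- setNames(sample(c("0", "1"), n, replace = TRUE), tr$tip.label)
    if (length(unique(st)) == 1) st[1] <- setdiff(c("0", "1"), st[1])
    orc <- oracle_fitch(tr, st)
    mpr_event_sets <- unique(lapply(orc$assignments, oracle_events,
                                    tree = tr))
    rec <- fitch_reconstruct(tr, matrix(st, ncol = 1,
                                        dimnames = list(names(st))),
                             states = c("0", "1"))
    for (mode in c("deltran", "acctran")) {
      ev <- resolve_optimization(rec, mode = mode)
      expect_equal(nrow(ev), orc$length)
      key <- sort(paste(ev$branch_id, ev$from, ev$to, sep = ">"))
      expect_true(list(key) %in% mpr_event_sets)
    }
  }
})

test_that("unambiguous characters resolve identically under both modes", {
  tr <- ape::read.tree(text = "((A:1,B:1):1,(C:1,D:1):1);")
  st <- c(A = "1", B = "1", C = "0", D = "0")
  rec <- fitch_reconstruct(tr, matrix(st, ncol = 1,
                                      dimnames = list(names(st))),
                           states = c("0", "1"))
  dl <- resolve_optimization(rec, "deltran")
  ac <- resolve_optimization(rec, "acctran")
  expect_equal(dl[1:4], ac[1:4])
})

test_that("branch change counts conserve total parsimony length", {
  set.seed(304)
  tr <- random_tree(8)
  m <- matrix(sample(c("0", "1"), 8 * 30, replace = TRUE), 8, 30,
              dimnames = list(tr$tip.label))
  rec <- fitch_reconstruct(tr, m, states = c("0", "1"))
  for (mode in c("deltran", "acctran")) {
    ev <- resolve_optimization(rec, mode)
    bc <- count_branch_changes(ev, tr)
    expect_equal(sum(bc$changes), sum(rec$lengths))
    expect_equal(sum(bc$gains) + sum(bc$losses), sum(bc$changes))
  }
  # empty matrix of events
  bc0 <- count_branch_changes(resolve_optimization(
    fitch_reconstruct(tr, matrix("1", 8, 2,
                                 dimnames = list(tr$tip.label)),
                      states = c("0", "1"))), tr)
  expect_true(all(bc0$changes == 0))
})

test_that("per-branch totals match the simulator's event log when the MPR is
           unique", {
  set.seed(305)
  checked <- 0L
  for (rep in 1:20) {
    tr <- simulate_tree(7, root_age = 100)
    p <- sim_params(n_taxa = 7,
                    genes = tibble::tibble(gene = "g", n_codons = 30L,
                                           n_edited = 8L),
                    subst_scale = 0.08, lambda_es = 4)
    sim <- simulate_sequences(tr, p, gene = "g")
    truth_log <- dplyr::filter(sim$truth$mutation_log,
                               position %in% sim$truth$edited_positions,
                               from == "C", to == "T")
    for (pos in unique(truth_log$position)) {
      st <- setNames(
        ifelse(sim$dna[tr$tip.label, pos] == "C", "1",
               ifelse(sim$dna[tr$tip.label, pos] == "T", "0", NA)),
        tr$tip.label)
      if (any(is.na(st)) || length(unique(st)) < 2) next
      orc <- oracle_fitch(tr, st)
      if (length(unique(lapply(orc$assignments, oracle_events,
                               tree = tr))) != 1) next
      # unique MPR; only compare when the true history is that MPR
      true_ev <- truth_log[truth_log$position == pos, ]
      other <- dplyr::filter(sim$truth$mutation_log,
                             position == pos,
                             !(from == "C" & to == "T"))
      if (nrow(other) > 0 || nrow(true_ev) != orc$length) next
      rec <- fitch_reconstruct(tr, matrix(st, ncol = 1,
                                          dimnames = list(names(st))),
                               states = c("0", "1"))
      ev <- resolve_optimization(rec, "deltran")
      expect_setequal(ev$branch_id[ev$event == "loss"], true_ev$branch_id)
      checked <- checked + 1L
    }
  }
  expect_gte(checked, 5L)
})

test_that("cumulative changes sum events along root-to-tip paths", {
  tr <- ape::read.tree(text = "(((A:1,B:1)X:1,C:1)Y:1,D:1)R;")
  ids <- branch_ids(tr)
  ev <- tibble::tibble(branch_id = ids,
                       gains = 0L,
                       losses = c(2L, 0L, 0L, 1L, 0L, 0L)[seq_along(ids)])
  ev$changes <- ev$gains + ev$losses
  root_lab <- node_labels(tr)[root_node(tr)]
  # direct path-walk oracle
  walk <- function(tip) {
    par <- tr$edge[, 1]
    labs <- node_labels(tr)
    v <- which(labs == tip)
    total <- 0
    repeat {
      e <- which(tr$edge[, 2] == v)
      if (length(e) == 0) break
      total <- total + ev$losses[ev$branch_id == labs[v]]
      v <- tr$edge[e, 1]
    }
    total
  }
  for (tip in tr$tip.label) {
    expect_equal(cumulative_changes(tr, ev, root_lab, tip), walk(tip))
  }
  # additivity over path concatenation
  mid <- setdiff(unique(node_labels(tr)[tr$edge[, 1]]), root_lab)[1]
  v_mid <- node_by_label(tr, mid)
  below <- tr$tip.label[tips_below(tr)[[v_mid]]]
  for (tip in below) {
    expect_equal(
      cumulative_changes(tr, ev, root_lab, tip),
      cumulative_changes(tr, ev, root_lab, v_mid) +
        cumulative_changes(tr, ev, mid, tip))
  }
  expect_error(cumulative_changes(tr, ev, "A", "D"), "lineage error")
})

test_that("parsimony statistics match the brute-force oracle", {
  tr <- ape::read.tree(text = "((A:1,B:1):1,(C:1,D:1):1);")
  x <- matrix(c("1", "1", "0", "0"), 4, 1,
              dimnames = list(c("A", "B", "C", "D")))
  ps <- parsimony_stats(tr, x)
  expect_equal(ps$CI, 1)
  expect_equal(ps$RI, 1)

  # invariant column contributes nothing to L
  x2 <- cbind(x, matrix("1", 4, 1))
  expect_equal(parsimony_stats(tr, x2)$L, 1)

  set.seed(306)
  for (i in 1:25) {
    n <- sample(5:6, 1)
    tr <- random_tree(n)
    m <- matrix(sample(c("0", "1"), n * 8, replace = TRUE), n, 8,
                dimnames = list(tr$tip.label))
    lens <- apply(m, 2, function(col)
      oracle_fitch(tr, setNames(col, rownames(m)))$length)
    tab <- apply(m, 2, table)
    mins <- apply(m, 2, function(col) length(unique(col)) - 1L)
    maxs <- apply(m, 2, function(col) {
      tt <- table(col)
      sum(tt) - max(tt)
    })
    info <- apply(m, 2, function(col) {
      tt <- table(col)
      sum(tt >= 2) >= 2
    })
    if (!any(info)) next
    got <- parsimony_stats(tr, m)
    expect_equal(got$L, sum(lens))
    expect_equal(got$CI, sum(mins[info]) / sum(lens[info]))
    expect_equal(got$RI,
                 (sum(maxs[info]) - sum(lens[info])) /
                   (sum(maxs[info]) - sum(mins[info])))
  }
  # no informative characters: RI undefined
  auta <- matrix(c("1", "0", "0", "0"), 4, 1,
                 dimnames = list(c("A", "B", "C", "D")))
  tr4 <- ape::read.tree(text = "((A:1,B:1):1,(C:1,D:1):1);")
  expect_error(parsimony_stats(tr4, auta), "RI undefined")
})
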