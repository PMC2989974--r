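#' Read and validate a pipeline configuration
#'
#' The YAML configuration surfaces every threshold and calibration used by
#' [run_pipeline()]; nothing is hard-coded. Expected fields:
#' \describe{
#'   \item{genes}{list of `name`, `dna` (FASTA path), optional `cdna`,
#'     optional `frame` (default 0).}
#'   \item{tree}{Newick path (rooted, branch lengths).}
#'   \item{mode}{`deltran` (default) or `acctran`.}
#'   \item{prep_threshold}{profile-prediction threshold, default 0.6.}
#'   \item{root_age}{root calibration in Ma, default 130.}
#'   \item{focal}{tip labels whose MRCA is the focal ancestor for per-taxon
#'     rates (default: all tips, i.e. the root).}
#'   \item{focal_age}{age of the focal node in Ma, default 79.1; set to
#'     `"estimate"` to take it from the NPRS chronogram.}
#'   \item{pruning}{`none` (default), `keep-longest`, `keep-shortest`.}
#'   \item{seed}{integer random seed, default 1.}
#'   \item{retro_n_perm}{permutations for the retro scan, default 10000.}
#' }
#'
#' @param path YAML file path, or a list with the same fields.
#' @return Validated config list of class `run_config`.
#' @export
read_config <- function(path) {
  cfg <- if (is.list(path)) path else yaml::read_yaml(path)
  defaults <- list(mode = "deltran", prep_threshold = 0.6, root_age = 130,
                   focal = NULL, focal_age = 79.1, pruning = "none",
                   seed = 1L, retro_n_perm = 10000L, alpha = 0.05)
  for (nm in names(defaults))
    if (is.null(cfg[[nm]])) cfg[[nm]] <- defaults[[nm]]
  if (is.null(cfg$genes) || length(cfg$genes) == 0)
    stop("validation error: config lists no genes", call. = FALSE)
  if (is.null(cfg$tree))
    stop("validation error: config lists no tree", call. = FALSE)
  gene_names <- vapply(cfg$genes, function(g) g$name %||% NA_character_,
                       character(1))
  if (!is.null(cfg$analyze)) {
    unknown <- setdiff(unlist(cfg$analyze), gene_names)
    if (length(unknown) > 0)
      stop("validation error: unknown gene name(s): ",
           paste(unknown, collapse = ", "), call. = FALSE)
    cfg$genes <- cfg$genes[gene_names %in% unlist(cfg$analyze)]
  }
  if (!cfg$mode %in% c("deltran", "acctran"))
    stop("config error: unknown optimization mode ", cfg$mode, call. = FALSE)
  if (!cfg$pruning %in% c("none", "keep-longest", "keep-shortest"))
    stop("config error: unknown pruning variant ", cfg$pruning, call. = FALSE)
  stopifnot(cfg$prep_threshold > 0, cfg$prep_threshold <= 1,
            cfg$root_age > 0)
  cfg$seed <- as.integer(cfg$seed)
  structure(cfg, class = "run_config")
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("stage %s: %s", name, conditionMessage(e)), call. = FALSE))
}

write_tsv_file <- function(df, path) {
  df <- as.data.frame(df)
  list_cols <- vapply(df, is.list, logical(1))
  df[list_cols] <- lapply(df[list_cols], function(col)
    vapply(col, function(x) paste(unlist(x), collapse = ";"), character(1)))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Run the full editing-dynamics pipeline
#'
#' Chains edit calling, heterogeneity filtering, parsimony mapping,
#' ancestral reconstruction and per-branch synonymous rates, NPRS dating and
#' absolute rates, the edited-site vs third-position rate comparison,
#' sister-clade and PIC correlations (with the configured pruning variant),
#' and the retroprocessing scan, writing one TSV per result table plus a
#' JSON run summary into `out_dir`.
#'
#' @param config path to a YAML config, or a config list (see
#'   [read_config()]).
#' @param out_dir output directory (created if needed).
#' @return Invisibly, a list with all result objects.
#' @export
run_pipeline <- function(config, out_dir = "editevol-out") {
  cfg <- if (inherits(config, "run_config")) config else read_config(config)
  set.seed(cfg$seed)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  tree <- stage("validate", {
    tr <- read_tree(cfg$tree)
    tr
  })
  genes <- stage("validate", {
    lapply(cfg$genes, function(g) {
      if (is.null(g$name) || is.null(g$dna))
        stop("each gene needs a name and a dna path")
      dna <- read_alignment(g$dna, gene = g$name,
                            frame = g$frame %||% 0L)
      miss <- setdiff(tree$tip.label, rownames(dna))
      if (length(miss) > 0)
        stop("tips missing from ", g$name, " alignment: ",
             paste(miss, collapse = ", "))
      cdna <- if (!is.null(g$cdna))
        read_alignment(g$cdna, gene = g$name, frame = g$frame %||% 0L)
      list(name = g$name, dna = dna, cdna = cdna)
    })
  })

  edit_tables <- stage("call-edits", lapply(genes, function(g) {
    if (is.null(g$cdna))
      stop("gene ", g$name, " has no cDNA; profile prediction needs a ",
           "reference profile supplied programmatically")
    filter_heterogeneous(call_edited_sites(g$dna, g$cdna))
  }))

  histories <- stage("map-changes", lapply(seq_along(genes), function(i) {
    m <- build_character_matrix(edit_tables[[i]], genes[[i]]$dna)
    if (ncol(m) == 0) return(NULL)
    map_editing(tree, m, mode = cfg$mode)
  }))

  ancs <- stage("rates", lapply(genes, function(g)
    reconstruct_ancestral_sequences(tree, g$dna, method = "parsimony")))
  ds_tabs <- stage("rates", lapply(ancs, tree_branch_ds))

  dated <- stage("date", nprs_date(tree, root_age = cfg$root_age))
  focal_lab <- stage("date", {
    if (is.null(cfg[["focal"]])) node_labels(tree)[root_node(tree)]
    else node_labels(tree)[ape::getMRCA(tree, cfg[["focal"]])]
  })
  focal_age <- if (identical(cfg[["focal_age"]], "estimate"))
    unname(dated$ages[focal_lab]) else cfg[["focal_age"]]

  focal_node <- node_by_label(tree, focal_lab)
  focal_tips <- tree$tip.label[tips_below(tree)[[focal_node]]]
  rates_tab <- stage("rates", purrr::map_dfr(seq_along(genes), function(i) {
    ds <- ds_tabs[[i]]
    purrr::map_dfr(focal_tips, function(tx) tibble::tibble(
      taxon = tx, gene = genes[[i]]$name,
      ds_path = sum(setNames(ds$ds, ds$branch_id)[
        node_labels(tree)[path_nodes(tree, focal_node,
                                     node_by_label(tree, tx))]]),
      r_s = absolute_rate(tree, ds, focal_lab, tx, focal_age)))
  }))

  summaries <- stage("rates", purrr::map_dfr(seq_along(genes), function(i) {
    if (is.null(histories[[i]])) return(NULL)
    rate_summary(histories[[i]], ancs[[i]], focal_lab,
                 gene = genes[[i]]$name)
  }))

  contrasts <- stage("contrasts", purrr::map_dfr(
    seq_along(genes), function(i) {
      if (is.null(histories[[i]])) return(NULL)
      h <- histories[[i]]
      ds <- ds_tabs[[i]]
      ctree <- tree
      es_counts <- apply(h$matrix, 1L, function(r) sum(r == "1",
                                                       na.rm = TRUE))
      if (cfg$pruning != "none")
        ctree <- prune_zero_edit(
          tree, es_counts,
          keep = sub("keep-", "", cfg$pruning, fixed = TRUE))
      keep_ids <- branch_ids(ctree)
      ds_v <- setNames(ds$ds, ds$branch_id)
      ch_v <- setNames(h$branch_events$changes, h$branch_events$branch_id)
      if (!all(keep_ids %in% names(ds_v))) {
        # pruning can merge branches; recompute on the pruned tree
        anc_p <- reconstruct_ancestral_sequences(
          ctree, genes[[i]]$dna, method = "parsimony")
        ds_v <- with(tree_branch_ds(anc_p), setNames(ds, branch_id))
        h_p <- map_editing(ctree,
                           h$matrix[ctree$tip.label, , drop = FALSE],
                           mode = cfg$mode)
        ch_v <- setNames(h_p$branch_events$changes,
                         h_p$branch_events$branch_id)
      }
      cs <- sister_contrasts(ctree, ds_v[keep_ids], ch_v[keep_ids])
      if (nrow(cs) < 3) return(NULL)
      fit <- regression_through_origin(cs)
      tibble::tibble(gene = genes[[i]]$name, analysis = "sister_ds_changes",
                     pruning = cfg$pruning, n = fit$n, r = fit$r,
                     p_value = fit$p_value)
    }))

  retro <- stage("retro-scan", purrr::map_dfr(
    seq_along(genes), function(i) {
      h <- histories[[i]]
      if (is.null(h)) return(NULL)
      loss <- dplyr::filter(h$events, .data$event == "loss")
      if (nrow(loss) == 0) return(NULL)
      pos <- as.integer(colnames(h$matrix))
      loss$position <- pos[loss$character]
      par <- parent_vec(tree)
      labs <- node_labels(tree)
      risk <- purrr::map_dfr(unique(loss$branch_id), function(bid) {
        v <- node_by_label(tree, bid)
        tibble::tibble(branch_id = bid,
                       position = pos[h$node_states[labs[par[v]], ] == "1"])
      })
      sc <- retro_scan(loss, risk, n_perm = cfg$retro_n_perm,
                       alpha = cfg$alpha)
      if (nrow(sc) == 0) return(NULL)
      sc$gene <- genes[[i]]$name
      dplyr::select(sc, "gene", dplyr::everything(), -"segments")
    }))

  stage("write", {
    write_tsv_file(dplyr::bind_rows(edit_tables), file.path(out_dir,
                                                            "edit_table.tsv"))
    ev <- purrr::map_dfr(seq_along(genes), function(i) {
      h <- histories[[i]]
      if (is.null(h)) return(NULL)
      e <- h$events
      e$gene <- genes[[i]]$name
      e$position <- as.integer(colnames(h$matrix))[e$character]
      e
    })
    write_tsv_file(ev, file.path(out_dir, "events.tsv"))
    write_tsv_file(dplyr::bind_rows(lapply(seq_along(genes), function(i) {
      d <- ds_tabs[[i]]
      d$gene <- genes[[i]]$name
      d
    })), file.path(out_dir, "branch_ds.tsv"))
    write_tsv_file(rates_tab, file.path(out_dir, "rates.tsv"))
    write_tsv_file(summaries, file.path(out_dir, "rate_summary.tsv"))
    write_tsv_file(contrasts, file.path(out_dir, "contrasts.tsv"))
    write_tsv_file(retro, file.path(out_dir, "retro_scan.tsv"))
    chron <- dated$chronogram
    chron$node.label <- sprintf("%.6g", dated$ages[node_labels(tree)[
      (length(tree$tip.label) + 1):(length(tree$tip.label) + tree$Nnode)]])
    write_tree(chron, file.path(out_dir, "chronogram.nwk"))
    jsonlite::write_json(list(
      seed = cfg$seed, mode = cfg$mode, pruning = cfg$pruning,
      prep_threshold = cfg$prep_threshold, root_age = cfg$root_age,
      focal_node = focal_lab, focal_age = focal_age,
      package_version = as.character(utils::packageVersion("editevol")),
      r_version = R.version.string,
      genes = vapply(genes, function(g) g$name, character(1))),
      file.path(out_dir, "summary.json"), auto_unbox = TRUE, digits = NA)
  })

  invisible(list(config = cfg, tree = tree, edit_tables = edit_tables,
                 histories = histories, ancestral = ancs, ds = ds_tabs,
                 dated = dated, rates = rates_tab, rate_summaries = summaries,
                 contrasts = contrasts, retro = retro))
}
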