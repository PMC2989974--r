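# Kyte-Doolittle hydropathy scale (one-letter amino acid codes)
kd_scale <- c(A =  1.8, R = -4.5, N = -3.5, D = -3.5, C =  2.5,
              Q = -3.5, E = -3.5, G = -0.4, H = -3.2, I =  4.5,
              L =  3.8, K = -3.9, M =  1.9, F =  2.8, P = -1.6,
              S = -0.8, T = -0.7, W = -0.9, Y = -1.3, V =  4.2)

# standard genetic code lookup, built once from seqinr
codon_table_env <- new.env(parent = emptyenv())

codon_table <- function() {
  if (is.null(codon_table_env$tab)) {
    nts <- c("A", "C", "G", "T")
    codons <- as.vector(outer(outer(nts, nts, paste0), nts, paste0))
    aas <- vapply(codons, function(cd)
      seqinr::translate(strsplit(cd, "")[[1]]), character(1))
    codon_table_env$tab <- setNames(aas, codons)
  }
  codon_table_env$tab
}

#' Translate codons under the standard genetic code
#'
#' Plant mitochondria use the standard code, which is assumed throughout.
#'
#' @param codons character vector of 3-letter codons (e.g. `"TCA"`).
#' @return One-letter amino acid codes (`"*"` for stops, `NA` for codons
#'   containing gaps or ambiguity).
#' @export
translate_codon <- function(codons) {
  codons <- toupper(codons)
  out <- unname(codon_table()[codons])
  out[!grepl("^[ACGT]{3}$", codons)] <- NA_character_
  out
}

edit_status_levels <- c("EDITED_C", "UNEDITED_C", "GENOMIC_T", "OTHER",
                        "MISSING")

new_edit_table <- function(df, gene, frame) {
  structure(df, gene = gene, frame = frame,
            class = c("edit_table", class(tibble::tibble())))
}

#' Call edited sites from a DNA/cDNA alignment pair
#'
#' An alignment column is an edited site when at least one cDNA-covered taxon
#' has a genomic `C` whose cDNA reads `T` (the C-to-U edit, reverse
#' transcribed). The returned table has one row per taxon for every edited
#' column, with status `EDITED_C` (DNA C, cDNA T), `UNEDITED_C` (DNA C, cDNA
#' C — or genomic C with no cDNA, reported with `evidence = "none"`),
#' `GENOMIC_T` (DNA T), `MISSING` (gap/unknown) or `OTHER`.
#'
#' @param dna genomic [codon_alignment()].
#' @param cdna cDNA [codon_alignment()] for a subset of the taxa, on the same
#'   coordinates.
#' @param taxon_map optional named character vector mapping cDNA record names
#'   to DNA taxon labels (defaults to identical names).
#' @return An `edit_table` tibble: `gene`, `position` (1-based alignment
#'   column), `codon_position`, `taxon`, `status`, `evidence`, `excluded`,
#'   `score`.
#' @export
call_edited_sites <- function(dna, cdna, taxon_map = NULL) {
  if (ncol(dna) != ncol(cdna) || attr(dna, "frame") != attr(cdna, "frame"))
    stop("coordinate error: DNA and cDNA alignments are not column-compatible",
         call. = FALSE)
  cdna_names <- rownames(cdna)
  if (is.null(taxon_map))
    taxon_map <- setNames(cdna_names, cdna_names)
  mapped <- unname(taxon_map[cdna_names])
  if (anyNA(mapped) || !all(mapped %in% rownames(dna)))
    stop("cDNA taxa must map into the DNA alignment's taxa", call. = FALSE)
  frame <- attr(dna, "frame")
  gene <- attr(dna, "gene")

  # edited columns: any covered taxon with DNA C and cDNA T
  is_edit <- rep(FALSE, ncol(dna))
  for (i in seq_along(cdna_names)) {
    d <- dna[mapped[i], ]
    r <- cdna[cdna_names[i], ]
    is_edit <- is_edit | (d == "C" & r == "T")
  }
  cols <- which(is_edit)
  taxa <- rownames(dna)
  has_cdna <- setNames(rep(FALSE, length(taxa)), taxa)
  has_cdna[mapped] <- TRUE
  cdna_row <- setNames(rep(NA_integer_, length(taxa)), taxa)
  cdna_row[mapped] <- seq_along(cdna_names)

  grid <- tidyr::expand_grid(position = cols, taxon = taxa)
  d_ch <- dna[cbind(match(grid$taxon, taxa), grid$position)]
  r_ch <- rep(NA_character_, nrow(grid))
  cov <- has_cdna[grid$taxon]
  if (any(cov))
    r_ch[cov] <- cdna[cbind(cdna_row[grid$taxon[cov]], grid$position[cov])]
  status <- rep("OTHER", nrow(grid))
  status[d_ch %in% c("-", "?")] <- "MISSING"
  status[d_ch == "T"] <- "GENOMIC_T"
  status[d_ch == "C"] <- "UNEDITED_C"
  status[d_ch == "C" & cov & !is.na(r_ch) & r_ch == "T"] <- "EDITED_C"
  evid <- ifelse(cov & !is.na(r_ch) & !(r_ch %in% c("-", "?")), "cDNA", "none")
  new_edit_table(tibble::tibble(
    gene = gene, position = grid$position,
    codon_position = codon_position(grid$position, frame),
    taxon = grid$taxon, status = status, evidence = evid,
    excluded = FALSE, score = NA_real_), gene, frame)
}

#' Exclude columns with heterogeneous experimental editing status
#'
#' A column where cDNA evidence shows the site edited in some taxa but
#' genomically `C` yet unedited in others cannot be scored as a simple
#' presence/absence character, and is flagged `excluded`. A `GENOMIC_T` in
#' other taxa is a loss, not heterogeneity, and does not trigger exclusion.
#' The operation is idempotent.
#'
#' @param table an `edit_table`.
#' @return The table with the `excluded` flag set on heterogeneous columns.
#' @export
filter_heterogeneous <- function(table) {
  if (nrow(table) == 0) return(table)
  het <- table |>
    dplyr::filter(.data$evidence == "cDNA") |>
    dplyr::group_by(.data$position) |>
    dplyr::summarise(
      het = any(.data$status == "EDITED_C") & any(.data$status == "UNEDITED_C"),
      .groups = "drop")
  bad <- het$position[het$het]
  out <- dplyr::mutate(table,
                       excluded = .data$excluded | .data$position %in% bad)
  new_edit_table(out, attr(table, "gene"), attr(table, "frame"))
}

#' Predict edited sites from a protein conservation profile
#'
#' A deliberately simple profile scorer in the spirit of editing predictors
#' that exploit protein-level conservation: for every genomic `C`, the codon
#' is virtually edited (that `C` read as `T`) and translated; the score is the
#' fraction of reference proteins whose residue at that codon equals the
#' edited translation but not the unedited one (references matching both or
#' neither contribute 0). The site is predicted edited when the score reaches
#' `threshold`. When cDNA evidence exists it always overrules predictions.
#'
#' @param dna genomic [codon_alignment()].
#' @param reference_profile references x codons character matrix of
#'   one-letter residues aligned to the gene's codons.
#' @param threshold prediction threshold in (0, 1]; default 0.6.
#' @return An `edit_table` tibble (`evidence = "predicted"`) covering every
#'   column predicted edited in at least one taxon; `score` holds the
#'   per-taxon score at genomic-C cells.
#' @export
predict_edited_sites <- function(dna, reference_profile, threshold = 0.6) {
  stopifnot(threshold > 0, threshold <= 1)
  if (!is.matrix(reference_profile))
    reference_profile <- matrix(reference_profile, nrow = 1)
  if (ncol(reference_profile) != n_codons(dna))
    stop("coordinate error: reference profile has ", ncol(reference_profile),
         " codons but alignment has ", n_codons(dna), call. = FALSE)
  frame <- attr(dna, "frame")
  gene <- attr(dna, "gene")
  taxa <- rownames(dna)
  rows <- list()
  for (tx in taxa) {
    seqv <- dna[tx, ]
    ccols <- which(seqv == "C" & seq_along(seqv) > frame)
    for (col in ccols) {
      ci <- codon_index(col, frame)
      cp <- codon_position(col, frame)
      start <- frame + (ci - 1L) * 3L + 1L
      codon <- seqv[start:(start + 2L)]
      if (!all(codon %in% c("A", "C", "G", "T"))) next
      un_aa <- translate_codon(paste0(codon, collapse = ""))
      ed <- codon
      ed[cp] <- "T"
      ed_aa <- translate_codon(paste0(ed, collapse = ""))
      if (identical(un_aa, ed_aa)) next  # synonymous edit: profile is blind
      ref <- reference_profile[, ci]
      ref <- ref[!is.na(ref) & ref != "-"]
      if (length(ref) == 0) next
      score <- mean(ref == ed_aa & ref != un_aa)
      rows[[length(rows) + 1L]] <- tibble::tibble(
        position = col, codon_position = cp, taxon = tx, score = score,
        predicted = score >= threshold)
    }
  }
  scored <- if (length(rows) > 0) dplyr::bind_rows(rows) else
    tibble::tibble(position = integer(), codon_position = integer(),
                   taxon = character(), score = numeric(),
                   predicted = logical())
  cols <- sort(unique(scored$position[scored$predicted]))
  grid <- tidyr::expand_grid(position = cols, taxon = taxa)
  d_ch <- dna[cbind(match(grid$taxon, taxa), grid$position)]
  status <- rep("OTHER", nrow(grid))
  status[d_ch %in% c("-", "?")] <- "MISSING"
  status[d_ch == "T"] <- "GENOMIC_T"
  status[d_ch == "C"] <- "UNEDITED_C"
  out <- tibble::tibble(
    gene = gene, position = grid$position,
    codon_position = codon_position(grid$position, frame),
    taxon = grid$taxon, status = status, evidence = "predicted",
    excluded = FALSE) |>
    dplyr::left_join(dplyr::select(scored, "position", "taxon", "score",
                                   "predicted"),
                     by = c("position", "taxon"))
  out$status[!is.na(out$predicted) & out$predicted &
               out$status == "UNEDITED_C"] <- "EDITED_C"
  out$predicted <- NULL
  new_edit_table(out, gene, frame)
}

#' Summarise the protein-level consequences of editing
#'
#' For each included edited column, the unedited amino acid is translated
#' from the genomic codon of an edited taxon, and the edited amino acid from
#' the same codon with that single `C` read as `T`. Returns codon-position
#' counts with integer-rounded percentages, the amino-acid change spectrum,
#' and Kyte-Doolittle hydropathy shifts.
#'
#' @param table an `edit_table`, typically after [filter_heterogeneous()].
#' @param dna the genomic [codon_alignment()].
#' @return An object of class `edit_effects`: a list with tibbles
#'   `positions` (`codon_position`, `n`, `pct`), `spectrum` (`from_aa`,
#'   `to_aa`, `n`, `freq`, `hydropathy_delta`) and scalar
#'   `mean_hydropathy_delta`.
#' @export
editing_effect_summary <- function(table, dna) {
  frame <- attr(dna, "frame")
  ed <- table |>
    dplyr::filter(!.data$excluded, .data$status == "EDITED_C")
  cols <- sort(unique(ed$position))
  eff <- purrr::map_dfr(cols, function(col) {
    tx <- ed$taxon[ed$position == col][1L]
    ci <- codon_index(col, frame)
    cp <- codon_position(col, frame)
    start <- frame + (ci - 1L) * 3L + 1L
    codon <- dna[tx, start:(start + 2L)]
    un_aa <- translate_codon(paste0(codon, collapse = ""))
    edited <- codon
    edited[cp] <- "T"
    ed_aa <- translate_codon(paste0(edited, collapse = ""))
    tibble::tibble(position = col, codon_position = cp,
                   from_aa = un_aa, to_aa = ed_aa)
  })
  pos <- tibble::tibble(codon_position = 1:3) |>
    dplyr::left_join(dplyr::count(eff, .data$codon_position),
                     by = "codon_position") |>
    dplyr::mutate(n = dplyr::coalesce(.data$n, 0L),
                  pct = round(100 * .data$n / max(sum(.data$n), 1L)))
  spec <- eff |>
    dplyr::filter(!is.na(.data$from_aa), !is.na(.data$to_aa),
                  .data$from_aa != .data$to_aa) |>
    dplyr::count(.data$from_aa, .data$to_aa, sort = TRUE) |>
    dplyr::mutate(freq = .data$n / sum(.data$n),
                  hydropathy_delta = unname(kd_scale[.data$to_aa] -
                                              kd_scale[.data$from_aa]))
  mean_delta <- if (nrow(spec) > 0)
    sum(spec$hydropathy_delta * spec$n) / sum(spec$n) else NA_real_
  structure(list(positions = pos, spectrum = spec,
                 mean_hydropathy_delta = mean_delta,
                 n_edited_columns = length(cols), effects = eff),
            class = "edit_effects")
}

#' @export
print.edit_effects <- function(x, ...) {
  cat(sprintf("<edit_effects> %d edited columns\n", x$n_edited_columns))
  print(x$positions)
  cat(sprintf("mean Kyte-Doolittle hydropathy shift: %+.2f\n",
              x$mean_hydropathy_delta))
  invisible(x)
}

#' Binary character matrix of editing presence
#'
#' Builds the taxa x characters 0/1 matrix fed to the parsimony mapper from
#' the included edited columns of an edit table: `1` for a genomic `C` at an
#' edited column (assumed edited even without cDNA coverage, the convention
#' that treats editing competence as conserved), `0` for a genomic `T`, `NA`
#' otherwise. With `strict = TRUE`, a genomic `C` without cDNA confirmation
#' is scored `NA` instead of `1`.
#'
#' @param table an `edit_table` after [filter_heterogeneous()].
#' @param dna the genomic [codon_alignment()].
#' @param strict require cDNA confirmation for state `1`.
#' @return taxa x characters matrix (columns named by 1-based alignment
#'   position) with entries `"1"`, `"0"`, `NA`.
#' @export
build_character_matrix <- function(table, dna, strict = FALSE) {
  inc <- dplyr::filter(table, !.data$excluded)
  cols <- sort(unique(inc$position[inc$status == "EDITED_C"]))
  taxa <- rownames(dna)
  m <- matrix(NA_character_, length(taxa), length(cols),
              dimnames = list(taxa, as.character(cols)))
  for (j in seq_along(cols)) {
    ch <- dna[, cols[j]]
    m[ch == "C", j] <- "1"
    m[ch == "T", j] <- "0"
    if (strict) {
      conf <- inc$taxon[inc$position == cols[j] & inc$status == "EDITED_C" &
                          inc$evidence %in% c("cDNA", "predicted")]
      m[ch == "C" & !(taxa %in% conf), j] <- NA_character_
    }
  }
  m
}
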