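quant_conditions <- c("ctrl", "neg", "exp")

intensity_matrix <- function(table, condition) {
  nt <- attr(table, "n_trials")
  cols <- paste0(condition, ".", seq_len(nt))
  as.matrix(table[, cols, drop = FALSE])
}

#' Load a protein quantitation table
#'
#' Reads a MaxQuant-proteinGroups-like TSV/CSV (one row per protein,
#' intensity columns per condition and trial) into the canonical
#' `quant_table` layout: `accession`, `gene`, and columns
#' `ctrl.<t>`, `neg.<t>`, `exp.<t>`. Missing intensities are read as 0
#' (not detected); contaminant and reverse-decoy rows (accession prefix
#' `CON__` / `REV__`) are dropped; duplicate accessions are an error.
#'
#' @param path TSV (default) or CSV file with a header row.
#' @param column_map data frame mapping file columns to the canonical
#'   layout, with columns `column` (name in the file), `condition`
#'   (`"ctrl"`, `"neg"` or `"exp"`) and `trial` (1-based integer); plus
#'   attributes-free rows with `condition = "accession"` / `"gene"` for
#'   the identifier columns.
#' @param sep field separator; guessed from the file extension when
#'   `NULL`.
#' @return A `quant_table` data frame; `attr(., "n_rows_read")` records
#'   the post-filter row count.
#' @export
load_quant_table <- function(path, column_map, sep = NULL) {
  stopifnot(all(c("column", "condition", "trial") %in% names(column_map)))
  if (is.null(sep))
    sep <- if (tolower(tools::file_ext(path)) == "csv") "," else "\t"
  raw <- read.delim(path, sep = sep, check.names = FALSE,
                    stringsAsFactors = FALSE)
  missing_cols <- setdiff(column_map$column, names(raw))
  if (length(missing_cols))
    stop("mapped columns absent from the file: ",
         paste(missing_cols, collapse = ", "))
  id_row <- function(cond) {
    r <- column_map[column_map$condition == cond, ]
    if (nrow(r) != 1L) stop("column_map must name exactly one ",
                            cond, " column")
    r$column
  }
  acc <- as.character(raw[[id_row("accession")]])
  gene_rows <- column_map[column_map$condition == "gene", ]
  gene <- if (nrow(gene_rows) == 1L)
    as.character(raw[[gene_rows$column]]) else rep("", nrow(raw))
  keep <- !grepl("^(CON__|REV__)", acc)
  raw <- raw[keep, , drop = FALSE]; acc <- acc[keep]; gene <- gene[keep]
  if (anyDuplicated(acc))
    stop("duplicate accession(s): ",
         paste(unique(acc[duplicated(acc)]), collapse = ", "))
  im <- column_map[column_map$condition %in% quant_conditions, ]
  if (!all(quant_conditions %in% im$condition))
    stop("column_map must map all three conditions: ",
         paste(quant_conditions, collapse = ", "))
  nt <- max(im$trial)
  tab <- data.frame(accession = acc, gene = gene,
                    stringsAsFactors = FALSE)
  for (cond in quant_conditions) for (t in seq_len(nt)) {
    r <- im[im$condition == cond & im$trial == t, ]
    v <- if (nrow(r) == 1L) suppressWarnings(as.numeric(raw[[r$column]]))
      else rep(NA_real_, nrow(raw))
    v[is.na(v)] <- 0
    tab[[paste0(cond, ".", t)]] <- v
  }
  class(tab) <- c("quant_table", "data.frame")
  attr(tab, "n_trials") <- nt
  attr(tab, "n_rows_read") <- nrow(tab)
  tab
}

#' Remove control-enriched proteins
#'
#' Drops proteins that look labeled independently of the kinase: a
#' protein is removed when its unlabeled-control (`ctrl`) intensity
#' exceeds its experimental (`exp`) intensity in a majority of the
#' trials where both were detected, or when it was detected only in the
#' control (exclusive to `ctrl`).
#'
#' @param table a `quant_table`.
#' @return The filtered `quant_table`; removed accessions are recorded
#'   in `attr(., "removed")`.
#' @export
filter_control_enriched <- function(table) {
  ctrl <- intensity_matrix(table, "ctrl")
  expm <- intensity_matrix(table, "exp")
  drop <- vapply(seq_len(nrow(table)), function(i) {
    both <- ctrl[i, ] > 0 & expm[i, ] > 0
    if (any(both))
      return(mean(ctrl[i, both] > expm[i, both]) > 0.5)
    any(ctrl[i, ] > 0) && all(expm[i, ] == 0)   # exclusive to control
  }, TRUE)
  out <- table[!drop, , drop = FALSE]
  class(out) <- class(table)
  attr(out, "n_trials") <- attr(table, "n_trials")
  attr(out, "removed") <- table$accession[drop]
  out
}

#' Per-trial fold enrichment
#'
#' For every protein and trial, the ratio of the experimental intensity
#' (ATP-biotin + kinase) to the negative control (ATP-biotin, no
#' kinase). A protein detected in `exp` but not in `neg` gets `Inf`
#' (exclusive to the experimental sample — maximal enrichment); a trial
#' where neither was detected is not evaluable (`NA`).
#'
#' @param table a `quant_table`, normally already control-filtered.
#' @return An `enrichment_table` data frame: `accession`, `gene`,
#'   `enrichment.<t>` per trial and `n_trials_evaluable`.
#' @export
compute_enrichment <- function(table) {
  neg <- intensity_matrix(table, "neg")
  expm <- intensity_matrix(table, "exp")
  nt <- attr(table, "n_trials")
  enr <- matrix(NA_real_, nrow(table), nt)
  enr[neg > 0] <- (expm / neg)[neg > 0]
  enr[neg == 0 & expm > 0] <- Inf
  out <- data.frame(accession = table$accession, gene = table$gene,
                    stringsAsFactors = FALSE)
  for (t in seq_len(nt)) out[[paste0("enrichment.", t)]] <- enr[, t]
  out$n_trials_evaluable <- rowSums(!is.na(enr))
  class(out) <- c("enrichment_table", "data.frame")
  attr(out, "n_trials") <- nt
  out
}

enrichment_matrix <- function(enrich) {
  nt <- attr(enrich, "n_trials")
  as.matrix(enrich[, paste0("enrichment.", seq_len(nt)), drop = FALSE])
}

#' Call hits by N-of-M-trials fold enrichment
#'
#' A protein is a hit when its enrichment is at least `threshold` (or
#' `Inf`, exclusive to the experimental sample) in at least `min_trials`
#' trials. The standard screens are `threshold = 1.5` (all possible
#' hits) and `threshold = 6` (high stringency), each with
#' `min_trials = 2` of 4. Hits are sorted by descending median finite
#' enrichment, ties by accession.
#'
#' @param enrich an `enrichment_table`.
#' @param threshold fold-enrichment threshold (> 0).
#' @param min_trials minimum number of passing trials.
#' @param count_inf count `Inf` (exclusive-to-experimental) trials as
#'   passing.
#' @return A `hit_list` object: `hits` data frame (accession, gene,
#'   per-trial enrichments, `n_passing_trials`), plus the calling
#'   parameters.
#' @export
call_hits <- function(enrich, threshold, min_trials, count_inf = TRUE) {
  stopifnot(inherits(enrich, "enrichment_table"))
  nt <- attr(enrich, "n_trials")
  if (threshold <= 0) stop("threshold must be > 0")
  if (min_trials < 1L || min_trials > nt)
    stop("min_trials must be between 1 and the number of trials")
  em <- enrichment_matrix(enrich)
  pass <- !is.na(em) & ((is.finite(em) & em >= threshold) |
                          (count_inf & is.infinite(em)))
  n_pass <- rowSums(pass)
  is_hit <- n_pass >= min_trials
  hits <- enrich[is_hit, , drop = FALSE]
  hits$n_passing_trials <- n_pass[is_hit]
  med <- apply(enrichment_matrix(hits), 1L, function(r)
    if (any(is.finite(r))) median(r[is.finite(r)]) else -Inf)
  ord <- order(-med, hits$accession)
  hits <- hits[ord, , drop = FALSE]
  rownames(hits) <- NULL
  class(hits) <- "data.frame"
  structure(list(hits = hits, threshold = threshold,
                 min_trials = min_trials, total_trials = nt,
                 n_hits = nrow(hits)),
            class = "hit_list")
}

#' @export
print.hit_list <- function(x, ...) {
  cat(sprintf("hit_list: %d hits at >= %.2g-fold in >= %d of %d trials\n",
              x$n_hits, x$threshold, x$min_trials, x$total_trials))
  if (x$n_hits) print(head(x$hits, 10L), row.names = FALSE, digits = 3)
  if (x$n_hits > 10L) cat("  ...", x$n_hits - 10L, "more\n")
  invisible(x)
}

#' Full screen pipeline
#'
#' Control filtering, enrichment and hit calling in one call.
#'
#' @param table a `quant_table`.
#' @inheritParams call_hits
#' @return A `hit_list`.
#' @export
screen_hits <- function(table, threshold = 6, min_trials = 2L,
                        count_inf = TRUE) {
  call_hits(compute_enrichment(filter_control_enriched(table)),
            threshold, min_trials, count_inf)
}
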