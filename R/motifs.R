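#' Scan a protein sequence for PKA consensus phosphosites
#'
#' Slides over every serine and threonine and inspects the -4..+1 window
#' for the basophilic PKA consensus. Tiers follow the classic consensus
#' hierarchy: \emph{strong} sites carry arginines at both -3 and -2
#' (R-R-x-S/T, as in the canonical RRAS/RRAT substrate sequences);
#' \emph{moderate} sites carry R at -3 only (R-x-x-S/T) or the K-R
#' variant (K-R-x-S/T). `X` (unknown residue) never matches.
#'
#' The score is a weighted fraction of matched determinants in `[0, 1]`:
#' the -3 and -2 basic positions (R = 1, K = 0.6) weighted twice, plus a
#' hydrophobic +1 residue (A, L, I, V, F, M) weighted once. It is a
#' transparent consensus score, not a neural-network site probability.
#'
#' @param sequence amino-acid string (one-letter code; `X` tolerated).
#' @param min_tier minimum tier to report: `"moderate"` (default) or
#'   `"strong"`.
#' @param accession optional identifier copied into the result.
#' @return Data frame of motif hits: `accession`, `position` (1-based
#'   index of the S/T), `residue`, `window` (-4..+1, `-`-padded),
#'   `tier`, `score`.
#' @examples
#' scan_pka_motifs("LRRATLV")   # strong site at T5 (RRAT)
#' @export
scan_pka_motifs <- function(sequence, min_tier = c("moderate", "strong"),
                            accession = "") {
  min_tier <- match.arg(min_tier)
  empty <- data.frame(accession = character(), position = integer(),
                      residue = character(), window = character(),
                      tier = character(), score = numeric(),
                      stringsAsFactors = FALSE)
  if (is.na(sequence) || nchar(sequence) == 0L) return(empty)
  sequence <- toupper(sequence)
  aa <- strsplit(sequence, "")[[1L]]
  if (!all(aa %in% c(LETTERS, "*", "-")))
    stop("sequence contains non-amino-acid characters")
  at <- function(i) if (i >= 1L && i <= length(aa)) aa[i] else "-"
  hydrophobic <- c("A", "L", "I", "V", "F", "M")
  rows <- list()
  for (i in which(aa %in% c("S", "T"))) {
    p3 <- at(i - 3L); p2 <- at(i - 2L); p1 <- at(i + 1L)
    tier <- if (p3 == "R" && p2 == "R") "strong"
      else if (p3 == "R" || (p3 == "K" && p2 == "R")) "moderate"
      else next
    if (min_tier == "strong" && tier != "strong") next
    w3 <- if (p3 == "R") 1 else if (p3 == "K") 0.6 else 0
    w2 <- if (p2 == "R") 1 else if (p2 == "K") 0.6 else 0
    w1 <- if (p1 %in% hydrophobic) 1 else 0
    rows[[length(rows) + 1L]] <- data.frame(
      accession = accession, position = i, residue = aa[i],
      window = paste(vapply((i - 4L):(i + 1L), at, ""), collapse = ""),
      tier = tier, score = (2 * w3 + 2 * w2 + w1) / 5,
      stringsAsFactors = FALSE)
  }
  if (length(rows)) do.call(rbind, rows) else empty
}

#' Scan a FASTA file of candidate substrates
#'
#' Applies [scan_pka_motifs()] to every sequence of a FASTA file (read
#' with \pkg{Biostrings}) and returns the combined motif table.
#'
#' @param path FASTA file of amino-acid sequences.
#' @param min_tier passed to [scan_pka_motifs()].
#' @return Combined motif data frame; sequence names become accessions.
#' @export
scan_fasta_pka_motifs <- function(path, min_tier = "moderate") {
  if (!requireNamespace("Biostrings", quietly = TRUE))
    stop("Biostrings is required to read FASTA files")
  seqs <- Biostrings::readAAStringSet(path)
  out <- lapply(seq_along(seqs), function(i)
    scan_pka_motifs(as.character(seqs[[i]]), min_tier,
                    accession = sub("\\s.*", "", names(seqs)[i])))
  do.call(rbind, out)
}
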