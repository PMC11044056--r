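#' Specification for a synthetic protein quantitation table
#'
#' Emulates a MaxQuant-proteinGroups-like label-free quantitation table
#' from a kinase-catalyzed biotinylation screen with three conditions
#' per trial — `ctrl` (kinase + plain ATP, unlabeled control), `neg`
#' (ATP-biotin without kinase) and `exp` (ATP-biotin with kinase) — and
#' known ground truth: planted substrate hits whose `exp` intensity is
#' `planted_fold` times their `neg` intensity in every trial (before
#' noise), a fraction of control-enriched proteins, and random missing
#' values stored as 0 (the not-detected convention).
#'
#' @param n_proteins number of proteins.
#' @param n_planted_hits number of true substrates (<= `n_proteins`).
#' @param planted_fold fold enrichment of hits (> 1).
#' @param n_trials number of independent trials.
#' @param lognormal_noise_sigma sdlog of multiplicative intensity noise.
#' @param control_enriched_fraction fraction of non-hit proteins whose
#'   `ctrl` intensity exceeds the others (to be filtered out).
#' @param missingness_rate probability that any intensity is zeroed.
#' @param seed integer seed.
#' @return A `quant_table_spec` object.
#' @export
quant_table_spec <- function(n_proteins = 1000L, n_planted_hits = 50L,
                             planted_fold = 8, n_trials = 4L,
                             lognormal_noise_sigma = 0.3,
                             control_enriched_fraction = 0.05,
                             missingness_rate = 0.05, seed = 1L) {
  if (n_planted_hits > n_proteins)
    stop("n_planted_hits must not exceed n_proteins")
  if (planted_fold <= 1) stop("planted_fold must be > 1")
  if (lognormal_noise_sigma < 0) stop("lognormal_noise_sigma must be >= 0")
  if (control_enriched_fraction < 0 || control_enriched_fraction >= 1)
    stop("control_enriched_fraction must be in [0, 1)")
  if (missingness_rate < 0 || missingness_rate >= 1)
    stop("missingness_rate must be in [0, 1)")
  structure(list(n_proteins = as.integer(n_proteins),
                 n_planted_hits = as.integer(n_planted_hits),
                 planted_fold = planted_fold,
                 n_trials = as.integer(n_trials),
                 lognormal_noise_sigma = lognormal_noise_sigma,
                 control_enriched_fraction = control_enriched_fraction,
                 missingness_rate = missingness_rate,
                 seed = as.integer(seed)),
            class = "quant_table_spec")
}

#' Generate a quantitation table with known ground truth
#'
#' @param spec a [quant_table_spec()].
#' @return List with
#'   \describe{
#'     \item{table}{a `quant_table` data frame: `accession`, `gene`,
#'       and intensity columns `ctrl.<t>`, `neg.<t>`, `exp.<t>` per
#'       trial.}
#'     \item{true_hits}{accessions of planted substrates.}
#'     \item{true_control_enriched}{accessions of planted
#'       control-enriched proteins.}
#'   }
#' @examples
#' g <- generate_quant_table(quant_table_spec(n_proteins = 20,
#'   n_planted_hits = 3, lognormal_noise_sigma = 0, missingness_rate = 0))
#' head(g$table)
#' @export
generate_quant_table <- function(spec) {
  stopifnot(inherits(spec, "quant_table_spec"))
  np <- spec$n_proteins; nt <- spec$n_trials
  acc <- sprintf("P%05d", seq_len(np))
  gene <- sprintf("GENE%d", seq_len(np))
  with_seed(spec$seed, {
    hit_idx <- if (spec$n_planted_hits > 0)
      sort(sample.int(np, spec$n_planted_hits)) else integer(0)
    non_hits <- setdiff(seq_len(np), hit_idx)
    n_ce <- round(spec$control_enriched_fraction * length(non_hits))
    ce_idx <- if (n_ce > 0) sort(sample(non_hits, n_ce)) else integer(0)
    base <- rlnorm(np, meanlog = log(1e8), sdlog = 1)
    noise <- function() if (spec$lognormal_noise_sigma > 0)
      matrix(rlnorm(np * nt, 0, spec$lognormal_noise_sigma), np, nt) else
      matrix(1, np, nt)
    # the three reactions of a trial are run from one lysate split, so
    # per-trial abundance variation is shared across conditions and the
    # kinase-dependent reactions carry per-reaction noise relative to
    # the trial's negative control; the enrichment ratio then has sdlog
    # equal to lognormal_noise_sigma
    lysate <- base * noise()
    neg <- lysate
    expm <- lysate * noise()
    expm[hit_idx, ] <- spec$planted_fold * expm[hit_idx, , drop = FALSE]
    # background binding keeps the unlabeled control low except for the
    # planted control-enriched class
    ctrl_scale <- rep(0.2, np)
    ctrl_scale[ce_idx] <- 5
    ctrl <- ctrl_scale * lysate * noise()
    if (spec$missingness_rate > 0) {
      zap <- function(m) { m[matrix(runif(np * nt) <
                                      spec$missingness_rate, np, nt)] <- 0; m }
      neg <- zap(neg); expm <- zap(expm); ctrl <- zap(ctrl)
    }
    tab <- data.frame(accession = acc, gene = gene)
    for (t in seq_len(nt)) {
      tab[[paste0("ctrl.", t)]] <- ctrl[, t]
      tab[[paste0("neg.", t)]] <- neg[, t]
      tab[[paste0("exp.", t)]] <- expm[, t]
    }
    class(tab) <- c("quant_table", "data.frame")
    attr(tab, "n_trials") <- nt
    list(table = tab, true_hits = acc[hit_idx],
         true_control_enriched = acc[ce_idx])
  })
}
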