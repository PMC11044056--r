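write_toy_table <- function(path) {
  df <- data.frame(
    `Protein IDs` = c("P11111", "P22222", "REV__P33333", "P44444"),
    `Gene names` = c("Abc1", "Def2", "Rev3", "Ghi4"),
    check.names = FALSE)
  for (t in 1:2) {
    df[[paste0("Intensity C", t)]] <- c(10, 500, 10, 0)
    df[[paste0("Intensity N", t)]] <- c(100, 100, 10, 50)
    df[[paste0("Intensity E", t)]] <- c(300, 120, 10, 400)
  }
  write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  path
}

toy_map <- function() {
  rbind(data.frame(column = "Protein IDs", condition = "accession",
                   trial = NA_integer_),
        data.frame(column = "Gene names", condition = "gene",
                   trial = NA_integer_),
        expand.grid(stringsAsFactors = FALSE,
                    condition = c("ctrl", "neg", "exp"), trial = 1:2) |>
          transform(column = paste0("Intensity ",
                                    c(ctrl = "C", neg = "N",
                                      exp = "E")[condition], trial)))
}

test_that("quant table loading maps columns and drops decoys", {
  path <- write_toy_table(tempfile(fileext = ".tsv"))
  tab <- load_quant_table(path, toy_map())
  expect_equal(nrow(tab), 3L)                  # REV__ row dropped
  expect_false(any(grepl("^REV__", tab$accession)))
  expect_equal(attr(tab, "n_trials"), 2L)
  expect_equal(tab$exp.1[tab$accession == "P11111"], 300)
  expect_equal(tab$ctrl.2[tab$accession == "P22222"], 500)
  # missing intensity read as zero
  expect_equal(tab$ctrl.1[tab$accession == "P44444"], 0)
  # duplicate accession is an error
  bad <- read.delim(path, check.names = FALSE)
  bad$`Protein IDs`[2] <- "P11111"
  p2 <- tempfile(fileext = ".tsv")
  write.table(bad, p2, sep = "\t", row.names = FALSE, quote = FALSE)
  expect_error(load_quant_table(p2, toy_map()), "duplicate")
  # unmapped column is an error
  m <- toy_map(); m$column[1] <- "Majority protein IDs"
  expect_error(load_quant_table(path, m), "absent")
})

test_that("control-enriched proteins are removed by the majority rule", {
  mk <- function(ctrl, neg, expv) {
    tab <- data.frame(accession = "P1", gene = "g")
    for (t in 1:4) {
      tab[[paste0("ctrl.", t)]] <- ctrl[t]
      tab[[paste0("neg.", t)]] <- neg[t]
      tab[[paste0("exp.", t)]] <- expv[t]
    }
    class(tab) <- c("quant_table", "data.frame")
    attr(tab, "n_trials") <- 4L
    tab
  }
  # ctrl > exp in 3 of 4 trials -> removed
  expect_equal(nrow(filter_control_enriched(
    mk(c(500, 500, 500, 10), rep(100, 4), rep(200, 4)))), 0L)
  # detected only in ctrl -> removed
  expect_equal(nrow(filter_control_enriched(
    mk(c(500, 0, 0, 0), rep(0, 4), rep(0, 4)))), 0L)
  # ctrl zero everywhere -> retained
  expect_equal(nrow(filter_control_enriched(
    mk(rep(0, 4), rep(100, 4), rep(200, 4)))), 1L)
  # ctrl > exp in only 2 of 4 evaluable trials -> retained (not a majority)
  expect_equal(nrow(filter_control_enriched(
    mk(c(500, 500, 10, 10), rep(100, 4), rep(200, 4)))), 1L)
})

test_that("enrichment arithmetic handles zeros via Inf/NA flags", {
  tab <- data.frame(accession = c("A", "B", "C"), gene = "")
  vals <- list(neg = c(100, 0, 0), exp = c(300, 500, 0))
  for (t in 1:2) {
    tab[[paste0("ctrl.", t)]] <- 0
    tab[[paste0("neg.", t)]] <- vals$neg
    tab[[paste0("exp.", t)]] <- vals$exp
  }
  class(tab) <- c("quant_table", "data.frame")
  attr(tab, "n_trials") <- 2L
  enr <- compute_enrichment(tab)
  expect_equal(enr$enrichment.1, c(3, Inf, NA))
  expect_equal(enr$n_trials_evaluable, c(2L, 2L, 0L))
})

test_that("hit calling follows the N-of-M rule and its oracle exactly", {
  mk_enr <- function(e) {
    df <- data.frame(accession = sprintf("P%02d", seq_len(nrow(e))),
                     gene = "")
    for (t in seq_len(ncol(e))) df[[paste0("enrichment.", t)]] <- e[, t]
    df$n_trials_evaluable <- rowSums(!is.na(e))
    class(df) <- c("enrichment_table", "data.frame")
    attr(df, "n_trials") <- ncol(e)
    df
  }
  # anchor cases
  e <- rbind(c(7, 6.5, 0.9, NA), c(1.6, 1.4, 1.4, 1.4))
  expect_equal(call_hits(mk_enr(e), 6, 2)$hits$accession, "P01")
  expect_equal(call_hits(mk_enr(e), 1.5, 2)$n_hits, 1L)  # P02 passes once only

  # exhaustive-ish oracle over a small enrichment alphabet
  alphabet <- c(0.5, 1.4, 1.6, 5.9, 6.1, Inf, NA)
  set.seed(33)
  for (rep in 1:300) {
    e <- matrix(sample(alphabet, 4 * 4, replace = TRUE), 4, 4)
    for (thr in c(1.5, 6)) for (mt in 1:3) {
      hl <- call_hits(mk_enr(e), thr, mt)
      want <- which(vapply(seq_len(4), function(i)
        hit_oracle(e[i, ], thr, mt), TRUE))
      expect_setequal(hl$hits$accession, sprintf("P%02d", want))
    }
  }

  # monotonicity in threshold and min_trials; 6.0-list nested in 1.5-list
  set.seed(44)
  for (rep in 1:20) {
    g <- generate_quant_table(quant_table_spec(n_proteins = 200,
      n_planted_hits = 20, seed = rep))
    enr <- compute_enrichment(filter_control_enriched(g$table))
    h15 <- call_hits(enr, 1.5, 2)$hits$accession
    h60 <- call_hits(enr, 6, 2)$hits$accession
    h60_3 <- call_hits(enr, 6, 3)$hits$accession
    expect_true(all(h60 %in% h15))
    expect_true(all(h60_3 %in% h60))
  }
})

test_that("motif scanning finds canonical PKA sites and tiers them", {
  h <- scan_pka_motifs("LRRATLV")
  expect_equal(nrow(h), 1L)
  expect_equal(h$position, 5L)
  expect_equal(h$residue, "T")
  expect_equal(h$tier, "strong")
  h2 <- scan_pka_motifs("AARRASLA")
  expect_equal(h2$position, 6L)
  expect_equal(h2$tier, "strong")
  expect_equal(nrow(scan_pka_motifs("AAAAASAA")), 0L)
  expect_equal(nrow(scan_pka_motifs("")), 0L)
  # moderate tiers: RxxS and KRxS; X never matches
  expect_equal(scan_pka_motifs("AARAASAA")$tier, "moderate")
  expect_equal(scan_pka_motifs("AAKRASAA")$tier, "moderate")
  expect_equal(nrow(scan_pka_motifs("AAXRASAA")), 0L)
  expect_equal(nrow(scan_pka_motifs("AARAASAA", min_tier = "strong")), 0L)
  # scores live in [0, 1] and strong sites outscore their moderate stubs
  expect_true(all(h$score >= 0 & h$score <= 1))
  expect_gt(scan_pka_motifs("AARRASAA")$score,
            scan_pka_motifs("AARAASAA")$score)
  # FASTA round trip
  fa <- tempfile(fileext = ".fasta")
  writeLines(c(">prot1 test", "LRRATLV", ">prot2", "AAAAAA"), fa)
  res <- scan_fasta_pka_motifs(fa)
  expect_equal(res$accession, "prot1")
})
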