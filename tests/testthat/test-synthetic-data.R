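# The synthetic RT-stop library generator: determinism, motif planting,
# truncation statistics, and knockout behaviour.

test_that("the generator is deterministic and conserves read depth", {
  cfg <- simulation_config(n_transcripts = 4, depth = 2e4,
                           planted_sites = planted_sites_grid(1:2), seed = 9)
  tx1 <- make_transcriptome(cfg)
  tx2 <- make_transcriptome(cfg)
  expect_identical(tx1$genome$sequence, tx2$genome$sequence)
  expect_identical(tx1$truth, tx2$truth)

  lib1 <- simulate_library(tx1, cfg, "CMC", seed = 33)
  lib2 <- simulate_library(tx1, cfg, "CMC", seed = 33)
  expect_identical(track_df(lib1), track_df(lib2))
  expect_equal(sum(lib1$count), cfg$depth)
  expect_equal(track_total(lib1), cfg$depth)
})

test_that("planted sites carry the recognition motif with the U at position 1", {
  cfg <- simulation_config(n_transcripts = 8, depth = 1000,
                           planted_sites = planted_sites_grid(1:6), seed = 14)
  tx <- make_transcriptome(cfg)
  for (i in seq_len(nrow(tx$truth))) {
    s <- tx$truth[i, ]
    km <- with(s, {
      if (strand == "+") genome_subseq(tx$genome, pos, pos + 5, "+")
      else genome_subseq(tx$genome, pos - 4, pos + 1, "-")
    })
    expect_match(chartr("T", "U", km), "^UU[AG]AA$")
  }
  # the motif count over all transcripts is at least the number planted
  n_motifs <- sum(purrr::map_int(seq_len(nrow(tx$models)), function(i) {
    m <- tx$models[i, ]
    s <- genome_subseq(tx$genome, m$start, m$end, m$strand)
    length(gregexpr("TT[AG](?=AA)", s, perl = TRUE)[[1]])
  }))
  expect_gte(n_motifs, nrow(tx$truth))
})

test_that("zero stop efficiency makes CMC statistically indistinguishable from mock", {
  ps <- planted_sites_grid(1:2, stop_efficiency = 0)
  pvals <- purrr::map_dbl(1:10, function(s) {
    cfg <- simulation_config(n_transcripts = 2, depth = 5e3,
                             planted_sites = ps, end_pileup_weight = 0,
                             seed = 100 + s)
    tx <- make_transcriptome(cfg)
    cmc <- simulate_library(tx, cfg, "CMC", seed = 1000 + s)
    mock <- simulate_library(tx, cfg, "mock", seed = 2000 + s)
    at_peak <- function(trk) {
      near <- unlist(purrr::map(tx$truth$peak_pos, ~.x + (-10:10)))
      sum(trk$count[trk$pos %in% near])
    }
    # two-sample binomial comparison of peak-position mass
    m <- matrix(c(at_peak(cmc), cfg$depth - at_peak(cmc),
                  at_peak(mock), cfg$depth - at_peak(mock)), 2)
    suppressWarnings(stats::chisq.test(m)$p.value)
  })
  expect_gt(min(pvals), 0.01 / 10)  # no seed rejects after Bonferroni
})

test_that("truncation probability at a fully modified site is recovered", {
  # efficiency 1, stoichiometry 1: every read crossing the site stops there,
  # so count(u+1) / reads starting 3' of the site is ~1 within binomial error
  cfg <- simulation_config(
    n_transcripts = 1, transcript_length = 1000, depth = 1e5,
    planted_sites = planted_sites_grid(1, stop_efficiency = 1),
    background_stop_rate = 0, end_pileup_weight = 0, seed = 77
  )
  tx <- make_transcriptome(cfg)
  lib <- simulate_library(tx, cfg, "CMC", seed = 78)
  u <- tx$truth$offset
  peak <- sum(lib$count[lib$pos == tx$truth$peak_pos])
  # fragment 3' starts are uniform, so a fraction (L - 1 - u) / L of reads
  # traverses the U; with eff * stoich = 1 every one of them stops at u + 1
  p_cross <- (1000 - u - 1) / 1000
  se <- sqrt(p_cross * (1 - p_cross) / cfg$depth)
  expect_equal(peak / cfg$depth, p_cross, tolerance = 5 * se / p_cross)
  # every other read runs to the transcript 5' boundary: nothing in between
  upstream <- sum(lib$count[lib$pos - tx$models$start < u + 1 &
                              lib$pos - tx$models$start > 0])
  expect_equal(upstream, 0)
  at_start <- sum(lib$count[lib$pos == tx$models$start])
  expect_equal(peak + at_start, cfg$depth)
})

test_that("knockouts silence their own sites and leave others unchanged in expectation", {
  cfg <- simulation_config(
    n_transcripts = 4, depth = 1e5, background_stop_rate = 0,
    end_pileup_weight = 0, minus_strand_fraction = 0,
    expression = rep(1, 4),
    planted_sites = planted_sites_grid(1:2, enzymes = c("rluA", "rluB"),
                                       stop_efficiency = 1),
    seed = 31
  )
  tx <- make_transcriptome(cfg)
  ko <- simulate_library(tx, cfg, "CMC", knockout = "rluA", seed = 99)
  peak_of <- function(trk, enzyme) {
    p <- tx$truth$peak_pos[tx$truth$enzyme == enzyme]
    sum(trk$count[trk$pos == p])
  }
  expect_equal(peak_of(ko, "rluA"), 0)
  # the rluB site keeps roughly half the reads of its transcript
  # (uniform 3' starts, site at the midpoint, full truncation)
  expect_equal(peak_of(ko, "rluB") / (cfg$depth / 4), 0.5, tolerance = 0.05)
  expect_error(simulate_library(tx, cfg, "CMC", knockout = "nope"),
               "unknown enzyme")
})

test_that("config validation rejects out-of-range parameters", {
  expect_error(simulation_config(planted_sites = tibble::tibble(
    transcript = 5L, offset = 100L, enzyme = "rluA"
  ), n_transcripts = 2), "outside any transcript")
  expect_error(simulation_config(planted_sites = tibble::tibble(
    transcript = 1L, offset = 100L, enzyme = "xyz"
  )), "enzyme")
  expect_error(simulation_config(depth = 0), "depth")
})

test_that("bidseq pileups reflect planted stoichiometry", {
  # stoichiometry 0: deletion rate at the site is just the error rate
  p0 <- simulate_bidseq_pileup(tibble::tibble(pos = 50L, stoichiometry = 0),
                               n_positions = 100, depth = 2e4, seed = 3)
  tr0 <- deletion_trace(p0)
  expect_lt(tr0$rate[tr0$pos == 50], 0.006)

  # stoichiometry 1 with proportionality constant 1: rate ~ 1
  p1 <- simulate_bidseq_pileup(tibble::tibble(pos = 50L, stoichiometry = 1),
                               n_positions = 100, depth = 2e4,
                               prop_const = 1, seed = 4)
  tr1 <- deletion_trace(p1)
  expect_equal(tr1$rate[tr1$pos == 50], 1, tolerance = 0.01)
})
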