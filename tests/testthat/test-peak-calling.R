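# Winsorized Z-score, end-aware window placement, and the CMC-dependence
# decision rule.

test_that("winsorization caps only values above the percentile", {
  expect_equal(winsorize(rep(4, 10)), rep(4, 10))

  # 19 ones and one 100: the 95th-percentile order statistic over 20 values
  # is the 19th, i.e. 1, so the outlier collapses onto the background
  v <- c(rep(1, 19), 100)
  w <- winsorize(v)
  expect_equal(w, rep(1, 20))
  expect_equal(oracle_percentile(v, 0.95), 1)

  # 100 values with six tens at the top: the cap is the 95th order
  # statistic (10), so nothing moves
  v2 <- c(rep(1, 94), rep(10, 6))
  expect_equal(winsorize(v2), v2)
  # ...but five outliers above the cap are pulled down onto it
  v3 <- c(rep(1, 94), 10, rep(500, 5))
  expect_equal(sort(winsorize(v3), decreasing = TRUE)[1:6], rep(10, 6))

  expect_error(winsorize(numeric(0)), "empty")
})

test_that("winsorization is idempotent and bounded by the original p95", {
  set.seed(5)
  for (i in 1:20) {
    v <- rpois(100, sample(c(1, 5, 50), 1)) + sample(0:200, 100, TRUE) *
      rbinom(100, 1, 0.05)
    w <- winsorize(v)
    expect_identical(winsorize(w), w)
    expect_lte(max(w), oracle_percentile(v, 0.95))
  }
})

test_that("compute_z matches a hand-computed alternating background", {
  # 100 background positions alternating 1 and 3: mean 2, population sd 1
  # (the p95 cap of 3 leaves them unchanged); target 22 gives z = 20
  bg_pos <- setdiff(250:350, 300)
  counts <- setNames(rep(c(1, 3), 50), bg_pos)
  trk <- toy_track(c(counts, `300` = 22))
  win <- adjust_background_window(300, toy_models(600))
  expect_false(win$shifted)
  res <- compute_z(trk, win)
  expect_true(res$covered)
  expect_equal(res$z, 20)

  # target equal to the background mean scores zero
  trk0 <- toy_track(c(counts, `300` = 2))
  expect_equal(compute_z(trk0, win)$z, 0)
})

test_that("coverage and degenerate backgrounds leave z undefined", {
  win <- adjust_background_window(300, toy_models(600))
  # 99 reads total with coverage_min 100
  low <- toy_track(setNames(rep(1, 99), setdiff(251:350, 300)))
  res <- compute_z(low, win)
  expect_false(res$covered)
  expect_true(is.na(res$z))
  expect_equal(res$window_reads, 99)

  # constant background: sd is zero, site not callable
  flat <- toy_track(c(setNames(rep(2, 100), setdiff(250:350, 300)), `300` = 50))
  res2 <- compute_z(flat, win)
  expect_true(res2$covered)
  expect_true(is.na(res2$z))
  expect_equal(res2$reason, "degenerate-background")
})

test_that("compute_z agrees with the brute-force oracle on random windows", {
  set.seed(101)
  models <- toy_models(600)
  win <- adjust_background_window(300, models)
  worst <- 0
  for (i in 1:200) {
    lambda <- sample(c(0.5, 2, 20, 200), 1)
    bg <- rpois(100, lambda) + sample(0:500, 100, TRUE) * rbinom(100, 1, 0.03)
    target <- sample(0:2000, 1)
    counts <- setNames(as.numeric(bg), win$background)
    trk <- toy_track(c(counts, setNames(target, "300")))
    got <- compute_z(trk, win)$z
    want <- oracle_z(target, bg)
    if (is.na(want)) {
      expect_true(is.na(got))
    } else {
      worst <- max(worst, abs(got - want))
      expect_equal(got, want, tolerance = 1e-9)
    }
  }
  expect_lt(worst, 1e-9)
})

test_that("z is invariant to positive scaling and monotone in the target", {
  set.seed(33)
  models <- toy_models(600)
  win <- adjust_background_window(300, models)
  bg <- rpois(100, 10)
  base <- toy_track(c(setNames(as.numeric(bg), win$background), `300` = 80))
  z1 <- compute_z(base, win)$z
  for (k in c(2, 7, 100)) {
    scaled <- toy_track(c(setNames(as.numeric(bg * k), win$background),
                          `300` = 80 * k))
    expect_equal(compute_z(scaled, win)$z, z1, tolerance = 1e-9)
  }
  zs <- purrr::map_dbl(c(80, 120, 200, 500), function(t) {
    trk <- toy_track(c(setNames(as.numeric(bg), win$background),
                       setNames(t, "300")))
    compute_z(trk, win)$z
  })
  expect_true(all(diff(zs) > 0))
})

test_that("centred windows are used when no end is nearby", {
  models <- toy_models(600)
  win <- adjust_background_window(300, models)
  expect_false(win$shifted)
  expect_true(win$feasible)
  expect_equal(length(win$background), 100)
  expect_equal(sort(win$background), setdiff(250:350, 300))
})

test_that("windows shift away from transcript ends as specified", {
  # 5' end at 940, target 1000: centred start 950 violates 940 + 40 = 980,
  # so the window becomes [980, 1080] minus the target
  models <- transcript_models(tibble::tibble(
    gene_id = "g", strand = "+", start = 900L, end = 2000L,
    five_prime_ends = list(940L), three_prime_ends = list(1999L)
  ))
  win <- adjust_background_window(1000, models)
  expect_true(win$shifted)
  expect_equal(range(win$background), c(980, 1080))
  expect_false(1000 %in% win$background)

  # downstream 3' end at 1030: centred end 1050 violates 1030 - 25 = 1005,
  # so the window shifts 5'-ward to end at or before 1005
  models2 <- transcript_models(tibble::tibble(
    gene_id = "g", strand = "+", start = 0L, end = 2000L,
    five_prime_ends = list(0L), three_prime_ends = list(c(1030L, 1999L))
  ))
  win2 <- adjust_background_window(1000, models2)
  expect_true(win2$shifted)
  expect_lte(max(win2$background), 1005)
  expect_true(oracle_window_ok(min(win2$background), max(win2$background),
                               ends5 = 0, ends3 = c(1030, 1999)))
})

test_that("an exhaustive grid of end placements yields valid or flagged windows", {
  # single extra end swept within +/-120 nt of the target; every feasible
  # placement must pass the independent four-distance checker
  L <- 1200
  target <- 600
  for (kind in c("five", "three")) {
    for (offset in -120:120) {
      e <- target + offset
      e5 <- c(0L, if (kind == "five") as.integer(e))
      e3 <- c(as.integer(L - 1), if (kind == "three") as.integer(e))
      models <- transcript_models(tibble::tibble(
        gene_id = "g", strand = "+", start = 0L, end = as.integer(L),
        five_prime_ends = list(e5), three_prime_ends = list(e3)
      ))
      win <- adjust_background_window(target, models)
      if (win$feasible) {
        b <- range(win$background)
        expect_true(oracle_window_ok(b[1], b[2], e5, e3),
                    label = sprintf("%s end at %+d", kind, offset))
      } else {
        # the checker must agree that no in-span placement works
        ok_any <- any(vapply(0:(L - 101), function(a) {
          oracle_window_ok(a, a + 100, e5, e3)
        }, logical(1)))
        expect_false(ok_any, label = sprintf("%s end at %+d", kind, offset))
      }
    }
  }
})

test_that("infeasible genes report uncovered sites instead of windows", {
  # a 150-nt gene cannot hold a 100-nt window 40 nt from its 5' end and
  # 25 nt from its 3' end
  models <- toy_models(150)
  win <- adjust_background_window(75, models)
  expect_false(win$feasible)
  trk <- toy_track(setNames(rep(10, 100), 20:119))
  res <- compute_z(trk, win)
  expect_false(res$covered)
  expect_equal(res$reason, "window-infeasible")
})

test_that("the decision rule applies both cutoffs", {
  t <- call_thresholds()
  zr <- function(z, covered = TRUE) {
    structure(list(z = z, covered = covered, window_reads = 1000,
                   p95 = 1, reason = NA), class = "psi_zresult")
  }
  expect_equal(call_cmc_dependent(zr(16), zr(5), t), "called")    # 16 >= 15, 16 >= 15
  expect_equal(call_cmc_dependent(zr(14.9), zr(0), t), "not_called")
  expect_equal(call_cmc_dependent(zr(30), zr(12), t), "not_called")  # 30 < 36
  expect_equal(call_cmc_dependent(zr(30), zr(-4), t), "called")   # mock <= 0
  expect_equal(call_cmc_dependent(zr(30), zr(5, covered = FALSE), t),
               "insufficient")
  expect_equal(call_cmc_dependent(zr(NA), zr(5), t), "insufficient")
})

test_that("empty tracks produce no calls and only insufficient sites", {
  cfg <- simulation_config(n_transcripts = 3, depth = 100, seed = 2)
  tx <- make_transcriptome(cfg)
  empty <- end_track(tibble::tibble(pos = integer(), strand = character(),
                                    count = numeric()))
  sc <- scan_sites(empty, empty, tx$genome, tx$models, keep = "all")
  expect_equal(sum(sc$sites$status == "called"), 0)
  expect_true(all(sc$sites$status == "insufficient"))
})

test_that("Z-scores are invariant under strand reflection of the genome", {
  cfg <- simulation_config(
    n_transcripts = 4, depth = 4e4, minus_strand_fraction = 0,
    planted_sites = planted_sites_grid(c(1, 3)), seed = 21
  )
  tx <- make_transcriptome(cfg)
  panel <- simulate_panel(tx, cfg)
  sc <- scan_sites(panel$cmc, panel$mock, tx$genome, tx$models)

  # reflect: reverse-complement genome, swap strands, mirror coordinates
  L <- genome_length(tx$genome)
  flip_pos <- function(p) L - 1L - p
  genome_rc <- psi_genome("rc", revcomp_chr(tx$genome$sequence))
  models_rc <- transcript_models(tibble::tibble(
    gene_id = tx$models$gene_id,
    strand = ifelse(tx$models$strand == "+", "-", "+"),
    start = L - tx$models$end,
    end = L - tx$models$start,
    five_prime_ends = purrr::map(tx$models$five_prime_ends, flip_pos),
    three_prime_ends = purrr::map(tx$models$three_prime_ends, flip_pos)
  ))
  flip_track <- function(trk) {
    end_track(tibble::tibble(
      pos = flip_pos(trk$pos),
      strand = ifelse(trk$strand == "+", "-", "+"),
      count = trk$count
    ), total_reads = track_total(trk), chrom = "rc")
  }
  sc_rc <- scan_sites(flip_track(panel$cmc), flip_track(panel$mock),
                      genome_rc, models_rc)

  a <- sc$sites |> dplyr::arrange(pos)
  b <- sc_rc$sites |> dplyr::mutate(pos = flip_pos(pos)) |> dplyr::arrange(pos)
  expect_equal(a$pos, b$pos)
  expect_equal(a$z_cmc, b$z_cmc, tolerance = 1e-12)
  expect_equal(a$z_mock, b$z_mock, tolerance = 1e-12)
  expect_equal(a$status, b$status)
})

test_that("per-position Z depends only on counts and ends, not gene labels", {
  cfg <- simulation_config(n_transcripts = 3, depth = 3e4,
                           planted_sites = planted_sites_grid(1), seed = 5)
  tx <- make_transcriptome(cfg)
  panel <- simulate_panel(tx, cfg)
  sc1 <- scan_sites(panel$cmc, panel$mock, tx$genome, tx$models)
  shuffled <- tx$models
  shuffled$gene_id <- rev(shuffled$gene_id)
  sc2 <- scan_sites(panel$cmc, panel$mock, tx$genome, shuffled)
  expect_equal(dplyr::arrange(sc1$sites, pos)$z_cmc,
               dplyr::arrange(sc2$sites, pos)$z_cmc)
})
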