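# Winsorized Z-score peak calling over transcript-end-aware background
# windows, and the CMC-dependence decision rule.
#
# For each uridine the statistic targets the read 5'-end pileup one nucleotide
# downstream (transcript orientation) of the modified U, where reverse
# transcriptase halts at the CMC adduct. Sites are reported at the U itself.

#' Calling thresholds
#'
#' @param z_min Minimum Z-score in the CMC-treated library (default 15).
#' @param mock_fold Required fold-excess of the CMC Z over the mock Z
#'   (default 3).
#' @param coverage_min Minimum reads mapping to the background window
#'   (default 100).
#' @param ko_z_max A knockout peak with Z below this is a candidate absence
#'   (default 10).
#' @param ko_fold Required fold-excess of the WT CMC Z over the knockout Z
#'   for absence (default 4).
#' @return A list of class `psi_thresholds`.
#' @export
call_thresholds <- function(z_min = 15, mock_fold = 3, coverage_min = 100,
                            ko_z_max = 10, ko_fold = 4) {
  vals <- c(z_min = z_min, mock_fold = mock_fold, coverage_min = coverage_min,
            ko_z_max = ko_z_max, ko_fold = ko_fold)
  assert_that(all(vals > 0), "all thresholds must be positive")
  structure(as.list(vals), class = "psi_thresholds")
}

#' Winsorize a vector at a percentile
#'
#' Values above the `pct`-th percentile are replaced by that percentile; all
#' other values are unchanged. The percentile is the sort-based
#' \eqn{\lceil p \cdot n \rceil}-th order statistic (the classical Tukey
#' definition), which makes winsorization exactly idempotent: capping cannot
#' move the capping order statistic, so a second application is a no-op. The
#' target position itself is excluded before calling this, so a genuine peak
#' is never capped.
#'
#' @param values Numeric vector (non-empty).
#' @param pct Percentile in (0, 100]; default 95.
#' @return Numeric vector of the same length.
#' @export
winsorize <- function(values, pct = 95) {
  assert_that(length(values) > 0, "cannot winsorize an empty vector")
  cap <- percentile_sorted(values, pct / 100)
  pmin(values, cap)
}

# Sort-based percentile: the ceil(p * n)-th order statistic; p in (0, 1].
percentile_sorted <- function(x, p) {
  n <- length(x)
  sx <- sort.int(x, method = "quick")
  sx[max(1L, ceiling(p * n))]
}

## ---------------------------------------------------------------------------
## Background window placement

# Disjunctive end-distance feasibility for a candidate window [a, a + wl]
# (inclusive, transcript coordinates). For every annotated transcript 5' end
# e: the window 5' boundary must be >= e + 40 (window fully downstream) OR
# the 3' boundary <= e - 5 (fully upstream). For every 3' end: >= e + 5 OR
# <= e - 25. Ends falling inside the window violate both branches.
END_GAPS <- c(five_down = 40L, five_up = 5L, three_down = 5L, three_up = 25L)

window_feasible <- function(a, wl, ends5, ends3) {
  w3 <- a + wl
  for (e in ends5) {
    if (!(a >= e + END_GAPS[["five_down"]] || w3 <= e - END_GAPS[["five_up"]])) {
      return(FALSE)
    }
  }
  for (e in ends3) {
    if (!(a >= e + END_GAPS[["three_down"]] || w3 <= e - END_GAPS[["three_up"]])) {
      return(FALSE)
    }
  }
  TRUE
}

# Feasible window starts for a whole gene: logical vector over a = 0 ..
# L - 1 - wl (1-indexed entry a + 1). Shared by every target in the gene.
gene_feasible_starts <- function(L, wl, ends5, ends3) {
  n_a <- L - wl  # starts 0 .. L - 1 - wl
  if (n_a <= 0) return(logical(0))
  a <- seq_len(n_a) - 1L
  ok <- rep(TRUE, n_a)
  for (e in ends5) {
    ok <- ok & (a >= e + END_GAPS[["five_down"]] |
                  a + wl <= e - END_GAPS[["five_up"]])
  }
  for (e in ends3) {
    ok <- ok & (a >= e + END_GAPS[["three_down"]] |
                  a + wl <= e - END_GAPS[["three_up"]])
  }
  ok
}

# Choose the window start closest to centred placement; ties break toward the
# transcript 3' direction (larger a). Returns NA when no feasible start.
nearest_feasible_start <- function(a0, feasible_idx) {
  if (!length(feasible_idx)) return(NA_integer_)
  d <- abs(feasible_idx - a0)
  best <- min(d)
  cand <- feasible_idx[d == best]
  max(cand)  # ties toward 3'
}

#' Place the background window for a target position
#'
#' Returns a contiguous window of `window_len` background positions around
#' `target` (the target itself is excluded from the background), positioned
#' as close to centred as possible subject to the transcript-end distance
#' constraints: the window 5' boundary must be at least 40 nt downstream of
#' the nearest upstream transcript 5' end and at least 5 nt downstream of the
#' nearest upstream 3' end; the window 3' boundary must be at least 25 nt
#' upstream of the nearest downstream 3' end and at least 5 nt upstream of
#' the nearest downstream 5' end. The window must also lie within the gene
#' span. Ties in displacement break toward the transcript 3' direction.
#'
#' @param target 0-based genomic position the statistic targets (the read
#'   5'-end pileup position, i.e. one nt downstream of a candidate U).
#' @param models A [transcript_models()] table.
#' @param strand Strand of the target.
#' @param window_len Background window size in nt (default 100).
#' @return A list of class `psi_window`: `target`, `background` (genomic
#'   positions), `window_len`, `shifted`, `feasible`, `strand`, `gene_id`.
#'   When no placement satisfies the constraints, `feasible = FALSE` and
#'   `background` is empty.
#' @export
adjust_background_window <- function(target, models, strand = "+",
                                     window_len = 100) {
  gi <- containing_gene(models, target, strand)
  assert_that(!is.na(gi), "target is not within any annotated gene span")
  m <- models[gi, , drop = FALSE]
  L <- m$end - m$start
  x <- to_tx_coord(target, m$strand, m$start, m$end)
  ends5 <- vapply(m$five_prime_ends[[1]], to_tx_coord, integer(1) * 1,
                  strand = m$strand, start = m$start, end = m$end)
  ends3 <- vapply(m$three_prime_ends[[1]], to_tx_coord, integer(1) * 1,
                  strand = m$strand, start = m$start, end = m$end)
  # include ends of other same-strand genes overlapping this span
  others <- which(models$strand == m$strand & models$gene_id != m$gene_id &
                    models$start < m$end & models$end > m$start)
  for (oi in others) {
    ends5 <- c(ends5, vapply(models$five_prime_ends[[oi]], to_tx_coord,
                             numeric(1), strand = m$strand, start = m$start,
                             end = m$end))
    ends3 <- c(ends3, vapply(models$three_prime_ends[[oi]], to_tx_coord,
                             numeric(1), strand = m$strand, start = m$start,
                             end = m$end))
  }
  ok <- gene_feasible_starts(L, window_len, ends5, ends3)
  a0 <- x - window_len %/% 2L
  a <- nearest_feasible_start(a0, which(ok) - 1L)
  if (is.na(a)) {
    return(structure(list(
      target = target, background = integer(0), window_len = window_len,
      shifted = NA, feasible = FALSE, strand = strand, gene_id = m$gene_id
    ), class = "psi_window"))
  }
  span <- a:(a + window_len)  # wl + 1 positions including (possibly) target
  bg <- setdiff(span, x)
  bg <- bg[seq_len(window_len)]  # exactly wl background positions
  bg_g <- vapply(bg, to_genomic_coord, numeric(1),
                 strand = m$strand, start = m$start, end = m$end)
  structure(list(
    target = target, background = as.integer(sort(bg_g)),
    window_len = window_len, shifted = a != a0, feasible = TRUE,
    strand = strand, gene_id = m$gene_id
  ), class = "psi_window")
}

## ---------------------------------------------------------------------------
## Z computation

# Core kernel shared by compute_z() and the transcriptome scan.
# target_count: count at the target; bg: background counts (length wl).
z_kernel <- function(target_count, bg, coverage_min) {
  window_reads <- target_count + sum(bg)
  if (window_reads < coverage_min) {
    return(list(z = NA_real_, window_reads = window_reads, covered = FALSE,
                p95 = NA_real_, reason = "low-coverage"))
  }
  p95 <- percentile_sorted(bg, 0.95)
  w <- pmin(bg, p95)
  m <- mean(w)
  s <- sqrt(mean((w - m)^2))  # population sd
  if (s <= 0) {
    return(list(z = NA_real_, window_reads = window_reads, covered = TRUE,
                p95 = p95, reason = "degenerate-background"))
  }
  list(z = (target_count - m) / s, window_reads = window_reads, covered = TRUE,
       p95 = p95, reason = NA_character_)
}

#' Winsorized Z-score of a target position against its background window
#'
#' `window_reads` counts reads over the background plus the target; if fewer
#' than `coverage_min` the site is uncovered and Z is undefined. Otherwise the
#' background is 95%-winsorized (the target is never capped) and
#' `z = (count[target] - mean) / sd` with a population-sd denominator. A
#' zero-dispersion background leaves Z undefined with reason
#' `"degenerate-background"`.
#'
#' @param track A `psi_track` (or plain tibble with `pos`, `strand`, `count`).
#' @param window A `psi_window` from [adjust_background_window()].
#' @param coverage_min Window coverage cutoff (default 100).
#' @return A list of class `psi_zresult`: `z`, `window_reads`, `covered`,
#'   `p95`, `reason`.
#' @export
compute_z <- function(track, window, coverage_min = 100) {
  assert_that(inherits(window, "psi_window"), "window must be a psi_window")
  if (!isTRUE(window$feasible)) {
    return(structure(list(z = NA_real_, window_reads = 0, covered = FALSE,
                          p95 = NA_real_, reason = "window-infeasible"),
                     class = "psi_zresult"))
  }
  rows <- track[track$strand == window$strand, , drop = FALSE]
  cnt <- setNames(rows$count, rows$pos)
  at <- function(p) {
    v <- unname(cnt[as.character(p)])
    ifelse(is.na(v), 0, v)
  }
  res <- z_kernel(at(window$target), as.numeric(at(window$background)),
                  coverage_min)
  structure(res, class = "psi_zresult")
}

#' @export
print.psi_zresult <- function(x, ...) {
  cat(sprintf("<psi_zresult> z=%s window_reads=%g covered=%s%s\n",
              ifelse(is.na(x$z), "NA", sprintf("%.3f", x$z)),
              x$window_reads, x$covered,
              ifelse(is.na(x$reason), "", paste0(" (", x$reason, ")"))))
  invisible(x)
}

#' CMC-dependence decision rule
#'
#' A site is `called` when both libraries are covered, the CMC-treated Z-score
#' reaches `z_min`, and it is at least `mock_fold` times the mock-treated
#' Z-score (a mock Z at or below zero satisfies the fold condition).
#' `insufficient` when either library lacks window coverage or Z is undefined.
#'
#' @param cmc,mock `psi_zresult`s for the same target.
#' @param thresholds A [call_thresholds()].
#' @return `"called"`, `"not_called"`, or `"insufficient"`.
#' @export
call_cmc_dependent <- function(cmc, mock, thresholds = call_thresholds()) {
  if (!isTRUE(cmc$covered) || !isTRUE(mock$covered) ||
      is.na(cmc$z) || is.na(mock$z)) {
    return("insufficient")
  }
  fold_ok <- mock$z <= 0 || cmc$z >= thresholds$mock_fold * mock$z
  if (cmc$z >= thresholds$z_min && fold_ok) "called" else "not_called"
}

## ---------------------------------------------------------------------------
## Transcriptome scan

#' Scan every uridine in annotated genes and call CMC-dependent peaks
#'
#' Iterates all strand-aware T/U positions within annotated gene spans,
#' computes the winsorized Z-score at the expected RT-stop position (one nt
#' downstream of the U in transcript orientation) in the CMC-treated and
#' mock-treated libraries over a shared end-aware background window, and
#' applies the decision rule. Sites are reported at the modified U, not at
#' the pileup position.
#'
#' @param cmc,mock `psi_track`s for the CMC-treated and mock-treated library.
#' @param genome A [psi_genome()].
#' @param models A [transcript_models()] table.
#' @param thresholds A [call_thresholds()].
#' @param window_len Background window size (default 100).
#' @param keep `"covered"` (default) returns rows for every uridine covered in
#'   at least one library plus all called sites; `"called"` only called
#'   sites; `"all"` every scanned uridine.
#' @return An object of class `psi_scan`: list with `sites` (tibble; columns
#'   `gene_id`, `pos` (U), `peak_pos`, `strand`, `z_cmc`, `z_mock`,
#'   `window_reads_cmc`, `window_reads_mock`, `covered_cmc`, `covered_mock`,
#'   `shifted`, `status`), `thresholds`, `window_len`, and scan metadata.
#' @export
scan_sites <- function(cmc, mock, genome, models,
                       thresholds = call_thresholds(), window_len = 100,
                       keep = c("covered", "called", "all")) {
  keep <- match.arg(keep)
  assert_that(!is.null(mock), "a mock-treated track is required")
  glen <- genome_length(genome)
  vec <- list(
    cmc = list(`+` = track_vector(cmc, "+", glen),
               `-` = track_vector(cmc, "-", glen)),
    mock = list(`+` = track_vector(mock, "+", glen),
                `-` = track_vector(mock, "-", glen))
  )
  out <- purrr::map(seq_len(nrow(models)), function(gi) {
    scan_gene(gi, vec, genome, models, thresholds, window_len)
  })
  sites <- dplyr::bind_rows(out)
  if (keep == "covered") {
    sites <- sites[sites$covered_cmc | sites$covered_mock |
                     sites$status == "called", , drop = FALSE]
  } else if (keep == "called") {
    sites <- sites[sites$status == "called", , drop = FALSE]
  }
  structure(list(
    sites = sites, thresholds = thresholds, window_len = window_len,
    n_uridines_scanned = sum(purrr::map_int(out, nrow)),
    libraries = c(cmc = track_label(cmc), mock = track_label(mock))
  ), class = "psi_scan")
}

# Scan one gene. vec: list(cmc = list(`+`, `-`), mock = ...) dense count
# vectors over the genome.
scan_gene <- function(gi, vec, genome, models, thresholds, window_len) {
  m <- models[gi, , drop = FALSE]
  L <- m$end - m$start
  if (L <= window_len) return(NULL)
  seq_tx <- genome_subseq(genome, m$start, m$end, m$strand)
  u_tx <- which(strsplit(seq_tx, "")[[1]] == "T") - 1L  # transcript coords
  u_tx <- u_tx[u_tx + 1L <= L - 1L]  # pileup position must exist
  if (!length(u_tx)) return(NULL)

  # transcript-oriented count vectors for this gene
  idx <- (m$start + 1L):m$end
  v_cmc <- vec$cmc[[m$strand]][idx]
  v_mock <- vec$mock[[m$strand]][idx]
  if (m$strand == "-") {
    v_cmc <- rev(v_cmc)
    v_mock <- rev(v_mock)
  }

  ends5 <- vapply(m$five_prime_ends[[1]], to_tx_coord, numeric(1),
                  strand = m$strand, start = m$start, end = m$end)
  ends3 <- vapply(m$three_prime_ends[[1]], to_tx_coord, numeric(1),
                  strand = m$strand, start = m$start, end = m$end)
  ok <- gene_feasible_starts(L, window_len, ends5, ends3)
  feas_idx <- which(ok) - 1L

  S_cmc <- cumsum(c(0, v_cmc))
  S_mock <- cumsum(c(0, v_mock))
  half <- window_len %/% 2L

  nu <- length(u_tx)
  z_cmc <- rep(NA_real_, nu); z_mock <- rep(NA_real_, nu)
  wr_cmc <- numeric(nu); wr_mock <- numeric(nu)
  cov_cmc <- logical(nu); cov_mock <- logical(nu)
  shifted <- rep(NA, nu)
  for (k in seq_len(nu)) {
    p <- u_tx[k] + 1L  # target: expected RT-stop pileup position
    a0 <- p - half
    a <- nearest_feasible_start(a0, feas_idx)
    if (is.na(a)) next
    shifted[k] <- a != a0
    span_cmc <- S_cmc[a + window_len + 2L] - S_cmc[a + 1L]
    span_mock <- S_mock[a + window_len + 2L] - S_mock[a + 1L]
    wr_cmc[k] <- span_cmc
    wr_mock[k] <- span_mock
    # quick coverage prefilter: neither library can reach coverage_min
    if (max(span_cmc, span_mock) + v_cmc[p + 1L] + v_mock[p + 1L] <
          thresholds$coverage_min) {
      next
    }
    span <- a:(a + window_len)
    bg_pos <- span[span != p]
    bg_pos <- bg_pos[seq_len(window_len)]
    zc <- z_kernel(v_cmc[p + 1L], v_cmc[bg_pos + 1L], thresholds$coverage_min)
    zm <- z_kernel(v_mock[p + 1L], v_mock[bg_pos + 1L], thresholds$coverage_min)
    z_cmc[k] <- zc$z; z_mock[k] <- zm$z
    wr_cmc[k] <- zc$window_reads; wr_mock[k] <- zm$window_reads
    cov_cmc[k] <- zc$covered; cov_mock[k] <- zm$covered
  }
  df <- tibble::tibble(
    u_tx = u_tx, z_cmc = z_cmc, z_mock = z_mock,
    wr_cmc = wr_cmc, wr_mock = wr_mock,
    cov_cmc = cov_cmc, cov_mock = cov_mock, shifted = shifted
  )
  status <- dplyr::case_when(
    !df$cov_cmc | !df$cov_mock | is.na(df$z_cmc) | is.na(df$z_mock) ~
      "insufficient",
    df$z_cmc >= thresholds$z_min &
      (df$z_mock <= 0 | df$z_cmc >= thresholds$mock_fold * df$z_mock) ~
      "called",
    TRUE ~ "not_called"
  )
  tibble::tibble(
    gene_id = m$gene_id,
    pos = to_genomic_coord(df$u_tx, m$strand, m$start, m$end),
    peak_pos = to_genomic_coord(df$u_tx + 1L, m$strand, m$start, m$end),
    strand = m$strand,
    z_cmc = df$z_cmc, z_mock = df$z_mock,
    window_reads_cmc = df$wr_cmc, window_reads_mock = df$wr_mock,
    covered_cmc = df$cov_cmc, covered_mock = df$cov_mock,
    shifted = df$shifted, status = status
  )
}

#' Called sites from a scan
#'
#' @param scan A `psi_scan`.
#' @return Tibble of rows with `status == "called"`.
#' @export
called_sites <- function(scan) {
  scan$sites[scan$sites$status == "called", , drop = FALSE]
}

#' @export
print.psi_scan <- function(x, ...) {
  cat(sprintf(
    "<psi_scan> %d uridines scanned, %d covered rows, %d called\n",
    x$n_uridines_scanned, nrow(x$sites), sum(x$sites$status == "called")
  ))
  invisible(x)
}
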