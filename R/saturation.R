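# Pooling, read-level subsampling, and saturation curves: how the number of
# called peaks grows with sequencing depth.

#' Pool end-count tracks
#'
#' Per-position counts and library totals are summed; order-invariant.
#'
#' @param tracks List of `psi_track`s over the same genome.
#' @param library_label Label for the pooled track.
#' @return A `psi_track`.
#' @export
pool_tracks <- function(tracks, library_label = "pool") {
  assert_that(length(tracks) >= 1, "need at least one track to pool")
  chroms <- unique(stats::na.omit(purrr::map_chr(tracks, track_chrom)))
  assert_that(length(chroms) <= 1, "tracks map to different genomes")
  df <- dplyr::bind_rows(purrr::map(tracks, tibble::as_tibble)) |>
    dplyr::group_by(.data$pos, .data$strand) |>
    dplyr::summarise(count = sum(.data$count), .groups = "drop")
  end_track(df, library_label = library_label,
            total_reads = sum(purrr::map_dbl(tracks, track_total)),
            chrom = if (length(chroms)) chroms else NA_character_)
}

#' Subsample a track to an exact read depth
#'
#' Draws exactly `depth` reads without replacement from the multiset of
#' (position, strand) read records — a multivariate hypergeometric draw,
#' realised as a chain of univariate hypergeometric draws over positions.
#' Deterministic given `seed`.
#'
#' @param track A `psi_track`.
#' @param depth Number of reads to keep (`0 <= depth <=` summed counts).
#' @param seed Integer seed.
#' @return A `psi_track` with `total_reads = depth`.
#' @export
subsample_track <- function(track, depth, seed = 1) {
  depth <- as.numeric(depth)
  n_avail <- sum(track$count)
  assert_that(depth <= n_avail, "depth exceeds the reads available in the track")
  assert_that(depth >= 0, "depth must be non-negative")
  df <- dplyr::arrange(tibble::as_tibble(track), .data$strand, .data$pos)
  with_seed(seed, {
    counts <- df$count
    kept <- numeric(length(counts))
    remaining_total <- n_avail
    remaining_draw <- depth
    for (i in seq_along(counts)) {
      if (remaining_draw <= 0) break
      # draws from this position given what must still be drawn overall
      k <- rhyper(1, counts[i], remaining_total - counts[i], remaining_draw)
      kept[i] <- k
      remaining_draw <- remaining_draw - k
      remaining_total <- remaining_total - counts[i]
    }
    df$count <- kept
    end_track(df, library_label = sprintf("%s@%g", track_label(track), depth),
              total_reads = depth, chrom = track_chrom(track))
  })
}

#' Saturation analysis: peaks called across a depth ladder
#'
#' Subsamples the pooled CMC library to each depth (the mock pool is
#' subsampled to the same fraction of its total so treated/mock ratios stay
#' comparable), re-calls peaks at default thresholds, and reports the number
#' of peaks per depth and the cumulative number of unique (position, strand)
#' peaks accumulated across the ladder.
#'
#' @param pool Pooled CMC-treated `psi_track`.
#' @param depths Increasing integer vector of subsample depths.
#' @param mock_pool Pooled mock-treated `psi_track`.
#' @param genome,models,thresholds,window_len Passed to [scan_sites()].
#' @param seed Integer seed (one independent subsample per depth).
#' @return A `psi_saturation`: list with `curve` (tibble: `depth`,
#'   `peaks_at_depth`, `cumulative_unique`), `calls` (per-depth called
#'   sites), and `seed`.
#' @export
saturation_curve <- function(pool, depths, mock_pool, genome, models,
                             thresholds = call_thresholds(),
                             window_len = 100, seed = 1) {
  assert_that(!is.unsorted(depths, strictly = TRUE),
              "depths must be strictly increasing")
  assert_that(max(depths) <= sum(pool$count), "a depth exceeds the pool")
  mock_total <- sum(mock_pool$count)
  pool_total <- sum(pool$count)
  seen <- character(0)
  rows <- vector("list", length(depths))
  calls <- vector("list", length(depths))
  for (i in seq_along(depths)) {
    d <- depths[i]
    cmc_i <- subsample_track(pool, d, seed = child_seed(seed, 2L * i))
    mock_d <- round(mock_total * d / pool_total)
    mock_i <- subsample_track(mock_pool, min(mock_d, mock_total),
                              seed = child_seed(seed, 2L * i + 1L))
    sc <- scan_sites(cmc_i, mock_i, genome, models, thresholds,
                     window_len = window_len, keep = "called")
    hits <- sc$sites
    key <- sprintf("%d%s", hits$pos, hits$strand)
    seen <- union(seen, key)
    rows[[i]] <- tibble::tibble(
      depth = d, peaks_at_depth = nrow(hits),
      cumulative_unique = length(seen)
    )
    calls[[i]] <- hits
  }
  structure(list(
    curve = dplyr::bind_rows(rows), calls = calls, seed = seed
  ), class = "psi_saturation")
}

#' @export
print.psi_saturation <- function(x, ...) {
  cat("<psi_saturation>\n")
  print(x$curve)
  invisible(x)
}
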