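# broom-style tidiers and ggplot2 autoplot methods for result objects.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a transcriptome scan
#'
#' @param x A `psi_scan`.
#' @param ... Unused.
#' @return The per-uridine site table as a tibble.
#' @export
tidy.psi_scan <- function(x, ...) tibble::as_tibble(x$sites)

#' One-row summary of a transcriptome scan
#'
#' @param x A `psi_scan`.
#' @param ... Unused.
#' @return Tibble with scan counts and the thresholds used.
#' @export
glance.psi_scan <- function(x, ...) {
  tibble::tibble(
    n_uridines_scanned = x$n_uridines_scanned,
    n_covered = sum(x$sites$covered_cmc & x$sites$covered_mock),
    n_called = sum(x$sites$status == "called"),
    n_assigned = if ("assignment" %in% names(x$sites)) {
      sum(x$sites$assignment == "assigned")
    } else {
      NA_integer_
    },
    z_min = x$thresholds$z_min,
    mock_fold = x$thresholds$mock_fold,
    coverage_min = x$thresholds$coverage_min,
    window_len = x$window_len
  )
}

#' Tidy a saturation analysis
#'
#' @param x A `psi_saturation`.
#' @param ... Unused.
#' @return The depth/peak-count curve as a tibble.
#' @export
tidy.psi_saturation <- function(x, ...) tibble::as_tibble(x$curve)

#' One-row summary of a saturation analysis
#'
#' @param x A `psi_saturation`.
#' @param ... Unused.
#' @return Tibble with the deepest depth, its peak count, and the cumulative
#'   unique total.
#' @export
glance.psi_saturation <- function(x, ...) {
  tibble::tibble(
    max_depth = max(x$curve$depth),
    peaks_at_max_depth = x$curve$peaks_at_depth[which.max(x$curve$depth)],
    cumulative_unique = max(x$curve$cumulative_unique),
    n_depths = nrow(x$curve),
    seed = x$seed
  )
}

#' Plot a saturation curve
#'
#' Two panels: peaks called at each subsample depth, and the cumulative
#' number of unique peaks across the ladder.
#'
#' @param object A `psi_saturation`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.psi_saturation <- function(object, ...) {
  df <- object$curve |>
    tidyr::pivot_longer(c("peaks_at_depth", "cumulative_unique"),
                        names_to = "panel", values_to = "peaks") |>
    dplyr::mutate(panel = dplyr::recode(.data$panel,
      peaks_at_depth = "peaks per subsample",
      cumulative_unique = "cumulative unique peaks"
    ))
  ggplot2::ggplot(df, ggplot2::aes(.data$depth, .data$peaks)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::scale_x_log10() +
    ggplot2::facet_wrap(~panel, ncol = 1, scales = "free_y") +
    ggplot2::labs(x = "mRNA-mapping reads (subsample depth)",
                  y = "CMC-dependent peaks") +
    ggplot2::theme_bw()
}

#' Plot pairing-probability distributions by relative position
#'
#' Median pairing probability with an interquartile ribbon at each offset
#' relative to the site; multiple summaries (e.g. target vs background) can
#' be overlaid via `...`.
#'
#' @param object A `psi_pairing_summary`.
#' @param ... Further `psi_pairing_summary` objects to overlay.
#' @return A ggplot object.
#' @export
autoplot.psi_pairing_summary <- function(object, ...) {
  extra <- list(...)
  extra <- extra[purrr::map_lgl(extra, inherits, "psi_pairing_summary")]
  df <- dplyr::bind_rows(c(list(object$summary),
                           purrr::map(extra, "summary")))
  ggplot2::ggplot(df, ggplot2::aes(.data$offset, .data$median,
                                   colour = .data$group,
                                   fill = .data$group)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$q25, ymax = .data$q75),
                         alpha = 0.25, colour = NA) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "position relative to Ψ",
                  y = "pairing probability") +
    ggplot2::theme_bw()
}

#' Plot a position-frequency matrix
#'
#' Stacked per-base frequencies at each offset relative to the site, the
#' tabular counterpart of a sequence logo.
#'
#' @param pfm Matrix from [position_frequency()].
#' @return A ggplot object.
#' @export
plot_position_frequency <- function(pfm) {
  df <- tibble::as_tibble(pfm, rownames = "base") |>
    tidyr::pivot_longer(-"base", names_to = "offset", values_to = "count") |>
    dplyr::mutate(offset = as.integer(.data$offset),
                  freq = .data$count / sum(pfm[, 1]))
  ggplot2::ggplot(df, ggplot2::aes(.data$offset, .data$freq,
                                   fill = .data$base)) +
    ggplot2::geom_col(width = 0.85) +
    ggplot2::labs(x = "position relative to Ψ", y = "frequency",
                  fill = NULL) +
    ggplot2::theme_bw()
}

#' Plot a count track around a position
#'
#' Read 5'-end counts near a site, one panel per library, with the expected
#' RT-stop position marked.
#'
#' @param tracks Named list of `psi_track`s.
#' @param pos Centre position (e.g. a called U).
#' @param strand Strand to show.
#' @param flank Flank size in nt.
#' @return A ggplot object.
#' @export
plot_track_window <- function(tracks, pos, strand = "+", flank = 50) {
  df <- purrr::imap(tracks, function(trk, nm) {
    rows <- trk[trk$strand == strand &
                  trk$pos >= pos - flank & trk$pos <= pos + flank, ,
                drop = FALSE]
    tibble::tibble(library = nm, pos = rows$pos, count = rows$count)
  }) |> dplyr::bind_rows()
  ggplot2::ggplot(df, ggplot2::aes(.data$pos, .data$count)) +
    ggplot2::geom_col(width = 1) +
    ggplot2::geom_vline(xintercept = pos, linetype = 2, colour = "red") +
    ggplot2::facet_wrap(~library, ncol = 1, scales = "free_y") +
    ggplot2::labs(x = "genomic position", y = "read 5' ends") +
    ggplot2::theme_bw()
}
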