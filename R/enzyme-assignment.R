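# Assign called pseudouridine sites to synthases via knockout signal loss.

#' Knockout absence test for one site
#'
#' A peak is `absent` from a knockout library when all three criteria hold:
#' (1) the knockout window has sufficient coverage, (2) the knockout peak
#' Z-score is below `ko_z_max` (default 10), and (3) the WT CMC Z-score is at
#' least `ko_fold` (default 4) times the knockout Z (a knockout Z at or below
#' zero satisfies the fold condition). A covered knockout failing either
#' Z criterion shows the peak (`present`); an uncovered one is
#' `insufficient`.
#'
#' @param wt,ko `psi_zresult`s for the same target in the WT CMC and knockout
#'   CMC libraries.
#' @param thresholds A [call_thresholds()].
#' @return `"absent"`, `"present"`, or `"insufficient"`.
#' @export
knockout_absence <- function(wt, ko, thresholds = call_thresholds()) {
  if (!isTRUE(ko$covered) || is.na(ko$z)) return("insufficient")
  fold_ok <- ko$z <= 0 || wt$z >= thresholds$ko_fold * ko$z
  if (ko$z < thresholds$ko_z_max && fold_ok) "absent" else "present"
}

# Vectorised version used by assign_enzymes(); NA z with covered TRUE is
# degenerate-background and treated as insufficient.
ko_absence_vec <- function(wt_z, ko_z, ko_cov, thresholds) {
  dplyr::case_when(
    !ko_cov | is.na(ko_z) ~ "insufficient",
    ko_z < thresholds$ko_z_max &
      (ko_z <= 0 | wt_z >= thresholds$ko_fold * ko_z) ~ "absent",
    TRUE ~ "present"
  )
}

#' Assign called sites to pseudouridine synthases
#'
#' Computes the winsorized Z-score for every called site in each knockout
#' library (same background windows as the WT scan) and classifies each site:
#' `assigned` when the peak is absent from exactly one knockout and present
#' in all others; `ambiguous` when absent from two or more; otherwise
#' `unassigned` (peak present wherever covered, or coverage missing in some
#' knockout). Supplying fewer than the full panel of knockouts triggers a
#' warning and the unavailable enzymes are recorded under
#' `low_coverage_in`.
#'
#' @param scan A `psi_scan` from [scan_sites()].
#' @param ko_tracks Named list of `psi_track`s, one per knockout enzyme
#'   (names are enzyme names).
#' @param genome,models The same genome and models used for the scan.
#' @param thresholds A [call_thresholds()] (defaults to the scan's).
#' @param n_expected Expected size of the knockout panel (default 11).
#' @return A `psi_scan` whose `sites` gains columns `assignment`
#'   (`assigned`/`ambiguous`/`unassigned`/`none`), `enzyme`, `absent_in`,
#'   `low_coverage_in` (list columns), and `z_<enzyme>` per knockout.
#'   Rows not called keep `assignment = "none"`.
#' @export
assign_enzymes <- function(scan, ko_tracks, genome, models,
                           thresholds = scan$thresholds, n_expected = 11) {
  assert_that(length(names(ko_tracks)) == length(ko_tracks) &&
                all(nzchar(names(ko_tracks))),
              "ko_tracks must be a named list (names are enzyme names)")
  if (length(ko_tracks) < n_expected) {
    warn(sprintf(
      "only %d of %d knockout libraries supplied; assignment computed on the available set",
      length(ko_tracks), n_expected
    ))
  }
  sites <- scan$sites
  called <- which(sites$status == "called")
  enzymes <- names(ko_tracks)
  glen <- genome_length(genome)
  wl <- scan$window_len

  # per-knockout Z at each called site, reusing the WT window placement
  zmat <- matrix(NA_real_, nrow(sites), length(enzymes),
                 dimnames = list(NULL, enzymes))
  covmat <- matrix(FALSE, nrow(sites), length(enzymes))
  for (j in seq_along(enzymes)) {
    trk <- ko_tracks[[j]]
    vecs <- list(`+` = track_vector(trk, "+", glen),
                 `-` = track_vector(trk, "-", glen))
    for (i in called) {
      win <- adjust_background_window(sites$peak_pos[i], models,
                                      strand = sites$strand[i],
                                      window_len = wl)
      if (!win$feasible) next
      v <- vecs[[sites$strand[i]]]
      res <- z_kernel(v[win$target + 1L], v[win$background + 1L],
                      thresholds$coverage_min)
      zmat[i, j] <- res$z
      covmat[i, j] <- res$covered
    }
  }

  sites$assignment <- "none"
  sites$enzyme <- NA_character_
  sites$absent_in <- rep(list(character(0)), nrow(sites))
  sites$low_coverage_in <- rep(list(character(0)), nrow(sites))
  missing_panel <- if (length(ko_tracks) < n_expected) {
    sprintf("panel_missing_%d", seq_len(n_expected - length(ko_tracks)))
  } else {
    character(0)
  }

  for (i in called) {
    status <- ko_absence_vec(sites$z_cmc[i], zmat[i, ], covmat[i, ], thresholds)
    absent <- enzymes[status == "absent"]
    insuff <- c(enzymes[status == "insufficient"], missing_panel)
    sites$absent_in[[i]] <- absent
    sites$low_coverage_in[[i]] <- insuff
    if (length(absent) >= 2) {
      sites$assignment[i] <- "ambiguous"
    } else if (length(absent) == 1 && length(insuff) == 0) {
      sites$assignment[i] <- "assigned"
      sites$enzyme[i] <- absent
    } else {
      sites$assignment[i] <- "unassigned"
    }
  }
  for (j in seq_along(enzymes)) {
    sites[[paste0("z_", enzymes[j])]] <- zmat[, j]
  }
  scan$sites <- sites
  scan$knockouts <- enzymes
  scan
}
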