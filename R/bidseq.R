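# Targeted bisulfite-sequencing validation: per-position deletion rates and
# site-level signal. Bisulfite chemistry converts pseudouridine into a 1-2 nt
# deletion whose frequency scales with modification stoichiometry.

#' Per-position deletion rates from a pileup
#'
#' @param pileup Tibble with columns `pos`, `depth`, `deletions` (deletion
#'   events counted at their 5'-most position).
#' @return Tibble adding `rate = deletions / depth` (`NA` where depth is 0).
#' @export
deletion_trace <- function(pileup) {
  pileup <- tibble::as_tibble(pileup)
  assert_that(all(c("pos", "depth", "deletions") %in% names(pileup)),
              "pileup needs columns pos, depth, deletions")
  assert_that(all(pileup$depth >= 0), "depth must be non-negative")
  assert_that(all(pileup$deletions <= pileup$depth),
              "deletions cannot exceed depth")
  dplyr::mutate(
    pileup,
    rate = ifelse(.data$depth > 0, .data$deletions / .data$depth, NA_real_)
  )
}

#' Site-level deletion signal
#'
#' The maximum deletion rate within `halfwidth` nt of the site, capturing the
#' 1-2 nt register spread of the deletion signature. Positions with undefined
#' rates are ignored; a window with no defined rate returns `NA`.
#'
#' @param trace A [deletion_trace()] result.
#' @param site 0-based position of the candidate site.
#' @param halfwidth Search radius in nt (default 2).
#' @return A number in \[0, 1\], or `NA`.
#' @export
site_signal <- function(trace, site, halfwidth = 2) {
  assert_that(site >= min(trace$pos) && site <= max(trace$pos),
              "site outside the trace")
  sel <- trace$pos >= site - halfwidth & trace$pos <= site + halfwidth
  rates <- trace$rate[sel]
  rates <- rates[!is.na(rates)]
  if (!length(rates)) return(NA_real_)
  max(rates)
}

#' Read / write deletion pileup TSV
#'
#' Plain TSV with columns `pos`, `depth`, `deletions`, as produced externally
#' from alignments or by [simulate_bidseq_pileup()].
#'
#' @param path TSV file.
#' @return `read_pileup_tsv()`: a pileup tibble.
#' @export
read_pileup_tsv <- function(path) {
  readr::read_tsv(path, col_types = "iii", progress = FALSE)
}

#' @rdname read_pileup_tsv
#' @param pileup A pileup tibble.
#' @export
write_pileup_tsv <- function(pileup, path) {
  readr::write_tsv(pileup, path, progress = FALSE)
  invisible(path)
}
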