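# Synthetic RT-stop library generator: transcriptomes with planted
# pseudouridine sites, CMC/mock/knockout 5'-end count tracks, and targeted
# bisulfite-sequencing deletion pileups with known ground truth.

# The eleven E. coli pseudouridine synthases.
PSI_SYNTHASES <- c("rluA", "rluB", "rluC", "rluD", "rluE", "rluF",
                   "rsuA", "truA", "truB", "truC", "truD")

#' Simulation configuration for synthetic RT-stop libraries
#'
#' Defines the study conditions for the generator: the transcriptome
#' (transcript count, lengths, log-normal expression), the planted
#' pseudouridine sites (enzyme, stop efficiency, stoichiometry), the noise
#' model, and sequencing depth.
#'
#' @param n_transcripts Number of transcripts.
#' @param transcript_length Length of each transcript in nt (scalar or vector).
#' @param expression Relative expression weights, one per transcript, or
#'   `NULL` to draw log-normal weights (`meanlog`, `sdlog`).
#' @param meanlog,sdlog Log-normal expression parameters used when
#'   `expression` is `NULL`.
#' @param planted_sites Tibble with columns `transcript` (1-based index),
#'   `offset` (0-based transcript coordinate of the modified U), `enzyme`
#'   (one of the eleven synthase names), and optionally `stop_efficiency`,
#'   `stoichiometry` (default 0.8 and 1).
#' @param background_stop_rate Per-position probability that reverse
#'   transcription terminates for reasons unrelated to the modification.
#' @param end_pileup_weight Fraction of reads whose 5' end falls exactly at
#'   the transcript 5' boundary, emulating transcript-end read pileups.
#' @param depth Total reads per simulated library.
#' @param intergenic Gap between transcripts on the synthetic genome.
#' @param minus_strand_fraction Fraction of transcripts placed on the minus
#'   strand (alternating placement, deterministic).
#' @param seed Integer seed; all generator randomness flows from it.
#' @return A list of class `psi_sim_config`.
#' @export
simulation_config <- function(n_transcripts = 20, transcript_length = 1000,
                              expression = NULL, meanlog = log(100), sdlog = 1,
                              planted_sites = NULL,
                              background_stop_rate = 1e-3,
                              end_pileup_weight = 0.05,
                              depth = 2e5, intergenic = 100,
                              minus_strand_fraction = 0.5, seed = 1) {
  transcript_length <- rep_len(as.integer(transcript_length), n_transcripts)
  assert_that(all(transcript_length >= 200),
              "transcripts must be at least 200 nt for windowed calling")
  if (is.null(planted_sites)) {
    planted_sites <- tibble::tibble(
      transcript = integer(), offset = integer(), enzyme = character(),
      stop_efficiency = numeric(), stoichiometry = numeric()
    )
  }
  planted_sites <- tibble::as_tibble(planted_sites)
  if (!"stop_efficiency" %in% names(planted_sites)) {
    planted_sites$stop_efficiency <- rep(0.8, nrow(planted_sites))
  }
  if (!"stoichiometry" %in% names(planted_sites)) {
    planted_sites$stoichiometry <- rep(1, nrow(planted_sites))
  }
  assert_that(all(planted_sites$enzyme %in% c(PSI_SYNTHASES, "none")),
              paste("enzyme must be one of:",
                    paste(c(PSI_SYNTHASES, "none"), collapse = ", ")))
  assert_that(all(planted_sites$transcript >= 1 &
                    planted_sites$transcript <= n_transcripts),
              "planted site outside any transcript")
  assert_that(
    all(planted_sites$offset >= 5 &
          planted_sites$offset <= transcript_length[planted_sites$transcript] - 6),
    "planted site offset too close to a transcript boundary"
  )
  assert_that(all(planted_sites$stop_efficiency >= 0 &
                    planted_sites$stop_efficiency <= 1 &
                    planted_sites$stoichiometry >= 0 &
                    planted_sites$stoichiometry <= 1),
              "stop_efficiency and stoichiometry must lie in [0, 1]")
  assert_that(background_stop_rate >= 0 && background_stop_rate < 1 &&
                end_pileup_weight >= 0 && end_pileup_weight < 1,
              "rates must lie in [0, 1)")
  assert_that(depth > 0, "depth must be positive")
  structure(list(
    n_transcripts = n_transcripts, transcript_length = transcript_length,
    expression = expression, meanlog = meanlog, sdlog = sdlog,
    planted_sites = planted_sites,
    background_stop_rate = background_stop_rate,
    end_pileup_weight = end_pileup_weight,
    depth = depth, intergenic = as.integer(intergenic),
    minus_strand_fraction = minus_strand_fraction,
    seed = as.integer(seed)
  ), class = "psi_sim_config")
}

#' Evenly spaced default planted sites
#'
#' Convenience constructor placing one site per listed transcript at its
#' midpoint, cycling through the given enzymes.
#'
#' @param transcripts 1-based transcript indices to modify.
#' @param config_length Transcript length(s) used to centre the sites.
#' @param enzymes Enzyme names recycled across sites.
#' @param stop_efficiency,stoichiometry Per-site values (recycled).
#' @return A planted-site tibble for [simulation_config()].
#' @export
planted_sites_grid <- function(transcripts, config_length = 1000,
                               enzymes = "rluA", stop_efficiency = 0.8,
                               stoichiometry = 1) {
  n <- length(transcripts)
  len <- rep_len(as.integer(config_length), max(transcripts))
  tibble::tibble(
    transcript = as.integer(transcripts),
    offset = as.integer(len[transcripts] %/% 2),
    enzyme = rep_len(enzymes, n),
    stop_efficiency = rep_len(stop_efficiency, n),
    stoichiometry = rep_len(stoichiometry, n)
  )
}

#' Generate a synthetic transcriptome with planted modification motifs
#'
#' Builds a random genome carrying `n_transcripts` transcripts separated by
#' intergenic gaps (alternating strands per `minus_strand_fraction`). At each
#' planted site a `UURAA` motif is written so that the modified U is motif
#' position 1. Deterministic given the config seed.
#'
#' @param config A [simulation_config()].
#' @return A list with `genome` ([psi_genome()]), `models`
#'   ([transcript_models()] with `expression` weights), and `truth`: a tibble
#'   of planted sites with genomic coordinates (`pos` = modified U on the
#'   coding strand, `peak_pos` = expected read 5'-end pileup position),
#'   enzyme, stop efficiency and stoichiometry.
#' @export
make_transcriptome <- function(config) {
  with_seed(child_seed(config$seed, 1L), {
    n <- config$n_transcripts
    len <- config$transcript_length
    gap <- config$intergenic
    expr <- config$expression %||% rlnorm(n, config$meanlog, config$sdlog)
    assert_that(length(expr) == n, "expression needs one weight per transcript")
    minus_every <- if (config$minus_strand_fraction <= 0) Inf
      else max(1, round(1 / config$minus_strand_fraction))
    strand <- ifelse(seq_len(n) %% minus_every == 0, "-", "+")

    # transcript sequences in transcript orientation (5'->3', DNA alphabet)
    tx_seq <- purrr::map_chr(len, function(L) {
      paste(sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = "")
    })
    ps <- config$planted_sites
    if (nrow(ps)) {
      for (i in seq_len(nrow(ps))) {
        t <- ps$transcript[i]; o <- ps$offset[i]
        motif <- paste0("TT", sample(c("A", "G"), 1), "AA")
        substr(tx_seq[t], o + 1, o + 5) <- motif
      }
    }

    start <- cumsum(c(gap, head(len + gap, -1)))
    end <- start + len
    glen <- end[n] + gap
    gseq <- paste(sample(c("A", "C", "G", "T"), glen, replace = TRUE),
                  collapse = "")
    for (i in seq_len(n)) {
      seg <- if (strand[i] == "+") tx_seq[i] else revcomp(tx_seq[i])
      substr(gseq, start[i] + 1, end[i]) <- seg
    }
    genome <- psi_genome("synthetic", gseq)

    models <- transcript_models(tibble::tibble(
      gene_id = sprintf("tx%02d", seq_len(n)),
      strand = strand, start = as.integer(start), end = as.integer(end),
      cds_start = as.integer(ifelse(strand == "+", start, end - 1L))
    ))
    models$expression <- expr / sum(expr)

    truth <- if (nrow(ps)) {
      site_pos <- purrr::map2_int(ps$transcript, ps$offset, function(t, o) {
        as.integer(to_genomic_coord(o, strand[t], start[t], end[t]))
      })
      tibble::tibble(
        gene_id = models$gene_id[ps$transcript],
        transcript = ps$transcript,
        offset = ps$offset,
        strand = strand[ps$transcript],
        pos = site_pos,
        enzyme = ps$enzyme,
        stop_efficiency = ps$stop_efficiency,
        stoichiometry = ps$stoichiometry
      )
    } else {
      tibble::tibble(gene_id = character(), transcript = integer(),
                     offset = integer(), strand = character(), pos = integer(),
                     enzyme = character(), stop_efficiency = numeric(),
                     stoichiometry = numeric())
    }
    truth$peak_pos <- as.integer(truth$pos + ifelse(truth$strand == "+", 1L, -1L))

    list(genome = genome, models = models, truth = truth)
  })
}

#' Simulate one RT-stop sequencing library
#'
#' Each of `depth` reads picks a transcript proportionally to expression and a
#' fragment 3' start uniform along it, then reverse transcription walks
#' 5'-ward: in the CMC condition it terminates at a planted site (whose enzyme
#' is not knocked out) with probability `stop_efficiency * stoichiometry`,
#' placing the read 5' end one nucleotide downstream (transcript orientation)
#' of the modified U; background termination occurs with
#' `background_stop_rate` per position; otherwise the read runs to the
#' transcript 5' end. A fraction `end_pileup_weight` of reads is placed
#' directly at the transcript 5' boundary. Mock libraries ignore planted
#' sites. Deterministic given `seed`; total counts equal `depth` exactly.
#'
#' @param transcriptome Result of [make_transcriptome()].
#' @param config The same [simulation_config()].
#' @param condition `"CMC"` or `"mock"`.
#' @param knockout A synthase name whose sites lose their CMC stop, or
#'   `"none"`.
#' @param seed Integer seed for this library.
#' @return A `psi_track` labelled `"<WT|knockout>-<condition>"`.
#' @export
simulate_library <- function(transcriptome, config,
                             condition = c("CMC", "mock"),
                             knockout = "none", seed = config$seed) {
  condition <- match.arg(condition)
  assert_that(knockout %in% c(PSI_SYNTHASES, "none"),
              sprintf("unknown enzyme '%s'", knockout))
  models <- transcriptome$models
  truth <- transcriptome$truth
  n <- nrow(models)
  L <- models$end - models$start
  depth <- as.integer(config$depth)

  with_seed(seed, {
    tx <- sample.int(n, depth, replace = TRUE, prob = models$expression)
    at_end <- runif(depth) < config$end_pileup_weight
    # fragment 3' start, transcript coordinate (0-based)
    s <- floor(runif(depth) * L[tx])
    # background termination: geometric walk length before a background stop
    b <- config$background_stop_rate
    g <- if (b > 0) rgeom(depth, b) else rep(Inf, depth)
    e <- pmax(s - g, 0)  # 5' end if only background acted

    if (condition == "CMC" && nrow(truth)) {
      active <- truth[truth$enzyme != knockout, , drop = FALSE]
      for (i in seq_len(nrow(active))) {
        ti <- active$transcript[i]
        u <- active$offset[i]
        q <- active$stop_efficiency[i] * active$stoichiometry[i]
        if (q <= 0) next
        hit <- tx == ti & s > u & runif(depth) < q
        # stop at the site wins if it lies 5'-ward of the background stop
        e <- ifelse(hit, pmax(e, u + 1), e)
      }
    }
    e[at_end] <- 0

    gpos <- ifelse(models$strand[tx] == "+",
                   models$start[tx] + e,
                   (models$end[tx] - 1L) - e)
    gstr <- models$strand[tx]
    df <- tibble::tibble(pos = as.integer(gpos), strand = gstr) |>
      dplyr::count(.data$pos, .data$strand, name = "count")
    label <- sprintf("%s-%s", if (knockout == "none") "WT" else knockout,
                     condition)
    end_track(df, library_label = label, total_reads = depth,
              chrom = transcriptome$genome$name)
  })
}

#' Simulate the full library panel
#'
#' WT-CMC, WT-mock, and one CMC library per knockout enzyme, with
#' deterministic per-library child seeds.
#'
#' @param transcriptome Result of [make_transcriptome()].
#' @param config A [simulation_config()].
#' @param knockouts Enzyme names to simulate knockouts for (default: the
#'   enzymes appearing in the truth table).
#' @return Named list: `cmc`, `mock`, and `ko` (named list per enzyme).
#' @export
simulate_panel <- function(transcriptome, config, knockouts = NULL) {
  knockouts <- knockouts %||%
    setdiff(unique(transcriptome$truth$enzyme), "none")
  list(
    cmc = simulate_library(transcriptome, config, "CMC", "none",
                           seed = child_seed(config$seed, 2L)),
    mock = simulate_library(transcriptome, config, "mock", "none",
                            seed = child_seed(config$seed, 3L)),
    ko = setNames(purrr::imap(knockouts, function(kz, idx) {
      simulate_library(transcriptome, config, "CMC", kz,
                       seed = child_seed(config$seed, 10L + idx))
    }), knockouts)
  )
}

#' Simulate a targeted bisulfite-sequencing deletion pileup
#'
#' Bisulfite chemistry converts pseudouridine into a 1-2 nt deletion whose
#' frequency is roughly proportional to the modification stoichiometry. At
#' each planted site, deletion events are drawn binomially with probability
#' `prop_const * stoichiometry` (lengths 1 or 2 with equal odds, counted at
#' their 5'-most position, which is the site itself); all other positions see
#' a small error rate.
#'
#' @param sites Tibble with columns `pos` (0-based) and `stoichiometry`.
#' @param n_positions Length of the simulated amplicon (positions `0 ..
#'   n_positions - 1`).
#' @param depth Reads covering each position.
#' @param prop_const Deletion rate at 100% stoichiometry (the oligo
#'   calibration constant).
#' @param error_rate Background deletion rate at unmodified positions.
#' @param seed Integer seed.
#' @return Tibble with `pos`, `depth`, `deletions`.
#' @export
simulate_bidseq_pileup <- function(sites, n_positions, depth,
                                   prop_const = 0.9, error_rate = 0.002,
                                   seed = 1) {
  assert_that(depth > 0, "depth must be positive")
  sites <- tibble::as_tibble(sites)
  assert_that(all(sites$pos >= 0 & sites$pos < n_positions),
              "site outside the simulated amplicon")
  with_seed(seed, {
    del <- rbinom(n_positions, depth, error_rate)
    if (nrow(sites)) {
      extra <- rbinom(nrow(sites), depth, pmin(1, prop_const * sites$stoichiometry))
      # deletion length 1 or 2 with equal odds; both anchor at the site's
      # 5'-most position, so the counting position is unchanged
      del[sites$pos + 1L] <- pmin(depth, del[sites$pos + 1L] + extra)
    }
    tibble::tibble(pos = seq_len(n_positions) - 1L,
                   depth = as.integer(depth), deletions = as.integer(del))
  })
}
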