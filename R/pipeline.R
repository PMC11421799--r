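# End-to-end driver: simulate (or load) -> call -> assign -> saturate ->
# motif -> structure -> bidseq, with a reproducibility manifest.

#' Pipeline configuration
#'
#' Collects everything a full run needs. Library roles (condition, knockout)
#' are declared here, never inferred from file names. Either `sim` (a
#' [simulation_config()], for a synthetic run) or `tracks` (named paths:
#' `cmc`, `mock`, plus optional knockout labels) must be supplied, together
#' with genome/annotation for file-based runs.
#'
#' @param sim Optional [simulation_config()] for a synthetic run.
#' @param tracks Named list of track file paths (bedGraph), requiring at
#'   least `cmc` and `mock`; any further entries are knockout CMC libraries
#'   keyed by enzyme name.
#' @param genome_fasta,models For file-based runs: genome FASTA path and a
#'   [transcript_models()] table.
#' @param thresholds A [call_thresholds()].
#' @param window_len Background window size.
#' @param saturation_depths Optional depth ladder for saturation analysis.
#' @param seed Master seed.
#' @return A list of class `psi_pipeline_config`.
#' @export
pipeline_config <- function(sim = NULL, tracks = NULL, genome_fasta = NULL,
                            models = NULL, thresholds = call_thresholds(),
                            window_len = 100, saturation_depths = NULL,
                            seed = 1) {
  if (is.null(sim)) {
    assert_that(!is.null(tracks), "either `sim` or `tracks` must be given")
    assert_that(all(c("cmc", "mock") %in% names(tracks)),
                "tracks must include 'cmc' and 'mock' libraries")
    assert_that(!anyDuplicated(names(tracks)), "track labels must be unique")
    missing <- !purrr::map_lgl(tracks, file.exists)
    assert_that(!any(missing),
                paste("missing track files:",
                      paste(unlist(tracks[missing]), collapse = ", ")))
    assert_that(!is.null(genome_fasta) && !is.null(models),
                "file-based runs need genome_fasta and models")
  }
  structure(list(
    sim = sim, tracks = tracks, genome_fasta = genome_fasta, models = models,
    thresholds = thresholds, window_len = window_len,
    saturation_depths = saturation_depths, seed = as.integer(seed)
  ), class = "psi_pipeline_config")
}

#' Run the full pipeline
#'
#' Synthetic runs simulate the transcriptome and the full library panel from
#' the embedded [simulation_config()]; file-based runs read the declared
#' tracks. Either way the driver calls sites, assigns enzymes when knockout
#' libraries are present, optionally computes a saturation curve, annotates
#' motif classes and codon context, summarises structure context with the
#' stub engine, and writes TSV outputs plus a YAML run manifest (seeds,
#' thresholds, library labels, package version) to `outdir`.
#'
#' @param config A [pipeline_config()].
#' @param outdir Output directory (created if missing).
#' @param engine Folding engine for the structure summary.
#' @return Invisibly, a list with `scan`, `sites`, `saturation` (or `NULL`),
#'   `motif`, `structure`, and the manifest.
#' @export
run_end_to_end <- function(config, outdir, engine = stub_engine()) {
  assert_that(inherits(config, "psi_pipeline_config"),
              "config must come from pipeline_config()")
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)

  if (!is.null(config$sim)) {
    txome <- make_transcriptome(config$sim)
    genome <- txome$genome
    models <- txome$models
    panel <- simulate_panel(txome, config$sim)
    cmc <- panel$cmc; mock <- panel$mock; kos <- panel$ko
    write_sites_tsv(txome$truth, file.path(outdir, "truth.tsv"))
    write_track(cmc, file.path(outdir, "wt_cmc.bedGraph"))
    write_track(mock, file.path(outdir, "wt_mock.bedGraph"))
  } else {
    genome <- read_genome(config$genome_fasta)
    models <- config$models
    cmc <- read_track(config$tracks$cmc, "bedGraph", library_label = "WT-CMC")
    mock <- read_track(config$tracks$mock, "bedGraph", library_label = "WT-mock")
    ko_names <- setdiff(names(config$tracks), c("cmc", "mock"))
    kos <- setNames(purrr::map(ko_names, function(nm) {
      read_track(config$tracks[[nm]], "bedGraph",
                 library_label = paste0(nm, "-CMC"))
    }), ko_names)
  }

  scan <- scan_sites(cmc, mock, genome, models, config$thresholds,
                     window_len = config$window_len)
  if (length(kos)) {
    scan <- assign_enzymes(scan, kos, genome, models, config$thresholds,
                           n_expected = length(kos))
  }
  sites <- called_sites(scan)
  write_sites_tsv(scan$sites, file.path(outdir, "sites.tsv"))
  if (length(kos)) {
    write_sites_tsv(sites, file.path(outdir, "assigned.tsv"))
  }

  sat <- NULL
  if (!is.null(config$saturation_depths)) {
    sat <- saturation_curve(cmc, config$saturation_depths, mock, genome,
                            models, config$thresholds,
                            window_len = config$window_len,
                            seed = child_seed(config$seed, 77L))
    readr::write_tsv(sat$curve, file.path(outdir, "curve.tsv"),
                     progress = FALSE)
  }

  motif <- NULL
  struct <- NULL
  if (nrow(sites)) {
    motif <- sites |>
      dplyr::mutate(motif = purrr::map2_chr(
        .data$pos, .data$strand, ~classify_motif(genome, .x, .y)
      ))
    motif <- codon_context_all(motif, models, genome)
    readr::write_tsv(
      dplyr::select(motif, "gene_id", "pos", "strand", "motif", "codon",
                    "amino_acid", "codon_index", "position_in_codon"),
      file.path(outdir, "motif.tsv"), progress = FALSE
    )
    pfm <- position_frequency(sites, genome, flank = 5)
    readr::write_tsv(
      tibble::as_tibble(pfm, rownames = "base"),
      file.path(outdir, "pfm.tsv"), progress = FALSE
    )
    struct <- structure_context(sites, genome, engine = engine)
    readr::write_tsv(struct$summary, file.path(outdir, "structure.tsv"),
                     progress = FALSE)
  }

  manifest <- list(
    package = "psistop",
    version = as.character(utils::packageVersion("psistop")),
    seed = config$seed,
    window_len = config$window_len,
    thresholds = unclass(config$thresholds),
    libraries = c(track_label(cmc), track_label(mock),
                  purrr::map_chr(kos, track_label)),
    n_called = nrow(sites),
    synthetic = !is.null(config$sim)
  )
  yaml::write_yaml(manifest, file.path(outdir, "manifest.yaml"))

  invisible(list(scan = scan, sites = sites, saturation = sat,
                 motif = motif, structure = struct, manifest = manifest))
}
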