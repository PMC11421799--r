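# Data model and I/O: genome sequences, end-count tracks, transcript models.
#
# Coordinate convention: 0-based half-open everywhere internally. bedGraph and
# BED writers emit 0-based half-open; the wiggle writer emits 1-based positions
# per the variableStep standard. Conversion is confined to this file.

#' Construct a genome sequence object
#'
#' A genome is a single named DNA sequence over the alphabet \{A,C,G,T\}.
#' Coordinates throughout the package are 0-based offsets into this sequence.
#'
#' @param name Sequence (chromosome) name.
#' @param sequence DNA string; upper/lowercase accepted, stored uppercase.
#' @return An object of class `psi_genome`: a list with `name` and `sequence`.
#' @export
psi_genome <- function(name, sequence) {
  sequence <- toupper(sequence)
  assert_that(nchar(sequence) > 0, "genome sequence must be non-empty")
  assert_that(
    !grepl("[^ACGT]", sequence),
    "genome sequence may only contain A, C, G, T"
  )
  structure(list(name = name, sequence = sequence), class = "psi_genome")
}

#' @export
print.psi_genome <- function(x, ...) {
  cat(sprintf(
    "<psi_genome> %s: %d nt (%s...)\n",
    x$name, nchar(x$sequence), substr(x$sequence, 1, 24)
  ))
  invisible(x)
}

#' Genome length in nucleotides
#' @param genome A [psi_genome()].
#' @return Integer length.
#' @export
genome_length <- function(genome) nchar(genome$sequence)

#' Read / write a genome FASTA
#'
#' Thin wrappers over Biostrings. `read_genome()` takes the first record of a
#' FASTA file.
#'
#' @param path FASTA file path.
#' @return `read_genome()`: a [psi_genome()].
#' @export
read_genome <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  assert_that(length(ss) >= 1, "FASTA file contains no records")
  psi_genome(sub("\\s.*$", "", names(ss)[1]), as.character(ss[[1]]))
}

#' @rdname read_genome
#' @param genome A [psi_genome()].
#' @export
write_genome <- function(genome, path) {
  ss <- Biostrings::DNAStringSet(setNames(genome$sequence, genome$name))
  Biostrings::writeXStringSet(ss, path, width = 70L)
  invisible(path)
}

#' Extract a strand-aware subsequence
#'
#' Returns the sequence of the half-open interval `[start, end)` read in
#' transcript orientation: for the minus strand the reverse complement is
#' returned, so the first character is the 5'-most transcribed base.
#'
#' @param genome A [psi_genome()].
#' @param start,end 0-based half-open interval on the reference.
#' @param strand `"+"` or `"-"`.
#' @return Character string.
#' @export
genome_subseq <- function(genome, start, end, strand = "+") {
  assert_that(start >= 0 && end <= genome_length(genome) && start < end,
              "interval outside genome")
  s <- substr(genome$sequence, start + 1, end)
  if (strand == "-") s <- revcomp(s) else s
}

## ---------------------------------------------------------------------------
## End-count tracks

#' Construct an end-count track
#'
#' An end-count track records, per strand, the number of read 5' ends at each
#' 0-based reference position. Positions with zero counts may be implicit.
#' `total_reads` defaults to the sum of all counts but can exceed it when the
#' track is a slice of a larger library.
#'
#' @param data A data frame with columns `pos` (0-based integer), `strand`
#'   (`"+"`/`"-"`), `count` (non-negative integer).
#' @param library_label Free-text label, e.g. `"WT-CMC"`, `"rluA-CMC"`.
#' @param total_reads Total mapped reads in the library; default `sum(count)`.
#' @param chrom Reference sequence name the positions refer to.
#' @return A tibble of class `psi_track` with columns `pos`, `strand`, `count`.
#' @export
end_track <- function(data, library_label = "track", total_reads = NULL,
                      chrom = NA_character_) {
  data <- tibble::as_tibble(data)
  assert_that(all(c("pos", "strand", "count") %in% names(data)),
              "track needs columns pos, strand, count")
  assert_that(all(data$count >= 0), "negative counts are not allowed")
  assert_that(all(data$strand %in% c("+", "-")), "strand must be '+' or '-'")
  data <- data |>
    dplyr::filter(.data$count > 0) |>
    dplyr::arrange(.data$strand, .data$pos)
  data$pos <- as.integer(data$pos)
  data$count <- as.numeric(data$count)
  total <- total_reads %||% sum(data$count)
  assert_that(total >= sum(data$count),
              "total_reads cannot be smaller than the summed counts")
  structure(data,
    class = c("psi_track", class(tibble::tibble())),
    library_label = library_label, total_reads = total, chrom = chrom
  )
}

#' Track accessors
#'
#' `track_total()` returns the library's total mapped reads (falling back to
#' the summed counts for plain data frames); `track_label()` its label.
#'
#' @param track A `psi_track` or plain data frame with a `count` column.
#' @return A scalar.
#' @export
track_total <- function(track) {
  attr(track, "total_reads") %||% sum(track$count)
}

#' @rdname track_total
#' @export
track_label <- function(track) attr(track, "library_label") %||% "track"

track_chrom <- function(track) attr(track, "chrom") %||% NA_character_

# Dense per-position count vector for one strand (length = genome length).
# Index i holds the count at 0-based position i - 1.
track_vector <- function(track, strand, len) {
  v <- numeric(len)
  rows <- track[track$strand == strand, , drop = FALSE]
  if (nrow(rows)) {
    assert_that(all(rows$pos < len), "track position beyond genome length")
    v[rows$pos + 1L] <- rows$count
  }
  v
}

#' Read an end-count track from bedGraph or wiggle
#'
#' bedGraph lines are `chrom start end count` (0-based half-open), with an
#' optional fifth `strand` column; without that column all counts are placed
#' on `strand`. Wiggle input must be `variableStep` (1-based positions), one
#' strand per file. Runs of length > 1 in bedGraph are expanded to
#' per-position counts.
#'
#' @param path Input file.
#' @param format `"bedGraph"` or `"wiggle"`.
#' @param strand Strand assigned to strand-less records.
#' @param library_label,total_reads Passed to [end_track()].
#' @return A `psi_track`.
#' @export
read_track <- function(path, format = c("bedGraph", "wiggle"), strand = "+",
                       library_label = basename(path), total_reads = NULL) {
  format <- match.arg(format)
  lines <- readr::read_lines(path)
  keep <- !grepl("^\\s*(#|$)", lines) & !grepl("^track\\b", lines)
  if (format == "bedGraph") {
    rows <- purrr::map(which(keep), function(i) {
      f <- strsplit(trimws(lines[i]), "\\s+")[[1]]
      if (!(length(f) %in% c(4L, 5L))) {
        abort(sprintf("%s:%d: malformed bedGraph line (need 4 or 5 fields)",
                      path, i))
      }
      start <- suppressWarnings(as.integer(f[2]))
      end <- suppressWarnings(as.integer(f[3]))
      count <- suppressWarnings(as.numeric(f[4]))
      if (anyNA(c(start, end, count)) || end <= start) {
        abort(sprintf("%s:%d: malformed bedGraph interval", path, i))
      }
      if (count < 0) {
        abort(sprintf("%s:%d: negative count", path, i))
      }
      tibble::tibble(
        chrom = f[1], pos = seq.int(start, end - 1L),
        strand = if (length(f) == 5L) f[5] else strand, count = count
      )
    })
    df <- dplyr::bind_rows(rows)
  } else {
    cur_chrom <- NA_character_
    recs <- vector("list", sum(keep))
    k <- 0L
    for (i in which(keep)) {
      ln <- trimws(lines[i])
      if (grepl("^variableStep", ln)) {
        m <- regmatches(ln, regexec("chrom=(\\S+)", ln))[[1]]
        if (length(m) < 2) abort(sprintf("%s:%d: variableStep without chrom", path, i))
        cur_chrom <- m[2]
      } else if (grepl("^fixedStep", ln)) {
        abort(sprintf("%s:%d: fixedStep wiggle is not supported", path, i))
      } else {
        f <- strsplit(ln, "\\s+")[[1]]
        p1 <- suppressWarnings(as.integer(f[1]))
        cnt <- suppressWarnings(as.numeric(f[2]))
        if (length(f) != 2L || anyNA(c(p1, cnt)) || p1 < 1) {
          abort(sprintf("%s:%d: malformed wiggle data line", path, i))
        }
        if (cnt < 0) abort(sprintf("%s:%d: negative count", path, i))
        if (is.na(cur_chrom)) {
          abort(sprintf("%s:%d: data line before variableStep header", path, i))
        }
        k <- k + 1L
        recs[[k]] <- tibble::tibble(
          chrom = cur_chrom, pos = p1 - 1L, strand = strand, count = cnt
        )
      }
    }
    df <- dplyr::bind_rows(recs[seq_len(k)])
  }
  if (nrow(df) == 0) {
    df <- tibble::tibble(chrom = character(), pos = integer(),
                         strand = character(), count = numeric())
  }
  chrom <- if (nrow(df)) df$chrom[1] else NA_character_
  df <- df |>
    dplyr::group_by(.data$pos, .data$strand) |>
    dplyr::summarise(count = sum(.data$count), .groups = "drop")
  end_track(df, library_label = library_label, total_reads = total_reads,
            chrom = chrom)
}

#' Write an end-count track
#'
#' The bedGraph writer emits one line per non-zero position; tracks carrying
#' both strands gain a fifth strand column (a documented dialect extension),
#' single-strand tracks are standard 4-column bedGraph. The wiggle writer is
#' `variableStep` (1-based) and requires a single-strand track (filter with
#' `strand` first).
#'
#' @param track A `psi_track`.
#' @param path Output file.
#' @param format `"bedGraph"` or `"wiggle"`.
#' @param strand For wiggle: which strand to emit.
#' @return `path`, invisibly.
#' @export
write_track <- function(track, path, format = c("bedGraph", "wiggle"),
                        strand = NULL) {
  format <- match.arg(format)
  chrom <- track_chrom(track)
  if (is.na(chrom)) chrom <- "genome"
  df <- dplyr::arrange(tibble::as_tibble(track), .data$strand, .data$pos)
  if (format == "bedGraph") {
    strands <- unique(df$strand)
    if (length(strands) > 1) {
      out <- sprintf("%s\t%d\t%d\t%s\t%s", chrom, df$pos, df$pos + 1L,
                     format(df$count, trim = TRUE, scientific = FALSE), df$strand)
    } else {
      out <- sprintf("%s\t%d\t%d\t%s", chrom, df$pos, df$pos + 1L,
                     format(df$count, trim = TRUE, scientific = FALSE))
    }
    readr::write_lines(out, path)
  } else {
    if (!is.null(strand)) df <- df[df$strand == strand, , drop = FALSE]
    assert_that(length(unique(df$strand)) <= 1,
                "wiggle output is single-strand; pass `strand` to select one")
    out <- c(
      sprintf("variableStep chrom=%s", chrom),
      sprintf("%d %s", df$pos + 1L,
              format(df$count, trim = TRUE, scientific = FALSE))
    )
    readr::write_lines(out, path)
  }
  invisible(path)
}

## ---------------------------------------------------------------------------
## Transcript models

#' Construct a transcript model table
#'
#' One row per gene: half-open span `[start, end)` on the reference, strand,
#' optional CDS start (genomic position of the first base of the start codon
#' on the coding strand), annotated transcript 5'/3' end positions (list
#' columns; e.g. from end-enriched RNA-seq), and optionally expression (RPKM).
#'
#' @param data Data frame with columns `gene_id`, `strand`, `start`, `end`,
#'   and optionally `cds_start`, `five_prime_ends`, `three_prime_ends`,
#'   `rpkm`. Missing end annotations default to the span boundaries.
#' @return A tibble of class `psi_models`.
#' @export
transcript_models <- function(data) {
  df <- tibble::as_tibble(data)
  assert_that(all(c("gene_id", "strand", "start", "end") %in% names(df)),
              "transcript models need gene_id, strand, start, end")
  assert_that(all(df$start < df$end), "transcript start must be < end")
  assert_that(all(df$strand %in% c("+", "-")), "strand must be '+' or '-'")
  if (!"cds_start" %in% names(df)) df$cds_start <- NA_integer_
  if (!"rpkm" %in% names(df)) df$rpkm <- NA_real_
  if (!"five_prime_ends" %in% names(df)) {
    df$five_prime_ends <- purrr::pmap(
      list(df$strand, df$start, df$end),
      function(s, a, b) if (s == "+") a else b - 1L
    )
  }
  if (!"three_prime_ends" %in% names(df)) {
    df$three_prime_ends <- purrr::pmap(
      list(df$strand, df$start, df$end),
      function(s, a, b) if (s == "+") b - 1L else a
    )
  }
  df$five_prime_ends <- purrr::map(df$five_prime_ends, as.integer)
  df$three_prime_ends <- purrr::map(df$three_prime_ends, as.integer)
  ok_ends <- purrr::pmap_lgl(
    list(df$five_prime_ends, df$three_prime_ends, df$start, df$end),
    function(e5, e3, s, e) all(c(e5, e3) >= s) && all(c(e5, e3) < e)
  )
  assert_that(all(ok_ends), "annotated transcript ends must lie within the span")
  class(df) <- c("psi_models", class(tibble::tibble()))
  df
}

# Transcript-oriented coordinate of genomic position g within gene row m:
# 0 at the transcript 5' boundary of the span, increasing 5'->3'.
to_tx_coord <- function(g, strand, start, end) {
  if (strand == "+") g - start else (end - 1L) - g
}

to_genomic_coord <- function(u, strand, start, end) {
  if (strand == "+") start + u else (end - 1L) - u
}

# Gene containing a position on a strand; overlapping genes resolve to the
# one whose span midpoint is nearest.
containing_gene <- function(models, pos, strand) {
  hits <- which(models$strand == strand & models$start <= pos & pos < models$end)
  if (!length(hits)) return(NA_integer_)
  if (length(hits) == 1) return(hits)
  mid <- (models$start[hits] + models$end[hits]) / 2
  hits[which.min(abs(mid - pos))]
}

#' Read transcript models from a GFF3 subset
#'
#' Reads `gene` features (span, strand) and `CDS` features (frame anchor) from
#' a GFF3 file via rtracklayer and returns a [transcript_models()] table.
#' GFF3 1-based closed coordinates are converted to the package's 0-based
#' half-open convention.
#'
#' @param path GFF3 file.
#' @return A `psi_models` tibble.
#' @export
read_models_gff3 <- function(path) {
  if (!requireNamespace("rtracklayer", quietly = TRUE)) {
    abort("read_models_gff3() requires the rtracklayer package")
  }
  g <- tibble::as_tibble(rtracklayer::readGFF(path))
  genes <- g |>
    dplyr::filter(.data$type == "gene") |>
    dplyr::transmute(
      gene_id = as.character(.data$ID),
      strand = as.character(.data$strand),
      start = as.integer(.data$start) - 1L,
      end = as.integer(.data$end)
    )
  cds <- g |>
    dplyr::filter(.data$type == "CDS") |>
    dplyr::transmute(
      gene_id = as.character(.data$Parent),
      cds_start = ifelse(as.character(.data$strand) == "+",
                         as.integer(.data$start) - 1L,
                         as.integer(.data$end) - 1L)
    )
  transcript_models(dplyr::left_join(genes, cds, by = "gene_id"))
}

#' Read / write transcript end annotations as BED6
#'
#' Each record is a single-base feature; `name` is `five_prime` or
#' `three_prime`. On read the ends are merged into an existing model table.
#'
#' @param models A `psi_models` table.
#' @param path BED6 file.
#' @param chrom Chromosome name for writing.
#' @return `read_ends_bed()`: updated models; `write_ends_bed()`: `path`.
#' @export
write_ends_bed <- function(models, path, chrom = "genome") {
  rows <- purrr::map(seq_len(nrow(models)), function(i) {
    e5 <- models$five_prime_ends[[i]]
    e3 <- models$three_prime_ends[[i]]
    tibble::tibble(
      pos = c(e5, e3),
      name = rep(c("five_prime", "three_prime"), c(length(e5), length(e3))),
      strand = models$strand[i]
    )
  }) |> dplyr::bind_rows()
  readr::write_lines(
    sprintf("%s\t%d\t%d\t%s\t0\t%s", chrom, rows$pos, rows$pos + 1L,
            rows$name, rows$strand),
    path
  )
  invisible(path)
}

#' @rdname write_ends_bed
#' @export
read_ends_bed <- function(models, path) {
  bed <- readr::read_tsv(
    path,
    col_names = c("chrom", "start", "end", "name", "score", "strand"),
    col_types = "ciicic", progress = FALSE
  )
  for (i in seq_len(nrow(models))) {
    sel <- bed$strand == models$strand[i] &
      bed$start >= models$start[i] & bed$start < models$end[i]
    e5 <- bed$start[sel & bed$name == "five_prime"]
    e3 <- bed$start[sel & bed$name == "three_prime"]
    if (length(e5)) models$five_prime_ends[[i]] <- as.integer(e5)
    if (length(e3)) models$three_prime_ends[[i]] <- as.integer(e3)
  }
  models
}

## ---------------------------------------------------------------------------
## Normalisation and expression

#' Normalise a track to per-transcript read fractions
#'
#' Expresses each position's count as a fraction of all reads mapped to the
#' containing transcript, the display normalisation used for per-gene track
#' figures. Values over one transcript sum to 1.
#'
#' @param track A `psi_track`.
#' @param models A `psi_models` table.
#' @param gene_id Gene to normalise over.
#' @return Tibble with `pos`, `strand`, `value`.
#' @export
normalize_to_transcript <- function(track, models, gene_id) {
  m <- models[models$gene_id == gene_id, , drop = FALSE]
  assert_that(nrow(m) == 1, sprintf("unknown gene_id '%s'", gene_id))
  rows <- track[track$strand == m$strand &
                  track$pos >= m$start & track$pos < m$end, , drop = FALSE]
  total <- sum(rows$count)
  if (total <= 0) {
    abort(sprintf("no reads map to transcript '%s'; normalisation undefined",
                  gene_id))
  }
  tibble::tibble(pos = rows$pos, strand = rows$strand,
                 value = rows$count / total)
}

#' Reads per kilobase per million mapped reads
#'
#' `rpkm()` for one gene; `add_rpkm()` annotates every model row. The library
#' size is the track's `total_reads` (mRNA-mapping reads).
#'
#' @param track A `psi_track`.
#' @param models A `psi_models` table.
#' @param gene_id Gene identifier.
#' @return `rpkm()`: a number; `add_rpkm()`: models with an `rpkm` column.
#' @export
rpkm <- function(track, models, gene_id) {
  m <- models[models$gene_id == gene_id, , drop = FALSE]
  assert_that(nrow(m) == 1, sprintf("unknown gene_id '%s'", gene_id))
  len <- m$end - m$start
  assert_that(len > 0, "zero-length gene")
  total <- track_total(track)
  assert_that(total > 0, "library has no mapped reads")
  reads <- sum(track$count[track$strand == m$strand &
                             track$pos >= m$start & track$pos < m$end])
  reads * 1e9 / (len * total)
}

#' @rdname rpkm
#' @export
add_rpkm <- function(models, track) {
  models$rpkm <- purrr::map_dbl(models$gene_id, ~rpkm(track, models, .x))
  models
}

#' Write a site-call result table as TSV
#'
#' Columns mirror the published per-site summary: position, gene, strand,
#' per-library Z-scores and coverage, call status, and enzyme assignment
#' (when present).
#'
#' @param sites A tibble of site calls (from [scan_sites()] / [assign_enzymes()]).
#' @param path Output TSV.
#' @return `path`, invisibly.
#' @export
write_sites_tsv <- function(sites, path) {
  out <- dplyr::mutate(
    sites,
    dplyr::across(dplyr::where(is.list), ~purrr::map_chr(.x, paste, collapse = ","))
  )
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}
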