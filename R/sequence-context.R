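# Sequence context of called sites: motif classes, position-frequency
# matrices, codon/amino-acid context, and expression-matched background
# selection.

#' Classify the 5-mer motif at a site
#'
#' Extracts the strand-aware 5-mer whose first base is the site's U,
#' transcribes to the RNA alphabet, and classifies it into one of the
#' recognition-motif classes: `UURAA` (R = A/G), `UUYAA` (Y = C/U),
#' `UURBA` (B = C/G/U, i.e. not A), or `other`. The classes are mutually
#' exclusive and exhaustive.
#'
#' @param genome A [psi_genome()].
#' @param site 0-based position of the U on the coding strand.
#' @param strand `"+"` or `"-"`.
#' @return One of `"UURAA"`, `"UURBA"`, `"UUYAA"`, `"other"`.
#' @export
classify_motif <- function(genome, site, strand = "+") {
  fm <- site_kmer(genome, site, strand, 0L, 4L)
  motif_class(fm)
}

# Classify RNA 5-mers (vectorised). First base must be the (candidate) site U.
motif_class <- function(fivemer) {
  b <- strsplit(fivemer, "")
  vapply(b, function(x) {
    if (length(x) != 5L) return("other")
    if (x[1] != "U" || x[2] != "U") return("other")
    r3 <- x[3] %in% c("A", "G")
    y3 <- x[3] %in% c("C", "U")
    if (r3 && x[4] == "A" && x[5] == "A") return("UURAA")
    if (y3 && x[4] == "A" && x[5] == "A") return("UUYAA")
    if (r3 && x[4] != "A" && x[5] == "A") return("UURBA")
    "other"
  }, character(1))
}

# Strand-aware RNA k-mer covering transcript-oriented offsets
# [site + from, site + to] relative to the site.
site_kmer <- function(genome, site, strand, from, to) {
  if (strand == "+") {
    a <- site + from; b <- site + to
  } else {
    a <- site - to; b <- site - from
  }
  assert_that(a >= 0 && b < genome_length(genome),
              "flank extends beyond the genome")
  dna_to_rna(genome_subseq(genome, a, b + 1L, strand))
}

#' Position-frequency matrix around a set of sites
#'
#' Counts each RNA base at every transcript-oriented offset in
#' `[-flank, +flank]` relative to the site (offset 0 is the site's U).
#' Columns sum to the number of sites.
#'
#' @param sites Tibble with columns `pos` and `strand`.
#' @param genome A [psi_genome()].
#' @param flank Number of positions on each side (default 5).
#' @return Integer matrix, rows `A`,`C`,`G`,`U`, columns named by offset.
#' @export
position_frequency <- function(sites, genome, flank = 5) {
  offs <- -flank:flank
  mat <- matrix(0L, 4, length(offs),
                dimnames = list(c("A", "C", "G", "U"), offs))
  for (i in seq_len(nrow(sites))) {
    km <- site_kmer(genome, sites$pos[i], sites$strand[i], -flank, flank)
    bases <- strsplit(km, "")[[1]]
    for (j in seq_along(offs)) {
      mat[bases[j], j] <- mat[bases[j], j] + 1L
    }
  }
  mat
}

#' Codon context of a site within a coding sequence
#'
#' Locates the site relative to the annotated CDS start (first base of the
#' start codon on the coding strand), returning the codon, its 1-based index,
#' the position of the site within the codon (1-3), and the encoded amino
#' acid (standard genetic code; `*` for stop).
#'
#' @param site 0-based coding-strand position of the U.
#' @param model One row of a [transcript_models()] table (the containing
#'   gene) or the full table plus `gene_id`.
#' @param genome A [psi_genome()].
#' @param gene_id Optional gene id when `model` is a full table.
#' @return Tibble with `codon`, `amino_acid`, `codon_index`,
#'   `position_in_codon`; or, for a site upstream of the CDS start
#'   (5' UTR) or without CDS annotation, a row of `NA`s.
#' @export
codon_context <- function(site, model, genome, gene_id = NULL) {
  if (!is.null(gene_id)) model <- model[model$gene_id == gene_id, , drop = FALSE]
  assert_that(nrow(model) == 1, "model must be a single gene row")
  no_ctx <- tibble::tibble(codon = NA_character_, amino_acid = NA_character_,
                           codon_index = NA_integer_,
                           position_in_codon = NA_integer_)
  if (is.na(model$cds_start)) return(no_ctx)
  offset <- if (model$strand == "+") site - model$cds_start
            else model$cds_start - site
  if (offset < 0) return(no_ctx)
  codon_index <- offset %/% 3L + 1L
  pos_in_codon <- offset %% 3L + 1L
  codon_from <- (codon_index - 1L) * 3L - offset  # offset of codon base 1 from site
  codon <- site_kmer(genome, site, model$strand, codon_from, codon_from + 2L)
  aa <- as.character(Biostrings::GENETIC_CODE[chartr("U", "T", codon)])
  tibble::tibble(codon = codon, amino_acid = aa,
                 codon_index = codon_index, position_in_codon = pos_in_codon)
}

#' Amino-acid context summary for a set of sites
#'
#' @param sites Tibble with `pos`, `strand`, `gene_id`.
#' @param models A [transcript_models()] table.
#' @param genome A [psi_genome()].
#' @return `sites` with codon-context columns appended.
#' @export
codon_context_all <- function(sites, models, genome) {
  ctx <- purrr::map2(sites$pos, sites$gene_id, function(p, g) {
    codon_context(p, models, genome, gene_id = g)
  })
  dplyr::bind_cols(sites, dplyr::bind_rows(ctx))
}

#' Select expression-matched background motif sites
#'
#' Finds all first-U positions of the `UURAA` motif (strand-aware) within
#' genes whose expression reaches `rpkm_min`, removes any that lie within
#' `exclusion_nt` of a called pseudouridine site on the same strand, and
#' optionally draws a deterministic uniform sample of `n_max` of them.
#'
#' @param models A [transcript_models()] table with an `rpkm` column.
#' @param genome A [psi_genome()].
#' @param psi_sites Tibble of called sites (`pos`, `strand`).
#' @param rpkm_min Expression floor (default 105).
#' @param exclusion_nt Exclusion radius around called sites (default 100).
#' @param n_max Optional cap on the number of returned sites.
#' @param seed Seed for the deterministic sample when `n_max` is set.
#' @return Tibble with `gene_id`, `pos`, `strand`, `motif`.
#' @export
select_background <- function(models, genome, psi_sites, rpkm_min = 105,
                              exclusion_nt = 100, n_max = NULL, seed = 1) {
  assert_that("rpkm" %in% names(models) && !anyNA(models$rpkm),
              "models must carry rpkm (see add_rpkm())")
  keep <- models[models$rpkm >= rpkm_min, , drop = FALSE]
  hits <- purrr::map(seq_len(nrow(keep)), function(i) {
    m <- keep[i, , drop = FALSE]
    s <- genome_subseq(genome, m$start, m$end, m$strand)  # coding strand
    starts <- gregexpr("TT[AG](?=AA)", s, perl = TRUE)[[1]]
    if (starts[1] == -1) return(NULL)
    u_tx <- as.integer(starts) - 1L
    tibble::tibble(
      gene_id = m$gene_id,
      pos = vapply(u_tx, to_genomic_coord, numeric(1), strand = m$strand,
                   start = m$start, end = m$end),
      strand = m$strand,
      motif = "UURAA"
    )
  })
  bg <- dplyr::bind_rows(hits)
  if (nrow(bg) && nrow(psi_sites)) {
    near <- purrr::map2_lgl(bg$pos, bg$strand, function(p, s) {
      any(psi_sites$strand == s & abs(psi_sites$pos - p) <= exclusion_nt)
    })
    bg <- bg[!near, , drop = FALSE]
  }
  if (!is.null(n_max) && nrow(bg) > n_max) {
    bg <- with_seed(seed, bg[sort(sample.int(nrow(bg), n_max)), , drop = FALSE])
  }
  bg
}
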