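# Independent brute-force oracles and small fixture builders. These
# re-derive expected values from first principles and deliberately share no
# code with the implementation.

# Sort-based order-statistic percentile (p in (0, 1]): walk the sorted
# values until at least a fraction p of them has been passed.
oracle_percentile <- function(x, p) {
  sx <- sort(x)
  n <- length(sx)
  for (k in seq_len(n)) {
    if (k / n >= p) return(sx[k])
  }
  sx[n]
}

# Brute-force winsorized Z: explicit capping, explicit mean and population sd.
oracle_z <- function(target_count, bg, coverage_min = 100) {
  if (target_count + sum(bg) < coverage_min) return(NA_real_)
  cap <- oracle_percentile(bg, 0.95)
  w <- bg
  for (i in seq_along(w)) if (w[i] > cap) w[i] <- cap
  m <- sum(w) / length(w)
  s2 <- sum((w - m)^2) / length(w)
  if (s2 <= 0) return(NA_real_)
  (target_count - m) / sqrt(s2)
}

# Independent window-constraint checker, phrased as the four nearest-end
# distances plus an interior-end check. w5/w3 are the inclusive window
# boundaries in transcript coordinates; ends5/ends3 are annotated transcript
# end positions in the same coordinates.
oracle_window_ok <- function(w5, w3, ends5, ends3) {
  up5 <- ends5[ends5 <= w5]
  if (length(up5) && w5 - max(up5) < 40) return(FALSE)
  up3 <- ends3[ends3 <= w5]
  if (length(up3) && w5 - max(up3) < 5) return(FALSE)
  down3 <- ends3[ends3 >= w3]
  if (length(down3) && min(down3) - w3 < 25) return(FALSE)
  down5 <- ends5[ends5 >= w3]
  if (length(down5) && min(down5) - w3 < 5) return(FALSE)
  # an end strictly inside the window violates the spirit of every rule
  if (any(ends5 > w5 & ends5 < w3) || any(ends3 > w5 & ends3 < w3)) {
    return(FALSE)
  }
  TRUE
}

# Independent reverse complement via character translation.
revcomp_chr <- function(s) {
  paste(rev(strsplit(chartr("ACGT", "TGCA", s), "")[[1]]), collapse = "")
}

# Regex-based 5-mer motif classifier.
oracle_motif <- function(k) {
  if (grepl("^UU[AG]AA$", k)) return("UURAA")
  if (grepl("^UU[CU]AA$", k)) return("UUYAA")
  if (grepl("^UU[AG][CGU]A$", k)) return("UURBA")
  "other"
}

# Window boundaries (transcript coordinates) recovered from a psi_window,
# mapped back through the containing gene.
window_tx_bounds <- function(win, models) {
  gi <- which(models$gene_id == win$gene_id)
  m <- models[gi, , drop = FALSE]
  tx <- if (m$strand == "+") win$background - m$start
        else (m$end - 1) - win$background
  range(tx)
}

# Bare data view of a track (drops library metadata attributes) for
# content comparisons.
track_df <- function(trk) {
  tibble::tibble(pos = trk$pos, strand = trk$strand, count = trk$count)
}

# A deterministic toy track from a named count specification
# (positions -> counts) on one strand.
toy_track <- function(counts_at, strand = "+", total = NULL, label = "toy") {
  end_track(
    tibble::tibble(pos = as.integer(names(counts_at)),
                   strand = strand, count = as.numeric(counts_at)),
    library_label = label, total_reads = total, chrom = "toy"
  )
}

# Single-gene fixture: plus-strand gene [0, L) with default boundary ends.
toy_models <- function(L = 600, strand = "+", gene_id = "g1") {
  transcript_models(tibble::tibble(
    gene_id = gene_id, strand = strand, start = 0L, end = as.integer(L),
    cds_start = if (strand == "+") 0L else as.integer(L - 1L)
  ))
}

# A small random genome with the given sequence inserted at `at` (plus
# strand coordinates).
toy_genome <- function(L = 600, insert = NULL, at = NULL, seed = 42) {
  set.seed(seed)
  s <- paste(sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = "")
  if (!is.null(insert)) substr(s, at + 1, at + nchar(insert)) <- insert
  psi_genome("toy", s)
}

# Shared synthetic study-condition fixture for recovery tests: 20 uniform
# transcripts of 1 kb, 10 planted sites across >= 3 enzymes.
recovery_config <- function(seed, depth = 2e5) {
  simulation_config(
    n_transcripts = 20, transcript_length = 1000,
    expression = rep(1, 20),
    planted_sites = planted_sites_grid(1:10,
                                       enzymes = c("rluA", "rluC", "rluD")),
    depth = depth, seed = seed
  )
}
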