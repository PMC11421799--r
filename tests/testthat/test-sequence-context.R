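# Motif classes, position-frequency matrices, codon context, and background
# site selection.

test_that("motif classes follow their definitions", {
  g <- toy_genome(40, insert = "TTGAA", at = 10)
  expect_equal(classify_motif(g, 10, "+"), "UURAA")
  g2 <- toy_genome(40, insert = "TTCAA", at = 10)
  expect_equal(classify_motif(g2, 10, "+"), "UUYAA")
  g3 <- toy_genome(40, insert = "TTGCA", at = 10)
  expect_equal(classify_motif(g3, 10, "+"), "UURBA")
  g4 <- toy_genome(40, insert = "ATGAA", at = 10)
  expect_equal(classify_motif(g4, 10, "+"), "other")
})

test_that("motif classification is strand-symmetric", {
  set.seed(9)
  for (i in 1:25) {
    km <- paste(sample(c("A", "C", "G", "T"), 5, TRUE), collapse = "")
    g <- toy_genome(40, insert = km, at = 10, seed = i)
    fwd <- classify_motif(g, 10, "+")
    grc <- psi_genome("rc", revcomp_chr(g$sequence))
    rev <- classify_motif(grc, 40 - 1 - 10, "-")
    expect_equal(fwd, rev)
  }
})

test_that("the motif-class partition is exhaustive and exclusive over all 1024 5-mers", {
  bases <- c("A", "C", "G", "U")
  kmers <- apply(expand.grid(bases, bases, bases, bases, bases), 1, paste,
                 collapse = "")
  expect_equal(length(kmers), 1024)
  got <- psistop:::motif_class(kmers)
  want <- vapply(kmers, oracle_motif, character(1), USE.NAMES = FALSE)
  expect_identical(got, want)
  # partition: every 5-mer lands in exactly one class
  expect_true(all(got %in% c("UURAA", "UURBA", "UUYAA", "other")))
  expect_equal(sum(got == "UURAA"), 2)       # UUAAA, UUGAA
  expect_equal(sum(got == "UUYAA"), 2)       # UUCAA, UUUAA
  expect_equal(sum(got == "UURBA"), 6)       # R x {C,G,U}
})

test_that("position-frequency matrices count planted motifs correctly", {
  # one site gives one-hot columns
  g <- toy_genome(60, insert = "TTGAA", at = 25)
  one <- position_frequency(tibble::tibble(pos = 25, strand = "+"), g,
                            flank = 3)
  expect_true(all(colSums(one) == 1))
  expect_equal(unname(one["U", "0"]), 1L)

  # 31 planted UURAA sites: invariant U columns at 0/+1 and A at +3/+4
  cfg <- simulation_config(n_transcripts = 31, transcript_length = 300,
                           depth = 100,
                           planted_sites = planted_sites_grid(
                             1:31, config_length = 300
                           ), seed = 23)
  tx <- make_transcriptome(cfg)
  pfm <- position_frequency(tx$truth, tx$genome, flank = 5)
  n <- nrow(tx$truth)
  expect_true(all(colSums(pfm) == n))
  expect_equal(unname(pfm["U", "0"]), n)
  expect_equal(unname(pfm["U", "1"]), n)
  expect_equal(unname(pfm["A", "3"]), n)
  expect_equal(unname(pfm["A", "4"]), n)
  expect_equal(unname(pfm["A", "2"] + pfm["G", "2"]), n)  # R at +2
})

test_that("codon context arithmetic and translation are correct", {
  # cds_start 100, site 106, plus strand: codon 3, position 1
  g <- toy_genome(300, insert = "GTT", at = 106)
  m <- transcript_models(tibble::tibble(
    gene_id = "g", strand = "+", start = 50L, end = 250L, cds_start = 100L
  ))
  ctx <- codon_context(106, m, g)
  expect_equal(ctx$codon_index, 3L)
  expect_equal(ctx$position_in_codon, 1L)
  expect_equal(ctx$codon, "GUU")
  expect_equal(ctx$amino_acid, "V")

  # site mid-codon: offset 7 -> codon 3, position 2
  ctx2 <- codon_context(107, m, g)
  expect_equal(ctx2$codon_index, 3L)
  expect_equal(ctx2$position_in_codon, 2L)

  # 5' UTR sites have no codon context
  utr <- codon_context(90, m, g)
  expect_true(is.na(utr$codon))

  # minus-strand gene: cds_start anchored at the 3'-most coordinate
  gm <- psi_genome("m", paste0(strrep("C", 100), revcomp_chr(
    paste0("ATG", "GTT", "TAA", strrep("G", 91))
  ), strrep("C", 100)))
  mm <- transcript_models(tibble::tibble(
    gene_id = "gm", strand = "-", start = 100L, end = 200L, cds_start = 199L
  ))
  ctx3 <- codon_context(196, mm, gm)  # transcript offset 3: codon 2, base 1
  expect_equal(ctx3$codon_index, 2L)
  expect_equal(ctx3$position_in_codon, 1L)
  expect_equal(ctx3$codon, "GUU")
  expect_equal(ctx3$amino_acid, "V")
})

test_that("sites planted in valine codons translate as valine throughout", {
  # plus-strand synthetic transcripts have their CDS anchored at the span
  # start; plant GTT at an in-frame offset and check the context end to end
  g <- toy_genome(400)
  s <- g$sequence
  for (off in c(120, 150, 180)) substr(s, off + 1, off + 3) <- "GTT"
  g <- psi_genome("toy", s)
  m <- transcript_models(tibble::tibble(
    gene_id = "g", strand = "+", start = 0L, end = 400L, cds_start = 0L
  ))
  sites <- tibble::tibble(gene_id = "g", pos = c(121, 151, 181), strand = "+")
  ctx <- codon_context_all(sites, m, g)
  expect_true(all(ctx$amino_acid == "V"))
  expect_true(all(ctx$position_in_codon == 2L))
})

test_that("background selection applies expression, motif, and exclusion filters", {
  cfg <- simulation_config(n_transcripts = 6, transcript_length = 600,
                           depth = 2e4,
                           planted_sites = planted_sites_grid(
                             1:2, config_length = 600
                           ), seed = 55)
  tx <- make_transcriptome(cfg)
  lib <- simulate_library(tx, cfg, "mock", seed = 56)
  models <- add_rpkm(tx$models, lib)

  rmin <- sort(models$rpkm)[3]  # keep the four most expressed genes
  bg <- select_background(models, tx$genome, tx$truth, rpkm_min = rmin)

  # brute-force scan: all UURAA first-U positions in qualifying genes,
  # minus anything within 100 nt of a planted site on the same strand
  want <- list()
  for (i in seq_len(nrow(models))) {
    m <- models[i, ]
    if (m$rpkm < rmin) next
    s <- genome_subseq(tx$genome, m$start, m$end, m$strand)
    hits <- gregexpr("TT[AG](?=AA)", s, perl = TRUE)[[1]]
    if (hits[1] == -1) next
    for (h in as.integer(hits) - 1L) {
      gpos <- if (m$strand == "+") m$start + h else (m$end - 1) - h
      near <- any(tx$truth$strand == m$strand &
                    abs(tx$truth$pos - gpos) <= 100)
      if (!near) want[[length(want) + 1]] <- c(gpos, m$strand)
    }
  }
  want_pos <- sort(as.integer(purrr::map_chr(want, 1)))
  expect_equal(sort(bg$pos), want_pos)
  # exclusion zones hold on every run
  for (i in seq_len(nrow(bg))) {
    expect_false(any(tx$truth$strand == bg$strand[i] &
                       abs(tx$truth$pos - bg$pos[i]) <= 100))
  }
  # motifs in under-expressed genes are excluded
  weak <- models$gene_id[models$rpkm < rmin]
  expect_false(any(bg$gene_id %in% weak))
  # n_max draws a deterministic subsample
  if (nrow(bg) > 3) {
    s1 <- select_background(models, tx$genome, tx$truth, rpkm_min = rmin,
                            n_max = 3, seed = 2)
    s2 <- select_background(models, tx$genome, tx$truth, rpkm_min = rmin,
                            n_max = 3, seed = 2)
    expect_identical(s1, s2)
    expect_equal(nrow(s1), 3)
  }
})
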