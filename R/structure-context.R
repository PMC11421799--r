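# Reactivity-constrained secondary-structure context: constraint preparation,
# a pluggable folding-engine contract, column-sum pairing profiles, and
# relative-position aggregation over site sets.

#' Build a reactivity window around a site
#'
#' Extracts the strand-aware sequence of the `2 * flank + 1` nt window
#' centred on the site (RNA alphabet) and aligns per-nucleotide chemical
#' probing reactivities to it. Only A and C react with DMS, so every other
#' base — and any A/C without a measurement — carries the placeholder
#' `-999`.
#'
#' @param site 0-based coding-strand position of the site.
#' @param strand `"+"` or `"-"`.
#' @param genome A [psi_genome()].
#' @param reactivities Tibble with columns `pos` (0-based genomic), `strand`,
#'   `reactivity`; may be `NULL` for a reactivity-free window.
#' @param flank Half-width in nt (default 50, i.e. a 101-nt window).
#' @return A list of class `psi_reactivity_window`: `site`, `strand`,
#'   `sequence` (RNA), `reactivity` (numeric vector, `-999` = no data),
#'   `offsets` (`-flank .. +flank`).
#' @export
reactivity_window <- function(site, strand, genome, reactivities = NULL,
                              flank = 50) {
  seq <- site_kmer(genome, site, strand, -flank, flank)
  offs <- -flank:flank
  react <- rep(-999, length(offs))
  bases <- strsplit(seq, "")[[1]]
  if (!is.null(reactivities)) {
    gpos <- if (strand == "+") site + offs else site - offs
    rr <- reactivities[reactivities$strand == strand, , drop = FALSE]
    hit <- match(gpos, rr$pos)
    ok <- !is.na(hit) & bases %in% c("A", "C")
    react[ok] <- rr$reactivity[hit[ok]]
  }
  structure(list(site = site, strand = strand, sequence = seq,
                 reactivity = react, offsets = offs),
            class = "psi_reactivity_window")
}

#' Emit a folding constraint table from a reactivity window
#'
#' One row per window position: 1-based position and reactivity, with `-999`
#' marking positions without data (non-A/C bases and unmeasured A/C). The
#' written file is whitespace-separated, the format consumed by
#' soft-constraint-aware folding engines.
#'
#' @param window A [reactivity_window()].
#' @param path Optional file to write.
#' @return Tibble with `position` (1-based) and `reactivity`.
#' @export
prepare_constraints <- function(window, path = NULL) {
  tab <- tibble::tibble(
    position = seq_along(window$reactivity),
    reactivity = window$reactivity
  )
  if (!is.null(path)) {
    readr::write_lines(sprintf("%d %g", tab$position, tab$reactivity), path)
  }
  tab
}

#' Read a constraint table written by [prepare_constraints()]
#' @param path Whitespace-separated (position, reactivity) file.
#' @return Tibble with `position`, `reactivity`.
#' @export
read_constraints <- function(path) {
  df <- readr::read_table(path, col_names = c("position", "reactivity"),
                          col_types = "id", progress = FALSE)
  tibble::as_tibble(df)
}

## ---------------------------------------------------------------------------
## Folding-engine contract
##
## An engine is a list with fields `name` and `fold`, where `fold(sequence,
## constraints)` returns a symmetric base-pair probability matrix over the
## sequence positions (partition-function ensemble, 37 degrees C).
## `constraints` is the tibble from prepare_constraints() or NULL for an
## unconstrained fold.

#' Deterministic stub folding engine
#'
#' Returns the configured matrix regardless of input — the engine used in
#' tests and anywhere the thermodynamic engine is not wanted. With
#' `matrix = NULL` it returns an all-zero matrix of the right size.
#'
#' @param matrix Optional fixed matrix to return (must match the sequence
#'   length at call time).
#' @return A folding engine.
#' @export
stub_engine <- function(matrix = NULL) {
  list(
    name = "stub",
    fold = function(sequence, constraints = NULL) {
      n <- nchar(sequence)
      if (is.null(matrix)) return(base::matrix(0, n, n))
      assert_that(nrow(matrix) == n && ncol(matrix) == n,
                  "stub matrix does not match sequence length")
      matrix
    }
  )
}

#' ViennaRNA RNAfold engine
#'
#' Shells out to `RNAfold -p -T 37` (partition-function mode), adding
#' `--shape <file> --shapeMethod=Z` when a constraint table is supplied, and
#' parses the base-pair probability dot plot (`ubox` records store
#' \eqn{\sqrt{p(i,j)}}). Requires the `RNAfold` executable on the PATH.
#'
#' @param rnafold Path to the RNAfold executable.
#' @param temperature Folding temperature in degrees C (default 37).
#' @return A folding engine.
#' @export
vienna_engine <- function(rnafold = "RNAfold", temperature = 37) {
  list(
    name = "RNAfold",
    fold = function(sequence, constraints = NULL) {
      if (Sys.which(rnafold) == "" && !file.exists(rnafold)) {
        abort(sprintf("folding engine '%s' not found on PATH", rnafold))
      }
      dir <- tempfile("fold")
      dir.create(dir)
      on.exit(unlink(dir, recursive = TRUE))
      fa <- file.path(dir, "in.fa")
      readr::write_lines(c(">win", dna_to_rna(sequence)), fa)
      args <- c("-p", "-T", format(temperature), "--noPS")
      if (!is.null(constraints)) {
        shp <- file.path(dir, "in.shape")
        readr::write_lines(
          sprintf("%d %g", constraints$position, constraints$reactivity), shp
        )
        args <- c(args, paste0("--shape=", shp), "--shapeMethod=Z")
      }
      out <- withr_local_dir(dir, function() {
        system2(rnafold, args, stdin = fa, stdout = TRUE, stderr = TRUE)
      })
      status <- attr(out, "status") %||% 0L
      dp <- file.path(dir, "win_dp.ps")
      if (status != 0 || !file.exists(dp)) {
        abort(paste0("RNAfold failed: ", paste(out, collapse = "\n")))
      }
      parse_dotplot(dp, nchar(sequence))
    }
  )
}

withr_local_dir <- function(dir, fn) {
  old <- setwd(dir)
  on.exit(setwd(old))
  fn()
}

# Parse an RNAfold dot-plot PostScript file into a symmetric probability
# matrix; ubox lines are "i j sqrt(p) ubox" (1-based).
parse_dotplot <- function(path, n) {
  lines <- readr::read_lines(path)
  ub <- grep("^\\d+\\s+\\d+\\s+[0-9.eE+-]+\\s+ubox\\s*$", lines, value = TRUE)
  mat <- matrix(0, n, n)
  if (length(ub)) {
    f <- do.call(rbind, strsplit(ub, "\\s+"))
    i <- as.integer(f[, 1]); j <- as.integer(f[, 2])
    p <- as.numeric(f[, 3])^2
    keep <- i >= 1 & j >= 1 & i <= n & j <= n
    mat[cbind(i[keep], j[keep])] <- p[keep]
    mat[cbind(j[keep], i[keep])] <- p[keep]
  }
  mat
}

#' Fold a reactivity window into a base-pair probability matrix
#'
#' Dispatches to the engine's `fold` method and validates the contract:
#' square symmetric matrix, probabilities in \[0, 1\].
#'
#' @param window A [reactivity_window()].
#' @param constraints Constraint tibble from [prepare_constraints()], or
#'   `NULL` for an unconstrained fold.
#' @param engine A folding engine ([stub_engine()] or [vienna_engine()]).
#' @return Symmetric numeric matrix of pairing probabilities.
#' @export
fold_window <- function(window, constraints = NULL, engine = stub_engine()) {
  mat <- engine$fold(window$sequence, constraints)
  n <- nchar(window$sequence)
  assert_that(is.matrix(mat) && nrow(mat) == n && ncol(mat) == n,
              sprintf("engine '%s' returned a malformed matrix", engine$name))
  assert_that(max(abs(mat - t(mat))) < 1e-8,
              sprintf("engine '%s' returned an asymmetric matrix", engine$name))
  assert_that(min(mat) >= 0 && max(mat) <= 1 + 1e-8,
              sprintf("engine '%s' returned probabilities outside [0, 1]",
                      engine$name))
  mat
}

#' Per-position pairing probability profile
#'
#' Sums each column of the base-pair probability matrix to summarise how
#' likely each position is to be paired with anything, clipping at 1. An
#' unclipped excess above 0.05 triggers a warning since a consistent ensemble
#' matrix should have row sums at most 1.
#'
#' @param matrix Symmetric pairing probability matrix.
#' @return Numeric vector of per-position pairing probabilities in \[0, 1\].
#' @export
pairing_profile <- function(matrix) {
  sums <- colSums(matrix)
  if (any(sums > 1.05)) {
    warn(sprintf("pairing profile exceeds 1 by up to %.3f before clipping; the matrix may be inconsistent",
                 max(sums) - 1))
  }
  pmin(sums, 1)
}

#' Aggregate pairing profiles by position relative to the site
#'
#' Stacks per-site pairing profiles (each centred on its site) and summarises
#' the distribution of pairing probability at every relative offset with the
#' median and quartiles. Target and background site sets are summarised with
#' identical machinery; results are invariant to site ordering.
#'
#' @param profiles List of numeric profiles, all the same odd length, each
#'   centred on its site.
#' @param group Label attached to the summary (e.g. `"target"`,
#'   `"background"`).
#' @return A `psi_pairing_summary`: list with `values` (tibble: `site_index`,
#'   `offset`, `pairing`) and `summary` (tibble: `offset`, `median`, `q25`,
#'   `q75`, `group`).
#' @export
aggregate_relative <- function(profiles, group = "target") {
  assert_that(length(profiles) >= 1, "need at least one profile")
  len <- unique(lengths(profiles))
  assert_that(length(len) == 1 && len %% 2 == 1,
              "profiles must share one odd length (centred on the site)")
  flank <- (len - 1) / 2
  offs <- -flank:flank
  values <- purrr::imap(profiles, function(p, i) {
    tibble::tibble(site_index = i, offset = offs, pairing = as.numeric(p))
  }) |> dplyr::bind_rows()
  summary <- values |>
    dplyr::group_by(.data$offset) |>
    dplyr::summarise(
      median = median(.data$pairing),
      q25 = quantile(.data$pairing, 0.25, names = FALSE),
      q75 = quantile(.data$pairing, 0.75, names = FALSE),
      .groups = "drop"
    ) |>
    dplyr::mutate(group = group)
  structure(list(values = values, summary = summary, group = group),
            class = "psi_pairing_summary")
}

#' Structure-context pipeline for a site set
#'
#' Builds reactivity windows, prepares constraints, folds each window with
#' the supplied engine, and aggregates column-sum pairing profiles by
#' relative position.
#'
#' @param sites Tibble with `pos`, `strand`.
#' @param genome A [psi_genome()].
#' @param reactivities Optional reactivity tibble (see
#'   [reactivity_window()]).
#' @param engine A folding engine.
#' @param flank Window half-width (default 50).
#' @param group Label for the resulting summary.
#' @return A `psi_pairing_summary`.
#' @export
structure_context <- function(sites, genome, reactivities = NULL,
                              engine = stub_engine(), flank = 50,
                              group = "target") {
  profiles <- purrr::map(seq_len(nrow(sites)), function(i) {
    w <- reactivity_window(sites$pos[i], sites$strand[i], genome,
                           reactivities, flank = flank)
    cons <- if (is.null(reactivities)) NULL else prepare_constraints(w)
    pairing_profile(fold_window(w, cons, engine))
  })
  aggregate_relative(profiles, group = group)
}
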