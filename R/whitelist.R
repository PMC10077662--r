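#' Select high-quality putative barcodes by minQ
#'
#' Step 2 of the pipeline: putative barcodes whose minimum per-base Phred
#' score across the 16 barcode bases (minQ) is below the threshold are
#' discarded, because basecalling errors concentrate at low-quality bases.
#'
#' @param pbs putative-barcode DataFrame from
#'   \code{\link{extractPutativeBarcodes}}.
#' @param min_q_threshold minimum acceptable minQ (default 15); records with
#'   \code{min_q >= min_q_threshold} are kept. 0 keeps everything.
#' @return the filtered DataFrame.
#' @export
filterHighQuality <- function(pbs, min_q_threshold = 15L) {
  stopifnot("min_q" %in% colnames(pbs))
  pbs[pbs$min_q >= min_q_threshold, , drop = FALSE]
}

#' Discard putative barcodes absent from a known barcode list
#'
#' Putative barcodes that do not appear in the list of all possible 10x
#' barcodes cannot be genuine and are dropped before counting. With
#' \code{full_list = NULL} the stream passes through unchanged.
#'
#' @param pbs putative-barcode DataFrame.
#' @param full_list character vector of admissible 16-mers, or \code{NULL}.
#' @return the filtered DataFrame.
#' @export
filterKnownBarcodes <- function(pbs, full_list = NULL) {
  if (is.null(full_list)) return(pbs)
  if (length(full_list) == 0L && nrow(pbs) > 0L)
    warning("empty known-barcode list: every putative barcode is dropped")
  pbs[pbs$barcode %in% full_list, , drop = FALSE]
}

#' Count unique putative barcodes
#'
#' @param pbs putative-barcode DataFrame (typically after
#'   \code{\link{filterKnownBarcodes}} and \code{\link{filterHighQuality}}).
#' @return a \linkS4class{BarcodeCountTable}; its \code{total} equals
#'   \code{nrow(pbs)}.
#' @export
countBarcodes <- function(pbs) {
  stopifnot("barcode" %in% colnames(pbs))
  if (nrow(pbs) == 0L)
    return(new("BarcodeCountTable", barcode = character(),
               count = integer(), total = 0L))
  tab <- table(pbs$barcode)
  BarcodeCountTable(names(tab), as.integer(tab))
}

#' Quantile-based count threshold
#'
#' For an expected number of recovered cells N, take c = the count of the
#' unique high-quality barcode at (1-based, descending) rank
#' \code{ceiling(0.95 * N)}, and return the threshold T = 0.05 * c. The rank
#' is clamped to the number of unique barcodes (with a warning) so that
#' small tables still run.
#'
#' @param x a non-empty \linkS4class{BarcodeCountTable}.
#' @param expected_cells N, a plausible number of recovered cells (>= 1).
#' @return numeric threshold T (generally fractional).
#' @examples
#' tab <- BarcodeCountTable(sprintf("BC%04d", 1:1000), rep(100L, 1000))
#' quantileThreshold(tab, 500)  # rank 475 -> c = 100 -> T = 5
#' @export
quantileThreshold <- function(x, expected_cells = 500L) {
  stopifnot(is(x, "BarcodeCountTable"))
  if (length(x) == 0L) stop("cannot take a quantile of an empty count table")
  if (expected_cells < 1L) stop("expected_cells must be >= 1")
  r <- ceiling(0.95 * expected_cells)
  if (r > length(x)) {
    warning("rank ", r, " exceeds the ", length(x),
            " unique barcodes; clamping to the smallest count")
    r <- length(x)
  }
  r <- max(r, 1L)
  0.05 * x@count[r]
}

#' Call the cell-associated barcode whitelist
#'
#' Step 3 of the pipeline: barcodes whose count is strictly greater than the
#' quantile threshold T (see \code{\link{quantileThreshold}}) are called as
#' cell-associated. In high-sensitivity mode T is reduced to 10% of the
#' default, trading precision for recall; the high-sensitivity whitelist is
#' therefore always a superset of the default one.
#'
#' @param x a non-empty \linkS4class{BarcodeCountTable}.
#' @param expected_cells N used for the quantile rank (default 500).
#' @param mode \code{"default"} or \code{"high_sensitivity"}.
#' @return a \linkS4class{BarcodeWhitelist}, barcodes in descending count
#'   order.
#' @export
buildWhitelist <- function(x, expected_cells = 500L,
                           mode = c("default", "high_sensitivity")) {
  mode <- match.arg(mode)
  thr <- quantileThreshold(x, expected_cells)
  if (mode == "high_sensitivity") thr <- 0.1 * thr
  new("BarcodeWhitelist", barcodes = x@barcode[x@count > thr],
      threshold = thr, expected_cells = as.integer(expected_cells),
      mode = mode)
}

#' Pairwise Levenshtein distances
#'
#' Unit-cost edit distance (insertions, deletions, substitutions) between
#' two sets of strings, computed with \code{utils::adist}.
#'
#' @param a,b character vectors.
#' @return an integer \code{length(a) x length(b)} matrix, dropped to a
#'   vector/scalar when either side has length 1.
#' @examples
#' editDistance("kitten", "sitting")  # 3
#' @export
editDistance <- function(a, b) {
  d <- drop(utils::adist(a, b))
  storage.mode(d) <- "integer"
  d
}

#' Minimum edit distance from each query to a reference set
#'
#' @param query character vector.
#' @param reference character vector; if empty, \code{Inf} is returned for
#'   every query (the constraint is vacuous).
#' @param chunk number of query rows per \code{adist} call (memory bound).
#' @return numeric vector of per-query minima.
#' @export
minEditDistance <- function(query, reference, chunk = 512L) {
  if (length(query) == 0L) return(numeric())
  if (length(reference) == 0L) return(rep(Inf, length(query)))
  out <- numeric(length(query))
  for (i in seq(1L, length(query), by = chunk)) {
    j <- min(i + chunk - 1L, length(query))
    out[i:j] <- apply(utils::adist(query[i:j], reference), 1L, min)
  }
  out
}

#' Generate background barcodes for empty-droplet analysis
#'
#' Returns \code{n} barcodes, each at Levenshtein distance strictly greater
#' than \code{min_ed_exclusive} from every whitelist barcode, so that reads
#' from real cells cannot be mis-assigned to them and bias the ambient RNA
#' profile. Candidates are drawn first (uniformly, seeded) from observed
#' non-whitelist barcodes in the count table -- these carry a genuine
#' ambient profile downstream -- then topped up with random 16-mers
#' satisfying the same constraint.
#'
#' @param x a \linkS4class{BarcodeCountTable} of observed barcodes.
#' @param whitelist a \linkS4class{BarcodeWhitelist} (or character vector).
#' @param n number of background barcodes to return (> 0).
#' @param min_ed_exclusive minimum excluded distance (default 4: kept
#'   barcodes satisfy min ED > 4).
#' @param seed optional integer seed for reproducible draws.
#' @return character vector of \code{n} distinct 16-mers.
#' @export
backgroundBarcodes <- function(x, whitelist, n = 5000L,
                               min_ed_exclusive = 4L, seed = NULL) {
  if (n <= 0L) stop("n must be positive")
  wl <- barcodes(whitelist)
  if (!is.null(seed)) set.seed(seed)
  observed <- setdiff(barcodes(x), wl)
  picked <- character()
  if (length(observed)) {
    cand <- sample(observed)
    ok <- minEditDistance(cand, wl) > min_ed_exclusive
    picked <- head(cand[ok], n)
  }
  tries <- 0L
  while (length(picked) < n) {
    batch <- randomBarcodes(max(256L, n - length(picked)),
                            avoid = c(wl, picked))
    ok <- minEditDistance(batch, wl) > min_ed_exclusive
    picked <- c(picked, head(batch[ok], n - length(picked)))
    tries <- tries + 1L
    if (tries > 1000L)
      stop("could not generate enough background barcodes at ED > ",
           min_ed_exclusive)
  }
  picked
}

#' Barcode rank (knee plot) data
#'
#' @param x a \linkS4class{BarcodeCountTable}.
#' @return data.frame with columns \code{rank}, \code{barcode}, \code{count}
#'   over all table entries, for log-log barcode-rank plots.
#' @export
kneeData <- function(x) {
  stopifnot(is(x, "BarcodeCountTable"))
  data.frame(rank = seq_along(x@barcode), barcode = x@barcode,
             count = x@count)
}

#' Write a whitelist (or any barcode set) to a text file
#'
#' One 16-mer per line, in the object's (descending count) order.
#'
#' @param x a \linkS4class{BarcodeWhitelist} or character vector.
#' @param path output path.
#' @param cellranger_suffix append "-1" to each barcode for compatibility
#'   with Cell Ranger-style whitelists.
#' @return \code{path}, invisibly.
#' @export
writeWhitelist <- function(x, path, cellranger_suffix = FALSE) {
  bc <- barcodes(x)
  if (cellranger_suffix) bc <- paste0(bc, "-1")
  writeLines(bc, path)
  invisible(path)
}
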