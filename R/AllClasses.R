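#' Ranked table of high-quality putative barcode counts
#'
#' Occurrence counts of unique (high-quality) putative barcodes, stored in
#' descending count order with lexicographic tie-breaking so that ranks are
#' reproducible. \code{total} is the number of putative-barcode records that
#' were counted.
#'
#' @slot barcode character vector of unique 16-mers, descending count order.
#' @slot count integer vector of occurrence counts (all >= 1).
#' @slot total integer, number of records counted (equals \code{sum(count)}).
#'
#' @seealso \code{\link{countBarcodes}}, \code{\link{quantileThreshold}},
#'   \code{\link{buildWhitelist}}, \code{\link{kneeData}}
#' @export
setClass("BarcodeCountTable",
  slots = c(barcode = "character", count = "integer", total = "integer"))

setValidity("BarcodeCountTable", function(object) {
  msg <- character()
  if (length(object@barcode) != length(object@count))
    msg <- c(msg, "barcode and count must have equal length")
  if (length(object@count) && any(object@count < 1L))
    msg <- c(msg, "all counts must be >= 1")
  if (length(object@total) != 1L || object@total != sum(object@count))
    msg <- c(msg, "total must equal sum(count)")
  if (anyDuplicated(object@barcode))
    msg <- c(msg, "barcodes must be unique")
  if (length(object@count) > 1L) {
    o <- order(-object@count, object@barcode)
    if (!identical(o, seq_along(object@count)))
      msg <- c(msg, "entries must be sorted by descending count, ties lexicographic")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a BarcodeCountTable
#'
#' @param barcode character vector of barcodes (not necessarily unique order).
#' @param count integer vector of counts, parallel to \code{barcode}.
#' @return A \linkS4class{BarcodeCountTable}, sorted by descending count with
#'   lexicographic tie-breaking.
#' @examples
#' BarcodeCountTable(c("AAAA", "CCCC", "GGGG"), c(5L, 10L, 5L))
#' @export
BarcodeCountTable <- function(barcode, count) {
  barcode <- as.character(barcode)
  count <- as.integer(count)
  o <- order(-count, barcode)
  new("BarcodeCountTable", barcode = barcode[o], count = count[o],
      total = sum(count))
}

#' A called barcode whitelist
#'
#' The set of cell-associated barcodes called from a
#' \linkS4class{BarcodeCountTable}, together with the count threshold T and
#' the expected cell number N that produced it. Barcodes are kept in
#' descending count order. Every member's count in the source table is
#' strictly greater than \code{threshold}.
#'
#' @slot barcodes character vector of called 16-mers, descending count order.
#' @slot threshold numeric scalar, the count threshold T (counts > T pass).
#' @slot expected_cells integer, the N used for the quantile rank.
#' @slot mode \code{"default"} or \code{"high_sensitivity"} (T reduced to 10%).
#' @seealso \code{\link{buildWhitelist}}, \code{\link{writeWhitelist}}
#' @export
setClass("BarcodeWhitelist",
  slots = c(barcodes = "character", threshold = "numeric",
            expected_cells = "integer", mode = "character"))

setValidity("BarcodeWhitelist", function(object) {
  msg <- character()
  if (length(object@threshold) != 1L || object@threshold < 0)
    msg <- c(msg, "threshold must be a single non-negative number")
  if (!object@mode %in% c("default", "high_sensitivity"))
    msg <- c(msg, "mode must be 'default' or 'high_sensitivity'")
  if (anyDuplicated(object@barcodes))
    msg <- c(msg, "whitelist barcodes must be unique")
  if (length(msg)) msg else TRUE
})

#' Precision-recall curve over count thresholds
#'
#' @slot points data.frame with columns \code{threshold}, \code{precision},
#'   \code{recall}, ordered by increasing threshold.
#' @slot auc numeric in [0, 1], trapezoidal area under precision over recall.
#' @seealso \code{\link{precisionRecallCurve}}
#' @export
setClass("PRCurve", slots = c(points = "data.frame", auc = "numeric"))

setValidity("PRCurve", function(object) {
  msg <- character()
  need <- c("threshold", "precision", "recall")
  if (!all(need %in% names(object@points)))
    msg <- c(msg, "points must have threshold, precision and recall columns")
  else {
    p <- object@points
    if (is.unsorted(p$threshold))
      msg <- c(msg, "points must be ordered by increasing threshold")
    # recall is non-increasing as the threshold rises
    if (nrow(p) > 1L && any(diff(p$recall) > 1e-12))
      msg <- c(msg, "recall must be non-increasing in the threshold")
  }
  if (length(object@auc) != 1L || object@auc < 0 || object@auc > 1 + 1e-12)
    msg <- c(msg, "auc must be a single value in [0, 1]")
  if (length(msg)) msg else TRUE
})

#' Simulation configuration
#'
#' Parameters of the single-cell long-read simulator. A simulated perfect
#' read is the concatenation nanopore adaptor + 10x adaptor + 16-nt cell
#' barcode + UMI + polyT + cDNA fragment + TSO, reverse-complemented with
#' probability 1/2, after which per-base errors and Phred scores are
#' injected. See \code{\link{simConfig}} for defaults and units.
#'
#' @slot n_cells integer, number of true cells.
#' @slot reads_per_cell per-cell read depth: a single number, a vector of
#'   length \code{n_cells}, or \code{list(dist="nb", mean=, size=)}.
#' @slot n_background integer, number of ambient (non-cell) barcodes.
#' @slot background_reads per-background-barcode read counts: a number, a
#'   vector, or \code{list(dist="uniform", min=, max=)}.
#' @slot barcode_universe optional character vector of 16-mers to draw cell
#'   and background barcodes from; \code{NULL} means random distinct 16-mers.
#' @slot umi_len,fragment_len,polyt_len integer segment lengths (nt).
#' @slot fragment_fasta optional path to a transcript FASTA to sample
#'   fragments from; \code{NULL} means uniform random fragments.
#' @slot sub_rate,ins_rate,del_rate per-base error probabilities.
#' @slot q_correct_mean,q_correct_sd,q_error_mean,q_error_sd,q_min,q_max
#'   parameters of the two-component Gaussian Phred model.
#' @slot nanopore_adaptor,tenx_adaptor,tso adaptor constants (the 10x adaptor
#'   must end in the searched tail, by default CTTCCGATCT).
#' @slot seed integer seed; \code{NA} leaves the RNG state untouched.
#' @export
setClass("SimConfig",
  slots = c(
    n_cells = "integer", reads_per_cell = "ANY",
    n_background = "integer", background_reads = "ANY",
    barcode_universe = "ANY",
    umi_len = "integer", fragment_len = "integer", polyt_len = "integer",
    fragment_fasta = "ANY",
    sub_rate = "numeric", ins_rate = "numeric", del_rate = "numeric",
    q_correct_mean = "numeric", q_correct_sd = "numeric",
    q_error_mean = "numeric", q_error_sd = "numeric",
    q_min = "integer", q_max = "integer",
    nanopore_adaptor = "character", tenx_adaptor = "character",
    tso = "character", seed = "integer"))

setValidity("SimConfig", function(object) {
  msg <- character()
  rates <- c(object@sub_rate, object@ins_rate, object@del_rate)
  if (any(rates < 0) || any(rates > 1))
    msg <- c(msg, "error rates must lie in [0, 1]")
  if (object@n_cells < 0L) msg <- c(msg, "n_cells must be >= 0")
  if (object@n_background < 0L) msg <- c(msg, "n_background must be >= 0")
  if (object@umi_len < 1L) msg <- c(msg, "umi_len must be >= 1")
  if (object@fragment_len < 1L) msg <- c(msg, "fragment_len must be >= 1")
  if (!grepl("^[ACGT]+$", object@tenx_adaptor))
    msg <- c(msg, "tenx_adaptor must be a non-empty ACGT string")
  if (length(msg)) msg else TRUE
})

## ---- accessors ------------------------------------------------------------

#' Extract barcodes from a whitelist or count table
#'
#' @param x a \linkS4class{BarcodeWhitelist}, \linkS4class{BarcodeCountTable}
#'   or plain character vector (returned as-is).
#' @return character vector of barcodes.
#' @export
setGeneric("barcodes", function(x) standardGeneric("barcodes"))

#' @rdname barcodes
#' @export
setMethod("barcodes", "BarcodeWhitelist", function(x) x@barcodes)

#' @rdname barcodes
#' @export
setMethod("barcodes", "BarcodeCountTable", function(x) x@barcode)

#' @rdname barcodes
#' @export
setMethod("barcodes", "character", function(x) x)

#' @describeIn BarcodeCountTable occurrence counts, named by barcode.
#' @param object a \linkS4class{BarcodeCountTable}.
#' @export
setMethod("counts", "BarcodeCountTable", function(object)
  stats::setNames(object@count, object@barcode))

#' Count threshold of a whitelist
#' @param x a \linkS4class{BarcodeWhitelist}.
#' @return numeric scalar T; barcodes with count > T were called.
#' @export
setGeneric("threshold", function(x) standardGeneric("threshold"))

#' @rdname threshold
#' @export
setMethod("threshold", "BarcodeWhitelist", function(x) x@threshold)

#' @describeIn PRCurve the (threshold, precision, recall) points.
#' @param x a \linkS4class{PRCurve}.
#' @export
prPoints <- function(x) {
  stopifnot(is(x, "PRCurve"))
  x@points
}

#' @describeIn PRCurve area under the precision-recall curve.
#' @export
prAUC <- function(x) {
  stopifnot(is(x, "PRCurve"))
  x@auc
}

setMethod("length", "BarcodeCountTable", function(x) length(x@barcode))
setMethod("length", "BarcodeWhitelist", function(x) length(x@barcodes))

## ---- show -----------------------------------------------------------------

setMethod("show", "BarcodeCountTable", function(object) {
  cat("BarcodeCountTable with", length(object@barcode),
      "unique barcodes from", object@total, "records\n")
  if (length(object@barcode)) {
    k <- min(5L, length(object@barcode))
    cat("  top counts:",
        paste0(object@barcode[seq_len(k)], "=", object@count[seq_len(k)],
               collapse = " "), "\n")
  }
})

setMethod("show", "BarcodeWhitelist", function(object) {
  cat("BarcodeWhitelist of", length(object@barcodes), "barcodes",
      sprintf("(mode=%s, N=%d, T=%.3g)\n", object@mode,
              object@expected_cells, object@threshold))
})

setMethod("show", "PRCurve", function(object) {
  cat("PRCurve with", nrow(object@points), "thresholds, AUC =",
      sprintf("%.4f\n", object@auc))
})

setMethod("show", "SimConfig", function(object) {
  cat("SimConfig:", object@n_cells, "cells,", object@n_background,
      "background barcodes\n")
  cat(sprintf("  error rates sub=%.3g ins=%.3g del=%.3g (total %.3g)\n",
              object@sub_rate, object@ins_rate, object@del_rate,
              object@sub_rate + object@ins_rate + object@del_rate))
  cat(sprintf("  layout: adaptor(%dnt)+10x(%dnt)+BC(16)+UMI(%d)+T%d+frag(%d)+TSO(%dnt)\n",
              nchar(object@nanopore_adaptor), nchar(object@tenx_adaptor),
              object@umi_len, object@polyt_len, object@fragment_len,
              nchar(object@tso)))
})
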