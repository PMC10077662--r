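#' Precision-recall curve of a barcode count table against a ground truth
#'
#' For every count threshold t the predicted whitelist is the set of
#' barcodes with count > t; precision is |predicted and true| / |predicted|
#' (defined as 1 when the prediction is empty) and recall is
#' |predicted and true| / |truth|. With \code{thresholds = "all"} every
#' distinct count value plus 0 is used, which traces the full curve. The
#' AUC is the trapezoidal area of precision over recall, with an anchored
#' (recall = 0, precision = first point's precision) endpoint.
#'
#' @param x a \linkS4class{BarcodeCountTable}.
#' @param truth non-empty character vector of true cell barcodes.
#' @param thresholds numeric vector of thresholds, or \code{"all"}.
#' @return a \linkS4class{PRCurve}.
#' @export
precisionRecallCurve <- function(x, truth, thresholds = "all") {
  stopifnot(is(x, "BarcodeCountTable"))
  truth <- unique(as.character(truth))
  if (length(truth) == 0L) stop("ground truth must be non-empty")
  if (identical(thresholds, "all"))
    thresholds <- sort(unique(c(0, x@count)))
  thresholds <- sort(as.numeric(thresholds))

  in_truth <- x@barcode %in% truth
  pts <- vapply(thresholds, function(t) {
    sel <- x@count > t
    np <- sum(sel)
    tp <- sum(in_truth & sel)
    c(precision = if (np == 0L) 1 else tp / np,
      recall = tp / length(truth))
  }, numeric(2))

  points <- data.frame(threshold = thresholds, precision = pts["precision", ],
                       recall = pts["recall", ])
  new("PRCurve", points = points, auc = prTrapezoidAUC(points))
}

# trapezoid over recall with an anchored (0, first-precision) endpoint;
# recall ties are walked in descending-threshold order so a perfect
# separation integrates to exactly 1
prTrapezoidAUC <- function(points) {
  o <- order(points$recall, -points$threshold)
  r <- points$recall[o]
  p <- points$precision[o]
  r <- c(0, r)
  p <- c(p[1L], p)
  sum(diff(r) * (utils::head(p, -1L) + p[-1L]) / 2)
}

#' Fraction of query barcodes within an edit-distance cutoff of a reference
#'
#' The contamination diagnostic: barcodes derived from sequencing errors of
#' real barcodes sit at small edit distance from them, whereas a random
#' selection of barcodes does not. Reports the fraction of \code{query}
#' whose minimum Levenshtein distance to any \code{reference} barcode is
#' <= \code{cutoff}.
#'
#' @param query,reference non-empty character vectors of barcodes.
#' @param cutoff edit-distance cutoff (default 2).
#' @return a fraction in [0, 1].
#' @export
edContaminationFraction <- function(query, reference, cutoff = 2L) {
  query <- as.character(query)
  reference <- as.character(reference)
  if (!length(query) || !length(reference))
    stop("query and reference must be non-empty")
  mean(minEditDistance(query, reference) <= cutoff)
}

#' Write precision-recall points to CSV
#'
#' @param x a \linkS4class{PRCurve}.
#' @param path output CSV path.
#' @return \code{path}, invisibly.
#' @export
writePRCurve <- function(x, path) {
  stopifnot(is(x, "PRCurve"))
  utils::write.csv(x@points, path, row.names = FALSE)
  invisible(path)
}
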