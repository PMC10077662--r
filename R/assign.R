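#' Assign putative barcodes to whitelist entries by edit distance
#'
#' Each read's putative barcode is matched to the whitelist: an exact match
#' wins immediately; otherwise the unique whitelist barcode at minimal
#' Levenshtein distance <= \code{max_ed} wins. If two or more whitelist
#' barcodes tie at the minimal distance the read is left unassigned (no
#' rescue by quality or abundance). Reads assigned to a whitelist barcode
#' are the "usable reads" of the pipeline.
#'
#' @param pbs putative-barcode DataFrame from
#'   \code{\link{extractPutativeBarcodes}} (any filtering level).
#' @param whitelist a \linkS4class{BarcodeWhitelist} or character vector;
#'   must be non-empty.
#' @param max_ed maximum allowed edit distance (default 2).
#' @return \link[S4Vectors]{DataFrame} with one row per input record:
#'   \code{read_id}, \code{barcode} (assigned whitelist 16-mer or \code{NA}),
#'   \code{edit_dist} (or \code{NA}), \code{umi}. \code{metadata()$summary}
#'   holds \code{n_putative}, \code{n_assigned} and \code{assigned_fraction}.
#' @export
assignReads <- function(pbs, whitelist, max_ed = 2L) {
  wl <- barcodes(whitelist)
  if (length(wl) == 0L) stop("whitelist is empty")
  stopifnot(all(c("read_id", "barcode", "umi") %in% colnames(pbs)))

  ub <- unique(as.character(pbs$barcode))
  hit <- rep(NA_character_, length(ub))
  ed <- rep(NA_integer_, length(ub))

  exact <- match(ub, wl)
  hit[!is.na(exact)] <- wl[exact[!is.na(exact)]]
  ed[!is.na(exact)] <- 0L

  todo <- which(is.na(exact))
  chunk <- 512L
  for (i in seq_len(ceiling(length(todo) / chunk))) {
    idx <- todo[((i - 1L) * chunk + 1L):min(i * chunk, length(todo))]
    d <- utils::adist(ub[idx], wl)
    mn <- apply(d, 1L, min)
    nmin <- rowSums(d == mn)
    okrow <- mn <= max_ed & nmin == 1L
    hit[idx[okrow]] <- wl[apply(d[okrow, , drop = FALSE], 1L, which.min)]
    ed[idx[okrow]] <- as.integer(mn[okrow])
  }

  m <- match(pbs$barcode, ub)
  out <- DataFrame(read_id = as.character(pbs$read_id), barcode = hit[m],
                   edit_dist = ed[m], umi = as.character(pbs$umi))
  n_assigned <- sum(!is.na(out$barcode))
  metadata(out)$summary <- list(
    n_putative = nrow(out), n_assigned = n_assigned,
    assigned_fraction = if (nrow(out)) n_assigned / nrow(out) else NA_real_)
  out
}
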