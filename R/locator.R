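#' Locator parameters
#'
#' Parameters of the adaptor/polyT locator. The defaults implement the
#' standard search: the last 10 nt of the 10x adaptor (\code{CTTCCGATCT})
#' aligned semi-globally with up to 2 edits within the first 200 nt of each
#' strand, a lenient polyT check looking for \code{t_run} consecutive Ts
#' 20--50 nt downstream of the adaptor end (lenient because nanopore
#' basecalling truncates homopolymers), and a 12-nt UMI.
#'
#' @param adaptor_tail ACGT string searched for (default the last 10 nt of
#'   the 10x adaptor).
#' @param max_ed maximum edit distance (mismatches, insertions, deletions).
#' @param search_window how many leading bases of each strand are searched.
#' @param polyt_start,polyt_end half-open offset window, relative to the
#'   first base after the adaptor, in which the polyT run must start.
#' @param t_run length of the required T homopolymer.
#' @param umi_len UMI length in nt (10x v3 chemistry uses 10--12).
#' @return a named list of class \code{locator_params}.
#' @export
locatorParams <- function(adaptor_tail = "CTTCCGATCT", max_ed = 2L,
                          search_window = 200L, polyt_start = 20L,
                          polyt_end = 50L, t_run = 4L, umi_len = 12L) {
  adaptor_tail <- toupper(adaptor_tail)
  if (!grepl("^[ACGT]+$", adaptor_tail))
    stop("adaptor_tail must be a non-empty ACGT string")
  structure(list(adaptor_tail = adaptor_tail, max_ed = as.integer(max_ed),
                 search_window = as.integer(search_window),
                 polyt_start = as.integer(polyt_start),
                 polyt_end = as.integer(polyt_end),
                 t_run = as.integer(t_run), umi_len = as.integer(umi_len)),
            class = "locator_params")
}

#' Find candidate adaptor alignments on one strand
#'
#' Aligns \code{adaptor_tail} semi-globally (the adaptor end-to-end, free
#' placement) within the first \code{search_window} nt of each sequence and
#' reports every distinct placement with edit cost <= \code{max_ed}. N in the
#' read never matches. Overlapping placements (end positions within
#' \code{nchar(adaptor_tail)} of each other) are collapsed to the single
#' lowest-cost one, ties resolved towards the smallest end position.
#'
#' @param seqs character vector of strand sequences (uppercase ACGTN).
#' @param adaptor_tail,max_ed,search_window see \code{\link{locatorParams}}.
#' @return a list, one element per sequence, each an integer matrix with
#'   columns \code{end_pos} (0-based index of the first base after the
#'   adaptor) and \code{edit_dist}. Short or empty sequences give 0 rows.
#' @examples
#' read <- paste0(strrep("A", 50), "CTTCCGATCT", strrep("G", 40))
#' findAdaptorHits(read)[[1]]  # end_pos 60, edit_dist 0
#' @export
findAdaptorHits <- function(seqs, adaptor_tail = "CTTCCGATCT", max_ed = 2L,
                            search_window = 200L) {
  adaptor_tail <- toupper(adaptor_tail)
  if (!grepl("^[ACGT]+$", adaptor_tail))
    stop("adaptor_tail must be a non-empty ACGT string")
  windows <- substr(seqs, 1L, search_window)
  scan_adaptor(windows, adaptor_tail, as.integer(max_ed),
               nchar(adaptor_tail))
}

#' Check for a polyT run downstream of an adaptor hit
#'
#' True iff \code{t_run} consecutive Ts lie within the half-open window
#' \code{[end_pos + polyt_start, end_pos + polyt_end)} of the strand
#' sequence (0-based coordinates; the window is truncated at the read end).
#'
#' @param seqs character vector of strand sequences.
#' @param end_pos integer vector (recycled pairwise with \code{seqs}) of
#'   0-based adaptor end positions.
#' @param polyt_start,polyt_end,t_run see \code{\link{locatorParams}}.
#' @return logical vector.
#' @export
confirmPolyT <- function(seqs, end_pos, polyt_start = 20L, polyt_end = 50L,
                         t_run = 4L) {
  # the full run must sit inside the half-open window [start, end); the
  # window is silently truncated at the read end
  win <- substr(seqs, end_pos + polyt_start + 1L, end_pos + polyt_end)
  grepl(strrep("T", t_run), win, fixed = TRUE)
}

#' Extract putative barcodes and UMIs from reads
#'
#' Step 1 of the pipeline. For each read, both the forward strand and its
#' reverse complement (with reversed qualities, so they stay base-aligned)
#' are scanned for the adaptor tail; a hit is valid only if a polyT run is
#' found downstream. Reads with exactly one valid adaptor across both
#' strands yield a putative barcode: the 16 bases immediately after the
#' adaptor, plus the following \code{umi_len} bases as UMI. Reads with no
#' hit, no polyT-confirmed hit, several valid adaptors, or fewer than 16
#' bases after the adaptor are rejected and tallied.
#'
#' @param reads DataFrame from \code{\link{readFastq}} (columns
#'   \code{read_id}, \code{seq}, \code{qual}).
#' @param params a \code{\link{locatorParams}} list.
#' @return \link[S4Vectors]{DataFrame} with one row per accepted read:
#'   \code{read_id}, \code{barcode} (16-mer), \code{barcode_qual} (offset-33
#'   string of the 16 barcode bases), \code{min_q} (minimum barcode Phred
#'   score), \code{umi} (possibly truncated at the read end) and
#'   \code{strand} ("forward"/"reverse"). \code{metadata()} carries
#'   \code{tally} (named counts along the pipeline: total, with_adaptor,
#'   with_polyt, putative, and the rejection reasons no_adaptor, no_polyt,
#'   multiple_adaptors, too_short) and \code{rejects} (read_id, reason).
#' @export
extractPutativeBarcodes <- function(reads, params = locatorParams()) {
  stopifnot(all(c("read_id", "seq", "qual") %in% colnames(reads)))
  n <- nrow(reads)
  empty <- DataFrame(read_id = character(), barcode = character(),
                     barcode_qual = character(), min_q = integer(),
                     umi = character(), strand = character())
  if (n == 0L) {
    metadata(empty)$tally <- c(total = 0L, with_adaptor = 0L, with_polyt = 0L,
                               putative = 0L, no_adaptor = 0L, no_polyt = 0L,
                               multiple_adaptors = 0L, too_short = 0L)
    metadata(empty)$rejects <- DataFrame(read_id = character(),
                                         reason = character())
    return(empty)
  }

  fwd <- as.character(reads$seq)
  rev_ <- revComp(fwd)
  strands <- list(forward = fwd, reverse = rev_)

  # flatten candidate hits from both strands into one table
  cand <- lapply(names(strands), function(s) {
    hits <- findAdaptorHits(strands[[s]], params$adaptor_tail, params$max_ed,
                            params$search_window)
    nh <- vapply(hits, nrow, integer(1))
    ep <- unlist(lapply(hits, function(h) h[, 1L]), use.names = FALSE)
    data.frame(read = rep.int(seq_len(n), nh),
               end_pos = if (is.null(ep)) integer() else as.integer(ep),
               strand = rep(s, sum(nh)))
  })
  cand <- do.call(rbind, cand)

  seq_at <- ifelse(cand$strand == "forward", fwd[cand$read], rev_[cand$read])
  ok <- confirmPolyT(seq_at, cand$end_pos, params$polyt_start,
                     params$polyt_end, params$t_run)

  n_hits <- tabulate(cand$read, nbins = n)
  n_valid <- tabulate(cand$read[ok], nbins = n)

  reason <- rep(NA_character_, n)
  reason[n_hits == 0L] <- "no_adaptor"
  reason[n_hits > 0L & n_valid == 0L] <- "no_polyt"
  reason[n_valid > 1L] <- "multiple_adaptors"

  sel <- which(n_valid == 1L)
  vcand <- cand[ok, , drop = FALSE]
  vcand <- vcand[match(sel, vcand$read), , drop = FALSE]

  sstr <- ifelse(vcand$strand == "forward", fwd[sel], rev_[sel])
  squal <- as.character(reads$qual)[sel]
  rev_sel <- vcand$strand == "reverse"
  if (any(rev_sel)) squal[rev_sel] <- reverseQual(squal[rev_sel])

  ep <- vcand$end_pos
  long_enough <- nchar(sstr) >= ep + 16L
  reason[sel[!long_enough]] <- "too_short"

  keep <- which(long_enough)
  sel <- sel[keep]; ep <- ep[keep]
  sstr <- sstr[keep]; squal <- squal[keep]
  strand <- vcand$strand[keep]

  bc <- substr(sstr, ep + 1L, ep + 16L)
  bq <- substr(squal, ep + 1L, ep + 16L)
  umi <- substr(sstr, ep + 17L, ep + 16L + params$umi_len)
  min_q <- vapply(bq, function(q) min(phredToInt(q)), integer(1),
                  USE.NAMES = FALSE)

  out <- DataFrame(read_id = as.character(reads$read_id)[sel], barcode = bc,
                   barcode_qual = bq, min_q = min_q, umi = umi,
                   strand = strand)
  tally <- c(total = n,
             with_adaptor = sum(n_hits > 0L),
             with_polyt = sum(n_valid > 0L),
             putative = nrow(out),
             no_adaptor = sum(reason == "no_adaptor", na.rm = TRUE),
             no_polyt = sum(reason == "no_polyt", na.rm = TRUE),
             multiple_adaptors = sum(reason == "multiple_adaptors",
                                     na.rm = TRUE),
             too_short = sum(reason == "too_short", na.rm = TRUE))
  rej <- !is.na(reason)
  metadata(out)$tally <- tally
  metadata(out)$rejects <- DataFrame(
    read_id = as.character(reads$read_id)[rej], reason = reason[rej])
  out
}
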