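#' Run the full barcode-calling pipeline on FASTQ input
#'
#' Executes locate -> (optional known-list filter) -> minQ filter -> count ->
#' whitelist -> assign on one or more FASTQ files, writes the standard
#' outputs and a run manifest, and returns the manifest.
#'
#' Outputs written to \code{out_dir}: \code{whitelist.txt} (one barcode per
#' line, descending count), \code{knee.csv} (rank, barcode, count over all
#' table entries), \code{assignments.csv} (read_id, barcode, edit_dist,
#' umi), \code{putative_barcodes.csv}, optionally \code{background.txt},
#' and \code{manifest.json} with the tool version, resolved configuration,
#' input checksums and per-stage read tallies. Tallies are monotone
#' non-increasing along each branch: the read chain total >= with_adaptor >=
#' with_polyt >= putative >= assigned (assignment operates on every putative
#' barcode, mirroring how usable reads are counted downstream), and the
#' whitelist branch putative >= in_known_list >= high_quality.
#'
#' @param fastq character vector of FASTQ paths (globs are expanded).
#' @param out_dir output directory, created if needed.
#' @param expected_cells N for the quantile threshold (default 500).
#' @param min_q_threshold minQ cutoff (default 15).
#' @param max_ed adaptor and assignment edit-distance budget (default 2).
#' @param umi_len UMI length (default 12).
#' @param full_barcode_list optional path to (or character vector of) the
#'   list of all possible 10x barcodes for membership filtering.
#' @param mode whitelist mode, \code{"default"} or \code{"high_sensitivity"}.
#' @param n_background if > 0, also emit that many background barcodes at
#'   ED > 4 from the whitelist (\code{background.txt}).
#' @param seed seed for the background-barcode draw.
#' @param params optional \code{\link{locatorParams}} override.
#' @return the manifest, invisibly (a named list).
#' @export
runPipeline <- function(fastq, out_dir, expected_cells = 500L,
                        min_q_threshold = 15L, max_ed = 2L, umi_len = 12L,
                        full_barcode_list = NULL,
                        mode = c("default", "high_sensitivity"),
                        n_background = 0L, seed = 1L, params = NULL) {
  mode <- match.arg(mode)
  files <- unlist(lapply(fastq, function(p)
    if (file.exists(p)) p else Sys.glob(p)))
  if (length(files) == 0L) stop("no FASTQ files match: ",
                                paste(fastq, collapse = ", "))
  if (is.null(params))
    params <- locatorParams(max_ed = max_ed, umi_len = umi_len)

  reads <- do.call(rbind, lapply(files, readFastq))
  if (nrow(reads) == 0L) stop("input FASTQ contains no reads")

  known <- full_barcode_list
  if (is.character(known) && length(known) == 1L && file.exists(known))
    known <- readLines(known)

  pbs <- extractPutativeBarcodes(reads, params)
  tally <- metadata(pbs)$tally
  pbs_known <- filterKnownBarcodes(pbs, known)
  pbs_hq <- filterHighQuality(pbs_known, min_q_threshold)
  tab <- countBarcodes(pbs_hq)
  if (length(tab) == 0L)
    stop("no high-quality putative barcodes found; cannot build a whitelist")
  wl <- buildWhitelist(tab, expected_cells, mode)
  asn <- assignReads(pbs, wl, max_ed)

  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  writeWhitelist(wl, file.path(out_dir, "whitelist.txt"))
  utils::write.csv(kneeData(tab), file.path(out_dir, "knee.csv"),
                   row.names = FALSE)
  utils::write.csv(as.data.frame(asn), file.path(out_dir, "assignments.csv"),
                   row.names = FALSE)
  utils::write.csv(as.data.frame(pbs),
                   file.path(out_dir, "putative_barcodes.csv"),
                   row.names = FALSE)
  if (n_background > 0L) {
    bg <- backgroundBarcodes(tab, wl, n = n_background, seed = seed)
    writeLines(bg, file.path(out_dir, "background.txt"))
  }

  manifest <- list(
    tool = "nanodemux",
    version = as.character(utils::packageVersion("nanodemux")),
    config = list(expected_cells = expected_cells,
                  min_q_threshold = min_q_threshold, max_ed = max_ed,
                  umi_len = umi_len, mode = mode,
                  n_background = n_background, seed = seed,
                  adaptor_tail = params$adaptor_tail,
                  search_window = params$search_window,
                  known_list = !is.null(known)),
    inputs = lapply(files, function(f)
      list(path = f, md5 = unname(tools::md5sum(f)))),
    tallies = list(total = unname(tally["total"]),
                   with_adaptor = unname(tally["with_adaptor"]),
                   with_polyt = unname(tally["with_polyt"]),
                   putative = unname(tally["putative"]),
                   assigned = metadata(asn)$summary$n_assigned),
    whitelist_branch = list(putative = unname(tally["putative"]),
                            in_known_list = nrow(pbs_known),
                            high_quality = nrow(pbs_hq)),
    rejections = as.list(tally[c("no_adaptor", "no_polyt",
                                 "multiple_adaptors", "too_short")]),
    whitelist_size = length(wl),
    threshold = threshold(wl),
    usable_fraction = metadata(asn)$summary$n_assigned /
      unname(tally["total"]))
  write_json(manifest, file.path(out_dir, "manifest.json"),
             auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
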