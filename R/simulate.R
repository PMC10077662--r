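#' Build a simulation configuration
#'
#' Defaults describe a realistic desk-scale 10x nanopore experiment: 500
#' true cells with negative-binomial read depth (mean 60, size 10), 5000
#' ambient background barcodes seen in 1--3 reads each, and a ~5% total
#' per-base error rate (substitutions 2%, insertions 1.5%, deletions 1.5%)
#' matching the typical nanopore error regime. Per-base Phred scores follow
#' a two-component model: correct bases draw from a rounded Gaussian around
#' Q20 (sd 3), error bases around Q8 (sd 3), clamped to [1, 40], so that
#' minQ filtering separates clean from erroneous barcodes as in real
#' basecalls.
#'
#' The 10x adaptor default ends in \code{CTTCCGATCT}, the tail searched by
#' the locator; the nanopore adaptor and TSO defaults are representative
#' placeholder sequences and can be overridden.
#'
#' @param n_cells number of true cells.
#' @param reads_per_cell a single count, a vector of length \code{n_cells},
#'   or \code{list(dist = "nb", mean =, size =)} for negative-binomial depth.
#' @param n_background number of ambient (non-cell) barcodes.
#' @param background_reads a count, a vector, or
#'   \code{list(dist = "uniform", min =, max =)}.
#' @param barcode_universe optional character vector of admissible 16-mers;
#'   \code{NULL} draws random distinct 16-mers.
#' @param umi_len UMI length (nt).
#' @param fragment_len cDNA fragment length (nt).
#' @param polyt_len length of the polyT tract in the perfect read.
#' @param fragment_fasta optional transcript FASTA to sample fragments from.
#' @param sub_rate,ins_rate,del_rate per-base error probabilities.
#' @param q_correct_mean,q_correct_sd,q_error_mean,q_error_sd,q_min,q_max
#'   Phred model parameters.
#' @param nanopore_adaptor,tenx_adaptor,tso adaptor constants.
#' @param seed integer seed consumed by \code{\link{simulateDataset}};
#'   \code{NA} uses the current RNG state.
#' @return a validated \linkS4class{SimConfig}.
#' @examples
#' simConfig(n_cells = 10, reads_per_cell = 20, n_background = 0)
#' @export
simConfig <- function(n_cells = 500L,
                      reads_per_cell = list(dist = "nb", mean = 60, size = 10),
                      n_background = 5000L,
                      background_reads = list(dist = "uniform",
                                              min = 1L, max = 3L),
                      barcode_universe = NULL,
                      umi_len = 12L, fragment_len = 200L, polyt_len = 15L,
                      fragment_fasta = NULL,
                      sub_rate = 0.02, ins_rate = 0.015, del_rate = 0.015,
                      q_correct_mean = 20, q_correct_sd = 3,
                      q_error_mean = 8, q_error_sd = 3,
                      q_min = 1L, q_max = 40L,
                      nanopore_adaptor = "AATGTACTTCGTTCAGTTACGTATTGCT",
                      tenx_adaptor = "CTACACGACGCTCTTCCGATCT",
                      tso = "CCCATGTACTCTGCGTTGATACCACTGCTT",
                      seed = NA_integer_) {
  new("SimConfig",
      n_cells = as.integer(n_cells), reads_per_cell = reads_per_cell,
      n_background = as.integer(n_background),
      background_reads = background_reads,
      barcode_universe = barcode_universe,
      umi_len = as.integer(umi_len), fragment_len = as.integer(fragment_len),
      polyt_len = as.integer(polyt_len), fragment_fasta = fragment_fasta,
      sub_rate = sub_rate, ins_rate = ins_rate, del_rate = del_rate,
      q_correct_mean = q_correct_mean, q_correct_sd = q_correct_sd,
      q_error_mean = q_error_mean, q_error_sd = q_error_sd,
      q_min = as.integer(q_min), q_max = as.integer(q_max),
      nanopore_adaptor = toupper(nanopore_adaptor),
      tenx_adaptor = toupper(tenx_adaptor), tso = toupper(tso),
      seed = as.integer(seed))
}

# n distinct random DNA k-mers avoiding a given set
randomBarcodes <- function(n, len = 16L, avoid = character()) {
  out <- character()
  while (length(out) < n) {
    m <- max(n - length(out), 64L)
    batch <- randomDNA(m, len)
    batch <- setdiff(unique(batch), c(avoid, out))
    out <- c(out, batch)
  }
  out[seq_len(n)]
}

# m random DNA strings of a common length
randomDNA <- function(m, len) {
  if (m == 0L) return(character())
  mat <- matrix(sample(c("A", "C", "G", "T"), m * len, replace = TRUE),
                nrow = m)
  do.call(paste0, as.data.frame(mat, stringsAsFactors = FALSE))
}

# resolve a per-barcode read-count specification into an integer vector
resolveCounts <- function(spec, n, what) {
  if (n == 0L) return(integer())
  if (is.list(spec)) {
    dist <- spec$dist
    if (identical(dist, "nb"))
      return(rnbinom(n, size = spec$size, mu = spec$mean))
    if (identical(dist, "uniform"))
      return(sample(seq(spec$min, spec$max), n, replace = TRUE))
    stop("unknown ", what, " distribution: ", dist)
  }
  if (length(spec) == 1L) return(rep(as.integer(spec), n))
  if (length(spec) != n)
    stop(what, " vector must have length ", n)
  as.integer(spec)
}

#' Construct error-free ("perfect") simulated reads
#'
#' A perfect read is the concatenation nanopore adaptor + 10x adaptor +
#' barcode + UMI + polyT + cDNA fragment + TSO; reads on the reverse strand
#' are the reverse complement of that construct.
#'
#' @param barcode,umi,fragment,strand parallel character vectors;
#'   \code{strand} entries are \code{"forward"} or \code{"reverse"}.
#' @param config a \linkS4class{SimConfig} providing adaptor constants and
#'   expected segment lengths.
#' @return character vector of read sequences.
#' @export
buildPerfectRead <- function(barcode, umi, fragment, strand,
                             config = simConfig()) {
  if (any(nchar(barcode) != 16L)) stop("barcodes must be 16 nt")
  if (any(nchar(umi) != config@umi_len))
    stop("UMIs must be ", config@umi_len, " nt")
  if (any(nchar(fragment) != config@fragment_len))
    stop("fragments must be ", config@fragment_len, " nt")
  if (!all(strand %in% c("forward", "reverse")))
    stop("strand must be 'forward' or 'reverse'")
  fwd <- paste0(config@nanopore_adaptor, config@tenx_adaptor, barcode, umi,
                strrep("T", config@polyt_len), fragment, config@tso)
  rev_sel <- strand == "reverse"
  if (any(rev_sel)) fwd[rev_sel] <- revComp(fwd[rev_sel])
  fwd
}

#' Inject sequencing errors and per-base qualities
#'
#' Applies the parametric per-base error model of the configuration
#' (independent substitution / insertion / deletion events) and draws a
#' Phred score for every emitted base: substituted and inserted bases from
#' the error-base distribution, copied bases from the correct-base
#' distribution. Randomness flows through R's RNG, so results are
#' reproducible under \code{set.seed()}.
#'
#' @param seqs character vector of (perfect) read sequences.
#' @param config a \linkS4class{SimConfig}.
#' @return list with character vectors \code{seq} (mutated bases) and
#'   \code{qual} (offset-33 Phred strings of matching length).
#' @export
injectErrors <- function(seqs, config = simConfig()) {
  validObject(config)
  inject_errors_cpp(as.character(seqs), config@sub_rate, config@ins_rate,
                    config@del_rate, config@q_correct_mean,
                    config@q_correct_sd, config@q_error_mean,
                    config@q_error_sd, config@q_min, config@q_max)
}

#' Simulate a single-cell nanopore dataset with ground truth
#'
#' Draws distinct cell and background barcodes, a read count for each
#' barcode, and for every read a random UMI, a cDNA fragment (uniform random
#' sequence, or a window of a transcript from \code{fragment_fasta}) and a
#' fair-coin strand; builds the perfect read and injects errors per the
#' configuration. The per-read truth (barcode, UMI, strand, fragment,
#' cell/background status) is the evaluation ground truth, and the true-cell
#' barcodes form the ground-truth whitelist.
#'
#' @param config a \linkS4class{SimConfig}; its \code{seed} (unless
#'   \code{NA}) seeds all randomness.
#' @param out_dir optional directory; when given, writes
#'   \code{reads.fastq.gz}, \code{truth.tsv}, \code{truth_whitelist.txt} and
#'   \code{barcode_universe.txt} there.
#' @return (invisibly when writing) a list with \code{reads} (DataFrame:
#'   read_id, seq, qual), \code{truth} (data.frame: read_id, barcode, umi,
#'   strand, fragment_id, is_cell), \code{truth_whitelist} (character),
#'   \code{universe} (all simulated barcodes) and \code{config}.
#' @export
simulateDataset <- function(config = simConfig(), out_dir = NULL) {
  validObject(config)
  if (!is.na(config@seed)) set.seed(config@seed)

  universe <- config@barcode_universe
  n_bc <- config@n_cells + config@n_background
  if (is.null(universe)) {
    bcs <- randomBarcodes(n_bc)
  } else {
    if (length(unique(universe)) < n_bc)
      stop("barcode universe smaller than n_cells + n_background")
    bcs <- sample(unique(universe), n_bc)
  }
  cell_bc <- bcs[seq_len(config@n_cells)]
  bg_bc <- bcs[config@n_cells + seq_len(config@n_background)]

  depth <- c(resolveCounts(config@reads_per_cell, config@n_cells,
                           "reads_per_cell"),
             resolveCounts(config@background_reads, config@n_background,
                           "background_reads"))
  is_cell <- rep(c(TRUE, FALSE), c(config@n_cells, config@n_background))

  n_reads <- sum(depth)
  barcode <- rep(bcs, depth)
  read_is_cell <- rep(is_cell, depth)
  umi <- randomDNA(n_reads, config@umi_len)
  strand <- sample(c("forward", "reverse"), n_reads, replace = TRUE)

  if (is.null(config@fragment_fasta)) {
    fragment <- randomDNA(n_reads, config@fragment_len)
    fragment_id <- rep("random", n_reads)
  } else {
    tx <- readDNAStringSet(config@fragment_fasta)
    tx <- tx[width(tx) >= config@fragment_len]
    if (length(tx) == 0L)
      stop("no transcript of length >= ", config@fragment_len,
           " in ", config@fragment_fasta)
    ti <- sample(length(tx), n_reads, replace = TRUE)
    start <- floor(runif(n_reads) *
                     (width(tx)[ti] - config@fragment_len + 1L)) + 1L
    fragment <- toupper(as.character(
      Biostrings::subseq(tx[ti], start = start,
                         width = config@fragment_len)))
    fragment_id <- paste0(sub(" .*", "", names(tx))[ti], ":", start)
  }

  perfect <- buildPerfectRead(barcode, umi, fragment, strand, config)
  noisy <- injectErrors(perfect, config)
  read_id <- sprintf("sim_%07d", seq_len(n_reads))

  reads <- DataFrame(read_id = read_id, seq = noisy$seq, qual = noisy$qual)
  truth <- data.frame(read_id = read_id, barcode = barcode, umi = umi,
                      strand = strand, fragment_id = fragment_id,
                      is_cell = read_is_cell)
  out <- list(reads = reads, truth = truth, truth_whitelist = cell_bc,
              universe = bcs, config = config)

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    writeFastq(reads, file.path(out_dir, "reads.fastq.gz"))
    utils::write.table(truth, file.path(out_dir, "truth.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    writeLines(cell_bc, file.path(out_dir, "truth_whitelist.txt"))
    writeLines(bcs, file.path(out_dir, "barcode_universe.txt"))
    return(invisible(out))
  }
  out
}
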