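# Independent oracles and small fixture builders. Everything here is kept
# deliberately naive (full DP matrices, exhaustive enumeration) so the fast
# implementations have something honest to be checked against.

rand_dna <- function(len, alphabet = c("A", "C", "G", "T")) {
  paste(sample(alphabet, len, replace = TRUE), collapse = "")
}

# full-matrix Levenshtein distance, written out loop by loop
lev_dp <- function(a, b) {
  na <- nchar(a); nb <- nchar(b)
  av <- strsplit(a, "")[[1]]; bv <- strsplit(b, "")[[1]]
  d <- matrix(0L, na + 1L, nb + 1L)
  d[, 1L] <- 0:na
  d[1L, ] <- 0:nb
  for (i in seq_len(na)) {
    for (j in seq_len(nb)) {
      d[i + 1L, j + 1L] <- min(d[i, j] + (av[i] != bv[j]),
                               d[i, j + 1L] + 1L,
                               d[i + 1L, j] + 1L)
    }
  }
  d[na + 1L, nb + 1L]
}

# exhaustive semi-global oracle: minimal edit distance of the full adaptor
# against ANY substring of the window (all start positions x all lengths
# that could stay within max_ed; |len - m| <= cost bounds the search).
# N in the window must never match, which utils::adist satisfies since the
# adaptor is ACGT-only. Returns the overall minimum cost (Inf if the window
# is shorter than any admissible substring).
semiglobal_min_oracle <- function(window, adaptor, max_ed) {
  m <- nchar(adaptor)
  L <- nchar(window)
  lens <- seq(max(1L, m - max_ed), m + max_ed)
  subs <- character()
  for (len in lens) {
    if (L < len) next
    starts <- seq_len(L - len + 1L)
    subs <- c(subs, substring(window, starts, starts + len - 1L))
  }
  if (!length(subs)) return(Inf)
  min(utils::adist(adaptor, subs))
}

# set-algebra precision/recall recomputation for one threshold
pr_point_oracle <- function(barcode, count, truth, t) {
  predicted <- barcode[count > t]
  tp <- length(intersect(predicted, truth))
  list(precision = if (length(predicted) == 0L) 1 else tp / length(predicted),
       recall = tp / length(unique(truth)))
}

# a synthetic read carrying one valid adaptor + barcode + UMI + polyT;
# G-homopolymer padding cannot resemble the adaptor tail or a polyT run
make_read <- function(barcode, umi = "ACGTACGTACGT",
                      adaptor = "CTTCCGATCT", prefix = strrep("G", 50),
                      polyt = strrep("T", 15), tail = strrep("G", 60),
                      qual_char = "I") {
  seq <- paste0(prefix, adaptor, barcode, umi, polyt, tail)
  list(seq = seq, qual = strrep(qual_char, nchar(seq)),
       bc_at = nchar(prefix) + nchar(adaptor))
}

reads_df <- function(...) {
  rl <- list(...)
  S4Vectors::DataFrame(
    read_id = paste0("r", seq_along(rl)),
    seq = vapply(rl, `[[`, "", "seq"),
    qual = vapply(rl, `[[`, "", "qual"))
}
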