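#' Assembly summary statistics from a FASTA file
#'
#' Scaffold count, total length, N50 and GC content of a (draft) genome
#' assembly. N50 follows the standard convention: the length of the
#' scaffold at which the cumulative sum of descending-sorted lengths first
#' reaches half the total (assemblers differ on ties; this is the "first
#' cumulative >= half" rule). GC is computed over unambiguous bases by
#' default: ambiguity codes (N etc.) count toward `total_length` but are
#' excluded from the GC denominator; set `gc_all_bases = TRUE` to divide by
#' all bases instead (the study does not state its convention).
#'
#' @param fasta path to a FASTA file (plain or gzip), or a
#'   `Biostrings::DNAStringSet`
#' @param gc_all_bases use all bases in the GC denominator
#' @return object of class `assembly_summary`: `n_scaffolds`,
#'   `total_length`, `n50`, `gc_percent` (rounded to 2 decimals)
#' @export
assembly_stats <- function(fasta, gc_all_bases = FALSE) {
  seqs <- if (inherits(fasta, "DNAStringSet")) {
    fasta
  } else {
    if (!file.exists(fasta)) stop("FASTA file not found: ", fasta)
    Biostrings::readDNAStringSet(fasta)
  }
  if (length(seqs) == 0L) stop("assembly contains no sequences")
  lens <- Biostrings::width(seqs)
  freq <- Biostrings::alphabetFrequency(seqs, baseOnly = TRUE,
                                        collapse = TRUE)
  gc <- sum(freq[c("C", "G")])
  denom <- if (gc_all_bases) sum(lens) else sum(freq[c("A", "C", "G", "T")])
  structure(
    list(n_scaffolds = length(seqs),
         total_length = sum(lens),
         n50 = n50(lens),
         gc_percent = round(100 * gc / denom, 2)),
    class = "assembly_summary"
  )
}

#' @export
print.assembly_summary <- function(x, ...) {
  cat(sprintf(
    "assembly_summary: %d scaffolds, %d bp total, N50 = %d bp, GC = %.2f%%\n",
    x$n_scaffolds, x$total_length, x$n50, x$gc_percent))
  invisible(x)
}

#' N50 of a set of scaffold lengths
#'
#' @param lengths scaffold lengths, bp
#' @return the N50 length, bp
#' @export
n50 <- function(lengths) {
  stopifnot(length(lengths) >= 1L, all(lengths > 0))
  s <- sort(lengths, decreasing = TRUE)
  s[which(cumsum(as.numeric(s)) >= sum(as.numeric(s)) / 2)[1L]]
}

#' Construct a synthetic assembly with prescribed summary statistics
#'
#' Builds a deterministic multiset of scaffold lengths realising the given
#' scaffold count, total length and N50 (a block of scaffolds above the
#' N50 length whose cumulative sum stops just short of half the total, one
#' scaffold of exactly the N50 length crossing the halfway point, and a
#' tail of shorter scaffolds), then fills the sequences with a base
#' composition hitting the requested GC percentage after rounding. This is
#' a synthetic stand-in used to exercise the statistics machinery; it is
#' not, and does not pretend to be, a deposited genome record.
#'
#' @param n_scaffolds scaffold count
#' @param total_length total assembly length, bp
#' @param n50_bp target N50, bp
#' @param gc_percent target GC percentage (all bases unambiguous)
#' @param seed integer seed for base shuffling
#' @return a `Biostrings::DNAStringSet` (write with
#'   `Biostrings::writeXStringSet()` if a file is needed)
#' @export
simulate_assembly <- function(n_scaffolds, total_length, n50_bp,
                              gc_percent, seed = 1L) {
  lens <- .assembly_lengths(n_scaffolds, total_length, n50_bp)
  stopifnot(sum(lens) == total_length, length(lens) == n_scaffolds)
  gc_total <- round(gc_percent / 100 * total_length)
  # distribute GC bases across scaffolds proportionally, fixing remainders
  gc_per <- floor(lens * gc_total / total_length)
  short <- gc_total - sum(gc_per)
  if (short > 0) {
    ord <- order(lens, decreasing = TRUE)
    gc_per[ord[seq_len(short)]] <- gc_per[ord[seq_len(short)]] + 1L
  }
  stopifnot(all(gc_per <= lens))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(as.integer(seed))
  seqs <- vapply(seq_along(lens), function(i) {
    L <- lens[i]; g <- gc_per[i]
    bases <- c(rep(c("G", "C"), length.out = g),
               rep(c("A", "T"), length.out = L - g))
    paste(bases[sample.int(L)], collapse = "")
  }, character(1))
  names(seqs) <- sprintf("synthetic_scaffold_%03d", seq_along(seqs))
  Biostrings::DNAStringSet(seqs)
}

# deterministic length multiset with exact count, total and N50
.assembly_lengths <- function(n, total, n50_bp) {
  stopifnot(n >= 3L, n50_bp >= 1, total > 3 * n50_bp)
  half <- total / 2
  s_big <- half - n50_bp / 2          # cumulative sum of the >N50 block
  k <- floor(s_big / (2 * n50_bp))    # big scaffolds of length 2*N50
  if (k >= 1L) {
    big <- rep(2 * n50_bp, k)
    big[1] <- big[1] + round(s_big - k * 2 * n50_bp)
  } else {
    big <- round(s_big)               # single scaffold >= N50
  }
  n_tail <- n - k - 1L
  s_tail <- total - sum(big) - n50_bp
  stopifnot(n_tail >= 1L, s_tail >= n_tail, s_tail <= n_tail * n50_bp)
  base <- s_tail %/% n_tail
  extra <- s_tail - base * n_tail
  tail_lens <- rep(base, n_tail)
  if (extra > 0) tail_lens[seq_len(extra)] <- base + 1L
  lens <- c(big, n50_bp, tail_lens)
  stopifnot(all(tail_lens <= n50_bp), all(tail_lens >= 1))
  lens
}
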