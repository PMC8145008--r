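# Independent oracles: deliberately naive re-derivations of the
# quantities the package computes, used to freeze expected values.

# Brute-force optimal global alignment score with affine gaps
# (gap of length L costs gap_open + L * gap_extend). Memoised recursion
# over (i, j, state-of-next-emitted-column); enumerates every alignment
# implicitly, so it is exact for short sequences.
brute_force_align_score <- function(a, b, match = 2, mismatch = -3,
                                    gap_open = 5, gap_extend = 2) {
  a <- strsplit(a, "")[[1]]
  b <- strsplit(b, "")[[1]]
  memo <- new.env(hash = TRUE)
  rec <- function(i, j, prev) {
    if (i == 0 && j == 0) return(0)
    key <- paste(i, j, prev)
    hit <- memo[[key]]
    if (!is.null(hit)) return(hit)
    best <- -Inf
    if (i > 0 && j > 0) {
      s <- if (a[i] == b[j]) match else mismatch
      best <- max(best, s + rec(i - 1, j - 1, "M"))
    }
    if (i > 0) {
      cost <- gap_extend + if (prev != "X") gap_open else 0
      best <- max(best, -cost + rec(i - 1, j, "X"))
    }
    if (j > 0) {
      cost <- gap_extend + if (prev != "Y") gap_open else 0
      best <- max(best, -cost + rec(i, j - 1, "Y"))
    }
    memo[[key]] <- best
    best
  }
  rec(length(a), length(b), "none")
}

# Exhaustive sample-based accumulation: mean richness over ALL k-subsets.
exhaustive_accumulation <- function(m) {
  m <- as.matrix(m) > 0
  N <- nrow(m)
  vapply(seq_len(N), function(k) {
    subsets <- utils::combn(N, k)
    mean(apply(subsets, 2, function(s) sum(colSums(m[s, , drop = FALSE]) > 0)))
  }, numeric(1))
}

# Naive six-frame ORF scan: walk from every ATG to the first in-frame
# stop, then keep the longest ORF per (strand, stop).
naive_orf_scan <- function(seq, min_len_nt = 300) {
  stops <- c("TAA", "TAG", "TGA")
  revcomp <- function(s) {
    chartr("ACGT", "TGCA", paste(rev(strsplit(s, "")[[1]]), collapse = ""))
  }
  L <- nchar(seq)
  hits <- list()
  for (st in c("+", "-")) {
    s <- if (st == "+") seq else revcomp(seq)
    for (i in seq_len(L - 2)) {
      if (substr(s, i, i + 2) != "ATG") next
      j <- i
      found <- FALSE
      while (j + 2 <= L) {
        if (substr(s, j, j + 2) %in% stops) { found <- TRUE; break }
        j <- j + 3
      }
      if (!found) next
      len <- j + 2 - i + 1
      if (len <= min_len_nt) next
      hits[[length(hits) + 1]] <- data.frame(strand = st, stop0 = j,
                                             start0 = i, length_nt = len)
    }
  }
  if (length(hits) == 0)
    return(data.frame(start = integer(), end = integer(),
                      strand = character(), length_nt = integer()))
  h <- do.call(rbind, hits)
  # longest ORF per shared stop
  h <- h[order(h$strand, h$stop0, -h$length_nt), ]
  h <- h[!duplicated(h[, c("strand", "stop0")]), ]
  b0 <- h$start0; e0 <- h$stop0 + 2
  start <- ifelse(h$strand == "+", b0, L - e0 + 1)
  end <- ifelse(h$strand == "+", e0, L - b0 + 1)
  res <- data.frame(start = start, end = end, strand = h$strand,
                    length_nt = h$length_nt)
  res[order(res$start, res$end, res$strand), ]
}

random_dna <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}
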