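# Brute-force reference implementations, written independently of the
# package internals (character scans and per-bp arrays, no cumsums or rle).

# G4 propensity per base: scan outward from each position to find its
# homopolymer run length.
oracle_g4_scores <- function(seq) {
  s <- strsplit(toupper(seq), "")[[1]]
  out <- numeric(length(s))
  for (i in seq_along(s)) {
    b <- s[i]
    if (b != "G" && b != "C") next
    k <- 1
    j <- i - 1
    while (j >= 1 && s[j] == b) { k <- k + 1; j <- j - 1 }
    j <- i + 1
    while (j <= length(s) && s[j] == b) { k <- k + 1; j <- j + 1 }
    out[i] <- if (b == "G") min(k, 4) else -min(k, 4)
  }
  out
}

oracle_gc_skew <- function(seq) {
  s <- strsplit(toupper(seq), "")[[1]]
  g <- sum(s == "G"); c <- sum(s == "C")
  if (g + c == 0) NA_real_ else (g - c) / (g + c)
}

# Interval union via a per-bp occupancy array (0-based half-open input).
oracle_merge <- function(start0, end0, chrom_len, max_gap = 0) {
  occ <- logical(chrom_len)
  for (i in seq_along(start0)) occ[(start0[i] + 1):end0[i]] <- TRUE
  if (max_gap > 0) {
    # bridge gaps of <= max_gap between covered stretches
    r <- rle(occ)
    pos <- cumsum(r$lengths)
    for (j in seq_along(r$lengths)) {
      if (!r$values[j] && r$lengths[j] <= max_gap &&
          j > 1 && j < length(r$lengths)) {
        occ[(pos[j] - r$lengths[j] + 1):pos[j]] <- TRUE
      }
    }
  }
  r <- rle(occ)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths
  data.frame(start0 = starts[r$values], end0 = ends[r$values])
}

random_dna <- function(n, gc = 0.5) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

revcomp_chr <- function(seq) {
  s <- rev(strsplit(toupper(seq), "")[[1]])
  paste(c(A = "T", C = "G", G = "C", T = "A", N = "N")[s], collapse = "")
}
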