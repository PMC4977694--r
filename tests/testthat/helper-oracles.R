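# Independent brute-force oracles used to cross-check the implementation.
# These deliberately share no code with the package internals.

# every exact occurrence of `read` in each precursor, by sliding a window
naive_map <- function(read, precursors) {
  out <- list()
  L <- nchar(read)
  for (i in seq_len(nrow(precursors))) {
    p <- precursors$sequence[i]
    s <- seq_len(max(0L, nchar(p) - L + 1L))
    hit <- s[substring(p, s, s + L - 1L) == read]
    if (length(hit)) {
      out[[length(out) + 1L]] <- data.frame(
        precursor_id = precursors$id[i], start = hit - 1L,
        stringsAsFactors = FALSE)
    }
  }
  if (length(out)) do.call(rbind, out) else
    data.frame(precursor_id = character(), start = integer())
}

# count of (possibly overlapping) occurrences of a 7-mer site in a UTR
naive_site_count <- function(utr, site) {
  n <- 0L
  for (s in seq_len(max(0L, nchar(utr) - nchar(site) + 1L))) {
    if (substr(utr, s, s + nchar(site) - 1L) == site) n <- n + 1L
  }
  n
}

# step-up BH from the definition: sort, scale by m/rank, cummin from the top
naive_bh <- function(p) {
  m <- length(p)
  o <- order(p, decreasing = TRUE)
  ro <- order(o)
  pmin(1, cummin(p[o] * m / rev(seq_len(m))))[ro]
}

# one-sided over-representation p as a hypergeometric tail by summation:
# N universe, K site-carriers, n drawn (downregulated), x observed carriers
hyper_tail <- function(x, K, N, n) {
  sum(vapply(x:min(n, K), function(i)
    choose(K, i) * choose(N - K, n - i) / choose(N, n), numeric(1)))
}

# two-group log-rank statistic from the risk table, (O-E)^2/V form
naive_logrank <- function(time, event, group) {
  stopifnot(length(unique(group)) == 2)
  g1 <- unique(group)[1]
  times <- sort(unique(time[event == 1]))
  O <- 0; E <- 0; V <- 0
  for (t in times) {
    at_risk <- time >= t
    n <- sum(at_risk)
    n1 <- sum(at_risk & group == g1)
    d <- sum(time == t & event == 1)
    d1 <- sum(time == t & event == 1 & group == g1)
    O <- O + d1
    E <- E + d * n1 / n
    if (n > 1) V <- V + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  (O - E)^2 / V
}

# a tiny reference: one precursor embedding the miR-140-3p mature sequence
# followed by AC, so 0|0 and +1|+2 reads both exist on it
mir140_reference <- function() {
  mature <- "TACCACAGGGTAGAACCACGG"
  prec <- paste0("GTGTCTCTCTGTGTCC", mature, "ACGGGTTATATGGGTTCTCTT")
  precursors <- data.frame(id = "hsa-mir-140", sequence = prec,
                           stringsAsFactors = FALSE)
  annotations <- data.frame(
    mirna_name = "hsa-miR-140-3p", precursor_id = "hsa-mir-140",
    start = 16L, end = 16L + nchar(mature), sequence = mature,
    stringsAsFactors = FALSE)
  stopifnot(substr(prec, 17, 16 + nchar(mature)) == mature)
  list(precursors = precursors, annotations = annotations)
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}
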