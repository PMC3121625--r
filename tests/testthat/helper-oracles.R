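# Independent oracles kept deliberately naive: they re-derive expected
# values by brute force and must never call the implementation paths they
# check.

oracle_base_counts <- function(seq) {
  ch <- strsplit(seq, "")[[1]]
  out <- c(a = 0L, c = 0L, g = 0L, t = 0L, n = 0L)
  for (b in ch) {
    slot <- switch(b, A = "a", C = "c", G = "g", T = "t", N = "n")
    out[slot] <- out[slot] + 1L
  }
  out
}

# Maximal-run census by regular expression on a linearization rotated so
# that no run spans the cut.
oracle_runs <- function(seq, base, circular, min_length = 2L) {
  ch <- strsplit(seq, "")[[1]]
  if (circular && any(ch != base)) {
    cut <- which(ch != base)[1]
    ch <- c(ch[cut:length(ch)], ch[seq_len(cut - 1L)])
  }
  s <- paste(ch, collapse = "")
  m <- gregexpr(paste0(base, "{", min_length, ",}"), s)[[1]]
  if (m[1] == -1) return(integer(0))
  lens <- attr(m, "match.length")
  tab <- table(lens)
  stats::setNames(as.integer(tab), names(tab))
}

oracle_majority_fraction <- function(column) {
  res <- column[column != "-" & column != "X"]
  if (length(res) == 0) return(NA_real_)
  best <- 0
  for (aa in unique(res)) best <- max(best, sum(res == aa))
  best / length(res)
}

oracle_window_ratio <- function(seq, p, left, right) {
  ch <- strsplit(seq, "")[[1]]
  n <- length(ch)
  idx <- ((p - left):(p + right)) %% n + 1L
  gt <- sum(ch[idx] %in% c("G", "T"))
  ac <- sum(ch[idx] %in% c("A", "C"))
  if (ac == 0) NA_real_ else gt / ac
}

random_seq <- function(n, probs = c(A = .25, C = .25, G = .25, T = .25)) {
  paste(sample(names(probs), n, replace = TRUE, prob = probs), collapse = "")
}
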