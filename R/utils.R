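## Small shared helpers: alphabet handling, complements, DNA/RNA conversion.

aa_one_letter <- function(x) {
  x <- as.character(x)
  out <- x
  long <- nchar(x) > 1L
  if (any(long)) {
    lut <- stats::setNames(names(AA3), tolower(AA3))
    hit <- lut[tolower(x[long])]
    if (anyNA(hit)) {
      stop("unknown amino-acid name(s): ",
           paste(unique(x[long][is.na(hit)]), collapse = ", "))
    }
    out[long] <- unname(hit)
  }
  out
}

aa_three_letter <- function(x) unname(AA3[aa_one_letter(x)])

#' Reverse complement of a DNA string
#'
#' @param seq A single character string over `A`, `C`, `G`, `T`, `N`.
#' @return The reverse-complemented string.
#' @export
revcomp <- function(seq) {
  stopifnot(is.character(seq), length(seq) == 1L)
  chartr("ACGTN", "TGCAN", paste(rev(strsplit(seq, "", fixed = TRUE)[[1]]),
                                 collapse = ""))
}

## RNA-space reverse complement (codon <-> anticodon).
revcomp_rna <- function(x) {
  vapply(x, function(s) {
    chartr("ACGUN", "UGCAN",
           paste(rev(strsplit(s, "", fixed = TRUE)[[1]]), collapse = ""))
  }, character(1), USE.NAMES = FALSE)
}

dna_to_rna <- function(x) chartr("T", "U", x)
rna_to_dna <- function(x) chartr("U", "T", x)

seq_chars <- function(seq) strsplit(seq, "", fixed = TRUE)[[1]]

check_alphabet <- function(seq, what = "sequence") {
  bad <- setdiff(unique(seq_chars(seq)), c(DNA_BASES, "N"))
  if (length(bad) > 0L) {
    stop(what, " contains characters outside {A,C,G,T,N}: ",
         paste(bad, collapse = ", "))
  }
  invisible(seq)
}

## Circular distance between two positions on a genome of length n.
circ_dist <- function(a, b, n) {
  d <- abs(a - b) %% n
  pmin(d, n - d)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
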