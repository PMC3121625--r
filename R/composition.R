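## Base tallies, AT/GC skews, region-restricted counts and the
## homopolymer-run census.  All statistics refer to the main-coding strand:
## operations taking a genome re-orient it with orient_main() first.

#' Tally bases of a nucleotide sequence
#'
#' @param seq Nucleotide string over `A`,`C`,`G`,`T`,`N`.
#' @return A `base_counts` object with fields `a`, `c`, `g`, `t`, `n_other`
#'   and `total` (`a+c+g+t`; `N` is counted in no tally).
#' @export
base_counts <- function(seq) {
  check_alphabet(seq)
  ch <- seq_chars(seq)
  cnt <- c(a = sum(ch == "A"), c = sum(ch == "C"),
           g = sum(ch == "G"), t = sum(ch == "T"))
  structure(c(as.list(cnt),
              list(n_other = sum(ch == "N"), total = sum(cnt))),
            class = "base_counts")
}

as_base_counts <- function(x) {
  if (inherits(x, "base_counts")) x else base_counts(x)
}

#' @export
print.base_counts <- function(x, ...) {
  cat(sprintf("<base_counts> A=%d C=%d G=%d T=%d (N=%d)\n",
              x$a, x$c, x$g, x$t, x$n_other))
  invisible(x)
}

#' AT-skew and GC-skew
#'
#' `at_skew` returns (A-T)/(A+T) and `gc_skew` (G-C)/(G+C).  A zero
#' denominator yields `NA` rather than an error.
#'
#' @param counts A `base_counts` object or a nucleotide string.
#' @return A value in `[-1, 1]`, or `NA_real_` when undefined.
#' @export
at_skew <- function(counts) {
  counts <- as_base_counts(counts)
  if (counts$a + counts$t == 0) return(NA_real_)
  (counts$a - counts$t) / (counts$a + counts$t)
}

#' @rdname at_skew
#' @export
gc_skew <- function(counts) {
  counts <- as_base_counts(counts)
  if (counts$g + counts$c == 0) return(NA_real_)
  (counts$g - counts$c) / (counts$g + counts$c)
}

#' Base counts restricted to a region class
#'
#' Counts are taken on the main-coding strand.  `third_codon_positions` pools
#' the third base of every complete codon over all CDS (a trailing incomplete
#' codon is excluded); `non_protein` pools every position covered by no CDS.
#'
#' @param genome An [annotated_genome()].
#' @param region_kind One of `"whole"`, `"third_codon_positions"`,
#'   `"non_protein"`.
#' @return A `base_counts` object.
#' @export
region_counts <- function(genome,
                          region_kind = c("whole", "third_codon_positions",
                                          "non_protein")) {
  region_kind <- match.arg(region_kind)
  genome <- orient_main(genome)
  if (region_kind == "whole") return(base_counts(genome$sequence))
  cds <- features_of_kind(genome, "CDS")
  if (length(cds) == 0L) {
    stop("genome has no CDS features; only region_kind = 'whole' is defined")
  }
  if (region_kind == "third_codon_positions") {
    thirds <- vapply(cds, function(f) {
      s <- extract_feature_seq(genome, f)
      ncod <- nchar(s) %/% 3L
      if (ncod == 0L) return("")
      paste(substring(s, seq_len(ncod) * 3L, seq_len(ncod) * 3L),
            collapse = "")
    }, character(1))
    return(base_counts(paste(thirds, collapse = "")))
  }
  ## non_protein: positions not covered by any CDS, on the main strand
  mask <- coverage_mask(genome, features_of_kind(genome, "CDS"))
  ch <- seq_chars(genome$sequence)
  base_counts(paste(ch[!mask], collapse = ""))
}

#' AT- and GT-content of a gene class
#'
#' Concatenates the main-strand-oriented sequences of all genes of one kind
#' (a base shared by two overlapping genes counts once per gene) and reports
#' the absolute A+T and G+T counts with their percentages of the
#' concatenated length.
#'
#' @param genome An [annotated_genome()].
#' @param kind One of `"CDS"`, `"tRNA"`, `"rRNA"`.
#' @return A `content_summary` list: `region_label`, `length`, `at_count`,
#'   `at_percent`, `gt_count`, `gt_percent`.
#' @export
gene_class_content <- function(genome, kind = c("CDS", "tRNA", "rRNA")) {
  kind <- match.arg(kind)
  feats <- features_of_kind(genome, kind)
  if (length(feats) == 0L) stop("no features of kind ", kind)
  seqs <- vapply(feats, function(f) extract_feature_seq(genome, f,
                                                        apply_frame = FALSE),
                 character(1))
  cnt <- base_counts(paste(seqs, collapse = ""))
  len <- cnt$total + cnt$n_other
  structure(list(region_label = kind, length = len,
                 at_count = cnt$a + cnt$t,
                 at_percent = round(100 * (cnt$a + cnt$t) / len, 1),
                 gt_count = cnt$g + cnt$t,
                 gt_percent = round(100 * (cnt$g + cnt$t) / len, 1)),
            class = "content_summary")
}

#' Census of maximal homopolymer runs
#'
#' Counts maximal runs of one base (a run of length L is not also counted at
#' L-1).  With `circular = TRUE` a run spanning the origin of the linearized
#' sequence is joined.
#'
#' @param seq Nucleotide string.
#' @param base One of `"A"`, `"C"`, `"G"`, `"T"`.
#' @param circular Join a run wrapping the origin (default `TRUE`).
#' @param min_length Smallest run length reported (default 2).
#' @return A `run_census` object: `base` and `counts`, a named integer vector
#'   mapping run length to the number of maximal runs.
#' @export
homopolymer_runs <- function(seq, base = "T", circular = TRUE,
                             min_length = 2L) {
  base <- match.arg(base, DNA_BASES)
  check_alphabet(seq)
  ch <- seq_chars(seq)
  r <- rle(ch == base)
  lens <- r$lengths[r$values]
  if (circular && length(r$values) >= 2L &&
      r$values[1] && r$values[length(r$values)]) {
    ## join the run spanning the origin
    joined <- r$lengths[1] + r$lengths[length(r$lengths)]
    lens <- c(lens[-c(1L, length(lens))], joined)
  }
  lens <- lens[lens >= min_length]
  counts <- table(lens)
  structure(list(base = base,
                 counts = stats::setNames(as.integer(counts),
                                          names(counts))),
            class = "run_census")
}

#' @export
print.run_census <- function(x, ...) {
  cat(sprintf("<run_census> base %s: %s\n", x$base,
              paste(sprintf("%sx%d", names(x$counts), x$counts),
                    collapse = ", ")))
  invisible(x)
}

#' Composition summary table for a genome
#'
#' One row per region/class with counts, percentages and skews; the column
#' schema is identical across genomes so rows from many genomes can be
#' stacked into a comparative atlas.
#'
#' @param genome An [annotated_genome()].
#' @return A data frame with one row per available region class.
#' @export
composition_table <- function(genome) {
  regions <- list(whole = function() region_counts(genome, "whole"))
  if (length(features_of_kind(genome, "CDS")) > 0L) {
    regions$third_codon_positions <-
      function() region_counts(genome, "third_codon_positions")
    regions$non_protein <- function() region_counts(genome, "non_protein")
  }
  rows <- lapply(names(regions), function(lab) {
    cnt <- regions[[lab]]()
    data.frame(genome = genome$id, region = lab,
               a = cnt$a, c = cnt$c, g = cnt$g, t = cnt$t,
               length = cnt$total + cnt$n_other,
               at_percent = round(100 * (cnt$a + cnt$t) / cnt$total, 1),
               gt_percent = round(100 * (cnt$g + cnt$t) / cnt$total, 1),
               at_skew = at_skew(cnt), gc_skew = gc_skew(cnt))
  })
  classes <- intersect(GENE_KINDS,
                       vapply(genome$features, `[[`, character(1), "kind"))
  class_rows <- lapply(classes, function(k) {
    cs <- gene_class_content(genome, k)
    seqs <- vapply(features_of_kind(genome, k),
                   function(f) extract_feature_seq(genome, f,
                                                   apply_frame = FALSE),
                   character(1))
    cnt <- base_counts(paste(seqs, collapse = ""))
    data.frame(genome = genome$id, region = k,
               a = cnt$a, c = cnt$c, g = cnt$g, t = cnt$t,
               length = cs$length, at_percent = cs$at_percent,
               gt_percent = cs$gt_percent,
               at_skew = at_skew(cnt), gc_skew = gc_skew(cnt))
  })
  out <- do.call(rbind, c(rows, class_rows))
  rownames(out) <- NULL
  out
}
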