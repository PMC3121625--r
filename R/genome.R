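## AnnotatedGenome and GeneFeature containers.
##
## Coordinates are 0-based half-open throughout.  A feature interval may wrap
## the circular origin, in which case end > genome length and the covered
## positions are (start:(end-1)) %% length.  GenBank I/O converts to and from
## 1-based inclusive coordinates at the boundary.

GENE_KINDS <- c("CDS", "tRNA", "rRNA")
STRANDS <- c("main", "opposite")

#' Create a gene feature
#'
#' @param name Canonical gene symbol (e.g. `"COX1"`, `"ND5"`, `"rrnS"`,
#'   `"trnK"`).
#' @param kind One of `"CDS"`, `"tRNA"`, `"rRNA"`.
#' @param strand `"main"` for the stored (plus) strand, `"opposite"` for the
#'   complement.
#' @param intervals Two-column numeric matrix of 0-based half-open
#'   `(start, end)` rows; `end` may exceed the genome length for an interval
#'   wrapping the circular origin.
#' @param frame_offset Number of bases (0..2) skipped before the first
#'   complete codon (GenBank `codon_start` minus one).
#' @return A `gene_feature` object.
#' @export
gene_feature <- function(name, kind, strand = "main", intervals,
                         frame_offset = 0L) {
  kind <- match.arg(kind, GENE_KINDS)
  strand <- match.arg(strand, STRANDS)
  if (is.vector(intervals) && length(intervals) == 2L) {
    intervals <- matrix(intervals, ncol = 2L)
  }
  intervals <- matrix(as.numeric(intervals), ncol = 2L,
                      dimnames = list(NULL, c("start", "end")))
  if (any(intervals[, "end"] <= intervals[, "start"])) {
    stop("feature '", name, "': interval end must exceed start")
  }
  structure(
    list(name = as.character(name), kind = kind, strand = strand,
         intervals = intervals, frame_offset = as.integer(frame_offset)),
    class = "gene_feature")
}

#' Spliced length of a feature
#' @param feature A [gene_feature()].
#' @return Total interval length in bases.
#' @export
feature_length <- function(feature) {
  sum(feature$intervals[, "end"] - feature$intervals[, "start"])
}

## Incomplete stop codons (completed by polyadenylation) leave a CDS whose
## spliced length is not a multiple of three.
feature_incomplete_stop <- function(feature) {
  feature$kind == "CDS" &&
    (feature_length(feature) - feature$frame_offset) %% 3 != 0
}

#' Create an annotated genome
#'
#' @param id Accession or other identifier.
#' @param sequence Upper-case nucleotide string over `A`,`C`,`G`,`T`,`N`.
#' @param circular Logical; circular topology.
#' @param features List of [gene_feature()] objects.
#' @return An `annotated_genome` object.
#' @export
annotated_genome <- function(id, sequence, circular = TRUE,
                             features = list()) {
  sequence <- toupper(sequence)
  if (nchar(sequence) == 0L) stop("empty sequence")
  check_alphabet(sequence, "genome sequence")
  n <- nchar(sequence)
  if (isTRUE(circular)) {
    ## canonical form: a splice running to the sequence end and resuming at 0
    ## is stored as one wrapping interval
    features <- lapply(features, function(f) {
      iv <- f$intervals
      i <- 1L
      while (i < nrow(iv)) {
        if (iv[i, "end"] == n && iv[i + 1L, "start"] == 0) {
          iv[i, "end"] <- n + iv[i + 1L, "end"]
          iv <- iv[-(i + 1L), , drop = FALSE]
        } else i <- i + 1L
      }
      f$intervals <- iv
      f
    })
  }
  for (f in features) {
    if (!inherits(f, "gene_feature")) stop("features must be gene_feature")
    iv <- f$intervals
    if (any(iv[, "start"] < 0) || any(iv[, "start"] >= n)) {
      stop("feature '", f$name, "': interval start outside [0, length)")
    }
    if (any(iv[, "end"] > iv[, "start"] + n)) {
      stop("feature '", f$name, "': interval wraps more than once")
    }
    if (!circular && any(iv[, "end"] > n)) {
      stop("feature '", f$name, "': wrapping interval on a linear genome")
    }
  }
  keys <- vapply(features, function(f) paste(f$name, f$kind), character(1))
  if (anyDuplicated(keys)) {
    stop("duplicate feature (name, kind): ", keys[duplicated(keys)][1])
  }
  structure(
    list(id = as.character(id), sequence = sequence,
         circular = isTRUE(circular), features = features),
    class = "annotated_genome")
}

#' @export
print.annotated_genome <- function(x, ...) {
  kinds <- vapply(x$features, `[[`, character(1), "kind")
  cat(sprintf("<annotated_genome> %s: %d bp %s, %d CDS / %d rRNA / %d tRNA\n",
              x$id, nchar(x$sequence),
              if (x$circular) "circular" else "linear",
              sum(kinds == "CDS"), sum(kinds == "rRNA"),
              sum(kinds == "tRNA")))
  invisible(x)
}

#' Genome length in bases
#' @param genome An [annotated_genome()].
#' @return Integer length.
#' @export
genome_length <- function(genome) nchar(genome$sequence)

#' Features of one kind
#' @param genome An [annotated_genome()].
#' @param kind `"CDS"`, `"tRNA"` or `"rRNA"`.
#' @return List of [gene_feature()] objects.
#' @export
features_of_kind <- function(genome, kind) {
  Filter(function(f) f$kind == kind, genome$features)
}

#' Look up a feature by name
#' @param genome An [annotated_genome()].
#' @param name Gene symbol.
#' @param kind Optional kind filter.
#' @return The matching [gene_feature()]; error when absent.
#' @export
get_feature <- function(genome, name, kind = NULL) {
  for (f in genome$features) {
    if (f$name == name && (is.null(kind) || f$kind == kind)) return(f)
  }
  stop("no feature named '", name, "' in genome ", genome$id)
}

#' Extract the spliced, strand-oriented sequence of a feature
#'
#' Intervals are concatenated in their listed order (wrapping the circular
#' origin when needed), the result is reverse-complemented for features on the
#' opposite strand, and `frame_offset` leading bases are dropped so a CDS
#' starts at its first complete codon.
#'
#' @param genome An [annotated_genome()].
#' @param feature A [gene_feature()] belonging to `genome`.
#' @param apply_frame Drop `frame_offset` leading bases (default `TRUE`).
#' @return Nucleotide string (DNA alphabet).
#' @export
extract_feature_seq <- function(genome, feature, apply_frame = TRUE) {
  n <- genome_length(genome)
  pieces <- apply(feature$intervals, 1L, function(iv) {
    s <- iv[[1]]; e <- iv[[2]]
    if (e > n) {
      if (!genome$circular) stop("wrapping interval on a linear genome")
      paste0(substr(genome$sequence, s + 1L, n),
             substr(genome$sequence, 1L, e - n))
    } else {
      substr(genome$sequence, s + 1L, e)
    }
  })
  out <- paste(pieces, collapse = "")
  if (feature$strand == "opposite") out <- revcomp(out)
  if (apply_frame && feature$frame_offset > 0L) {
    out <- substr(out, feature$frame_offset + 1L, nchar(out))
  }
  out
}

## Logical coverage vector (length n) of one feature or a list of features.
coverage_mask <- function(genome, features) {
  n <- genome_length(genome)
  mask <- logical(n)
  if (inherits(features, "gene_feature")) features <- list(features)
  for (f in features) {
    for (i in seq_len(nrow(f$intervals))) {
      s <- f$intervals[i, "start"]; e <- f$intervals[i, "end"]
      idx <- (seq.int(s, e - 1L) %% n) + 1L
      mask[idx] <- TRUE
    }
  }
  mask
}

#' Determine the main-coding strand of a genome
#'
#' The main-coding strand is the strand carrying the majority of
#' protein-coding nucleotides (all 13 CDS in a typical metazoan mitogenome).
#'
#' @param genome An [annotated_genome()].
#' @param override Optional `"main"` or `"opposite"` to force the call.
#' @return `"main"` (the stored sequence) or `"opposite"` (its complement).
#' @export
main_strand <- function(genome, override = NULL) {
  if (!is.null(override)) return(match.arg(override, STRANDS))
  cds <- features_of_kind(genome, "CDS")
  if (length(cds) == 0L) return("main")
  len_by_strand <- c(main = 0, opposite = 0)
  for (f in cds) {
    len_by_strand[f$strand] <- len_by_strand[f$strand] + feature_length(f)
  }
  if (len_by_strand["opposite"] > len_by_strand["main"]) "opposite" else "main"
}

#' Re-orient a genome so its main-coding strand is the stored sequence
#'
#' If the majority of CDS nucleotides lie on the opposite strand, the sequence
#' is reverse-complemented and every feature is remapped; otherwise the genome
#' is returned unchanged.
#'
#' @inheritParams main_strand
#' @return An [annotated_genome()] whose plus strand is the main-coding
#'   strand.
#' @export
orient_main <- function(genome, override = NULL) {
  if (main_strand(genome, override) == "main") return(genome)
  n <- genome_length(genome)
  feats <- lapply(genome$features, function(f) {
    iv <- f$intervals
    new_iv <- t(apply(iv, 1L, function(r) {
      len <- r[[2]] - r[[1]]
      s <- (n - r[[2]]) %% n
      c(s, s + len)
    }))
    f$intervals <- new_iv[rev(seq_len(nrow(new_iv))), , drop = FALSE]
    colnames(f$intervals) <- c("start", "end")
    f$strand <- if (f$strand == "main") "opposite" else "main"
    f
  })
  starts <- vapply(feats, function(f) f$intervals[1, "start"], numeric(1))
  annotated_genome(genome$id, revcomp(genome$sequence), genome$circular,
                   feats[order(starts)])
}

## Main-coding-strand sequence without re-mapping features.
main_strand_seq <- function(genome, override = NULL) {
  if (main_strand(genome, override) == "main") genome$sequence
  else revcomp(genome$sequence)
}

#' Unassigned-sequence (UAS) census
#'
#' Maximal regions covered by no annotated feature, computed against the
#' union of all features on both strands, with circular joining across the
#' origin.
#'
#' @param genome An [annotated_genome()] with at least one feature.
#' @return A list with `regions` (data frame: `start`, `end`, `length`,
#'   `upstream`, `downstream` flanking feature names; 0-based half-open, `end`
#'   may exceed the genome length for the region spanning the origin) and
#'   `fraction`, the total UAS share of the genome.
#' @export
unassigned_regions <- function(genome) {
  if (length(genome$features) == 0L) stop("genome has no features")
  n <- genome_length(genome)
  covered <- coverage_mask(genome, genome$features)
  empty <- data.frame(start = numeric(0), end = numeric(0),
                      length = numeric(0), upstream = character(0),
                      downstream = character(0))
  if (all(covered)) return(list(regions = empty, fraction = 0))
  if (!any(covered)) {
    return(list(regions = data.frame(start = 0, end = n, length = n,
                                     upstream = NA_character_,
                                     downstream = NA_character_),
                fraction = 1))
  }
  r <- rle(covered)
  ends <- cumsum(r$lengths)           # 1-based inclusive run ends
  starts0 <- c(0, ends[-length(ends)])  # 0-based run starts
  gaps <- data.frame(start = starts0[!r$values],
                     end = ends[!r$values])
  ## circular joining: a gap touching both ends of the linearization is one
  ## region wrapping the origin
  if (genome$circular && nrow(gaps) >= 2L &&
      gaps$start[1] == 0 && gaps$end[nrow(gaps)] == n) {
    gaps$end[nrow(gaps)] <- n + gaps$end[1]
    gaps <- gaps[-1L, , drop = FALSE]
  }
  gaps$length <- gaps$end - gaps$start
  ## flanking features: nearest feature boundary on each side
  fstart <- unlist(lapply(genome$features,
                          function(f) f$intervals[, "start"]))
  fend <- unlist(lapply(genome$features, function(f) f$intervals[, "end"]))
  fname <- rep(vapply(genome$features, `[[`, character(1), "name"),
               vapply(genome$features, function(f) nrow(f$intervals),
                      integer(1)))
  gaps$upstream <- vapply(gaps$start, function(s) {
    d <- (s - (fend %% n)) %% n
    fname[which.min(d)]
  }, character(1))
  gaps$downstream <- vapply(gaps$end, function(e) {
    d <- (fstart - (e %% n)) %% n
    fname[which.min(d)]
  }, character(1))
  rownames(gaps) <- NULL
  list(regions = gaps[, c("start", "end", "length", "upstream", "downstream")],
       fraction = sum(gaps$length) / n)
}
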