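## Codon usage tables, amino-acid composition, GT/AC codon-class labelling,
## anticodon-versatility classification and the adaptation test.

#' Codon usage over all protein-coding genes
#'
#' Counts every complete in-frame codon of every CDS, including full stop
#' codons.  A trailing incomplete stop (1-2 bases, completed to UAA by
#' polyadenylation of the transcript) is excluded from the 64-codon counts
#' and tallied separately.  A CDS containing an internal stop raises a
#' warning but is counted anyway.
#'
#' @param genome An [annotated_genome()] with at least one CDS.
#' @param code A [genetic_code()].
#' @return A `codon_usage` object: `counts` (named integer, 64 RNA codons),
#'   `incomplete_stops` (number of CDS ending in a partial stop), `code`,
#'   `genes`.
#' @export
codon_usage <- function(genome, code = genetic_code("rhabdopleura")) {
  cds <- features_of_kind(genome, "CDS")
  if (length(cds) == 0L) stop("genome has no CDS features")
  counts <- stats::setNames(integer(64L), ALL_CODONS)
  incomplete <- 0L
  for (f in cds) {
    s <- extract_feature_seq(genome, f)
    ncod <- nchar(s) %/% 3L
    if (nchar(s) %% 3L != 0L) incomplete <- incomplete + 1L
    if (ncod == 0L) next
    codons <- dna_to_rna(substring(s, 3L * seq_len(ncod) - 2L,
                                   3L * seq_len(ncod)))
    keep <- codons %in% ALL_CODONS   # codons containing N are not tallied
    aa <- translate_codons(codons[keep], code)
    if (any(aa[-length(aa)] == "*")) {
      warning("internal stop codon in CDS '", f$name, "'")
    }
    tab <- table(codons[keep])
    counts[names(tab)] <- counts[names(tab)] + as.integer(tab)
  }
  structure(list(counts = counts, incomplete_stops = incomplete,
                 code = code,
                 genes = vapply(cds, `[[`, character(1), "name")),
            class = "codon_usage")
}

## A usage table from bare counts (e.g. a published codon-usage table).
usage_from_counts <- function(counts, code) {
  full <- stats::setNames(integer(64L), ALL_CODONS)
  nm <- dna_to_rna(names(counts))
  stopifnot(all(nm %in% ALL_CODONS))
  full[nm] <- as.integer(counts)
  structure(list(counts = full, incomplete_stops = NA_integer_, code = code,
                 genes = character(0)),
            class = "codon_usage")
}

#' Read a codon-usage table from a TSV file
#'
#' Expects at least columns `codon` and `count`; further columns (amino
#' acid, anticodon markers) are ignored.
#'
#' @param path TSV file path.
#' @param code A [genetic_code()] attached to the table.
#' @return A `codon_usage` object.
#' @export
read_codon_usage <- function(path, code = genetic_code("rhabdopleura")) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          comment.char = "#")
  usage_from_counts(stats::setNames(df$count, df$codon), code)
}

#' Amino-acid composition from a codon usage table
#'
#' Frequencies over non-stop codons, normalised to sum to one.
#'
#' @param usage A [codon_usage()] table.
#' @return Named numeric vector of one-letter amino-acid frequencies.
#' @export
aa_composition <- function(usage) {
  aa <- usage$code$map
  sense <- aa != "*"
  tot <- sum(usage$counts[sense])
  if (tot == 0) stop("usage contains no sense codons")
  freq <- tapply(usage$counts[sense], aa[sense], sum) / tot
  out <- as.vector(freq)
  names(out) <- names(freq)
  out[order(names(out))]
}

codon_is_gt_rich <- function(codon) {
  vapply(strsplit(codon, ""), function(ch) sum(ch %in% c("G", "U", "T")) >= 2L,
         logical(1))
}

#' Classify an amino acid by the strandedness of its codons
#'
#' A codon is GT-rich when at least two of its three bases are G or U, and
#' AC-rich when at least two are A or C.  An amino acid is `GT_exclusive`
#' when every codon encoding it under `code` is GT-rich, `AC_exclusive` when
#' every codon is AC-rich, and `mixed` otherwise.  On a GT-rich main-coding
#' strand the GT-exclusive amino acids (Phe, Gly, Val, Trp in metazoan
#' mitochondrial codes) are enriched and the AC-exclusive ones (Thr, Pro,
#' Asn, His, Gln) depleted.
#'
#' @param amino_acid One-letter or three-letter amino-acid symbol.
#' @param code A [genetic_code()].
#' @return `"GT_exclusive"`, `"AC_exclusive"`, or `"mixed"`.
#' @export
classify_codon_strandedness <- function(amino_acid, code) {
  aa <- aa_one_letter(amino_acid)
  codons <- names(code$map)[code$map == aa]
  if (length(codons) == 0L) stop("amino acid '", amino_acid,
                                 "' is not encoded by code ", code$id)
  gt <- codon_is_gt_rich(codons)
  ac <- vapply(strsplit(codons, ""),
               function(ch) sum(ch %in% c("A", "C")) >= 2L, logical(1))
  if (all(gt)) "GT_exclusive" else if (all(ac)) "AC_exclusive" else "mixed"
}

#' Anticodon set of a tRNA system
#'
#' @param aa Amino acids served (one- or three-letter).
#' @param anticodon Anticodons, 5'→3' in RNA.
#' @param name Optional tRNA names (default `trnX` from the amino acid).
#' @return An `anticodon_set` data frame with columns `name`, `aa`,
#'   `anticodon`, `codon_recognized` (the exact Watson-Crick complement).
#' @export
anticodon_set <- function(aa, anticodon, name = NULL) {
  aa <- aa_one_letter(aa)
  anticodon <- dna_to_rna(toupper(anticodon))
  stopifnot(all(nchar(anticodon) == 3L))
  df <- data.frame(name = name %||% paste0("trn", aa), aa = aa,
                   anticodon = anticodon,
                   codon_recognized = anticodon_to_codon(anticodon),
                   stringsAsFactors = FALSE)
  class(df) <- c("anticodon_set", "data.frame")
  df
}

#' Read an anticodon set from a TSV file with columns `aa` and `anticodon`
#' (optionally `name`).
#'
#' @param path TSV file path.
#' @return An [anticodon_set()].
#' @export
read_anticodons <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          comment.char = "#")
  anticodon_set(df$aa, df$anticodon, df$name)
}

#' The fully versatile anticodon set for a genetic code
#'
#' One tRNA per codon family, each carrying the anticodon of highest
#' versatility; useful as a baseline in pairing classification tests.
#'
#' @param code A [genetic_code()].
#' @return An [anticodon_set()].
#' @export
versatile_anticodon_set <- function(code) {
  fams <- codon_families(code)
  anticodon_set(vapply(fams, `[[`, character(1), "aa"),
                vapply(fams, function(f) as.character(versatile_anticodon(f)),
                       character(1)))
}

## Codons an anticodon can read: exact pairing at positions 2 and 3 of the
## codon, wobble pairing at position 3 (anticodon position 1): G reads U/C,
## U reads A/G, C reads G, A reads U.
anticodon_reads <- function(anticodon) {
  wobble_sets <- list(G = c("C", "U"), U = c("A", "G"), C = "G", A = "U")
  first2 <- revcomp_rna(substr(anticodon, 2, 3))
  paste0(first2, wobble_sets[[substr(anticodon, 1, 1)]])
}

## The tRNA cognate to a family: same amino acid and at least one family
## codon readable under the wobble rules.
cognate_index <- function(family, anticodons) {
  which(anticodons$aa == family$aa &
          vapply(anticodons$anticodon,
                 function(ac) any(anticodon_reads(ac) %in% family$codons),
                 logical(1)))
}

#' Classify each codon family against the versatility scheme
#'
#' Each family is classified as `versatile` when its cognate anticodon
#' equals [versatile_anticodon()] for the family, `adapted` when it is
#' instead the exact complement of the family's most frequent codon,
#' `deviant` when neither, and `uncovered` when no cognate tRNA exists.  The
#' deviation count is the number of families not classified `versatile` --
#' the departures from an anticodon system of highest versatility.
#'
#' @param anticodons An [anticodon_set()].
#' @param code A [genetic_code()].
#' @param usage A [codon_usage()] table (for the `adapted` test).
#' @return A `pairing_report`: `families` data frame (`aa`, `codons`,
#'   `anticodon`, `classification`, `note`), `deviations` count and
#'   `deviant_families` labels.
#' @export
classify_pairing <- function(anticodons, code, usage) {
  fams <- codon_families(code)
  served <- unlist(lapply(fams, function(f) cognate_index(f, anticodons)))
  orphan <- setdiff(seq_len(nrow(anticodons)), served)
  if (length(orphan) > 0L) {
    stop("anticodon(s) serving no codon family of code ", code$id, ": ",
         paste(anticodons$anticodon[orphan], collapse = ", "))
  }
  rows <- lapply(fams, function(f) {
    idx <- cognate_index(f, anticodons)
    note <- ""
    if (length(idx) == 0L) {
      cls <- "uncovered"
      ac <- NA_character_
      ## AGR codons left without a cognate tRNA can be read by a
      ## methylated-G GCU serine anticodon in some lineages
      ser_gcu <- anticodons$anticodon[anticodons$aa == "S"] == "GCU"
      if (any(f$codons %in% c("AGA", "AGG")) && any(ser_gcu)) {
        note <- "AGR may pair with tRNA-Ser/GCU via anticodon G methylation"
      }
    } else {
      ac <- anticodons$anticodon[idx[1]]
      va <- tryCatch(versatile_anticodon(f), error = function(e) NA)
      top <- f$codons[which.max(usage$counts[f$codons])]
      if (!is.na(va[1]) && ac == as.character(va)) {
        cls <- "versatile"
        if (attr(va, "singleton")) note <- "singleton family"
      } else if (ac == revcomp_rna(top)) {
        cls <- "adapted"
        note <- paste0("complement of most frequent codon ", top)
      } else {
        cls <- "deviant"
      }
      if (cls != "versatile" && f$aa == "S" && ac == "GCU" &&
          any(substr(f$codons, 3, 3) %in% c("A", "G"))) {
        note <- paste0(note, if (nzchar(note)) "; ",
                       "purine-ending codons readable via G methylation")
      }
    }
    data.frame(aa = f$aa, codons = paste(f$codons, collapse = ","),
               anticodon = ac, classification = cls, note = note,
               stringsAsFactors = FALSE)
  })
  families <- do.call(rbind, rows)
  deviant <- families$classification != "versatile"
  structure(list(families = families, deviations = sum(deviant),
                 deviant_families = paste(families$aa[deviant],
                                          families$codons[deviant])),
            class = "pairing_report")
}

#' @export
print.pairing_report <- function(x, ...) {
  cat(sprintf("<pairing_report> %d families, %d deviation(s) from highest versatility\n",
              nrow(x$families), x$deviations))
  for (i in which(x$families$classification != "versatile")) {
    cat(sprintf("  %s [%s]: %s %s\n", x$families$aa[i], x$families$codons[i],
                x$families$classification[i], x$families$note[i]))
  }
  invisible(x)
}

#' Test anticodon adaptation to the most frequent codon
#'
#' For each codon family with a cognate tRNA, reports whether the reverse
#' complement of its anticodon is the family's most frequent codon.  Under
#' the codon-anticodon adaptation hypothesis this should usually be true;
#' in strongly biased genomes the complements instead tend to be the rare
#' codons, rejecting adaptation.
#'
#' @param anticodons An [anticodon_set()].
#' @param usage A [codon_usage()] table (its code defines the families).
#' @return Data frame: `aa`, `codons`, `anticodon`, `recognized`,
#'   `top_codon`, `adapted` (`NA` for a family with zero usage), `tie`.
#' @export
adaptation_test <- function(anticodons, usage) {
  fams <- codon_families(usage$code)
  rows <- lapply(fams, function(f) {
    idx <- cognate_index(f, anticodons)
    if (length(idx) == 0L) return(NULL)
    cnt <- usage$counts[f$codons]
    top <- f$codons[cnt == max(cnt)]
    rec <- anticodons$codon_recognized[idx[1]]
    adapted <- if (sum(cnt) == 0) NA else rec %in% top
    data.frame(aa = f$aa, codons = paste(f$codons, collapse = ","),
               anticodon = anticodons$anticodon[idx[1]], recognized = rec,
               top_codon = top[1], adapted = adapted,
               tie = length(top) > 1L && sum(cnt) > 0,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write a codon usage table in the classic 64-row layout
#'
#' @param usage A [codon_usage()] table.
#' @param path Output TSV path.
#' @param anticodons Optional [anticodon_set()]; recognized codons are
#'   marked in an `anticodon` column.
#' @return `path`, invisibly.
#' @export
write_codon_usage <- function(usage, path, anticodons = NULL) {
  df <- data.frame(codon = ALL_CODONS,
                   count = unname(usage$counts),
                   aa = aa_three_letter(unname(usage$code$map)),
                   stringsAsFactors = FALSE)
  if (!is.null(anticodons)) {
    df$anticodon <- ifelse(df$codon %in% anticodons$codon_recognized,
                           "*", "")
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
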