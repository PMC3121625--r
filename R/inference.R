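## Conservation-based genetic-code assignment.
##
## Each codon of each protein-coding gene is mapped onto a column of an
## aligned set of reference protein sequences; columns are graded into four
## conservation degrees by their majority-residue fraction; the reference
## residues at a codon's sites are tallied degree by degree; and the codon's
## amino acid is called from the most conserved non-empty degree when the
## majority fraction reaches the call threshold.  Reference alignments are
## inputs (aligned FASTA), never computed here.

DEGREES <- c("highly_conserved", "conserved", "weakly_conserved", "variable")

#' Build a reference alignment object
#'
#' @param gene Gene name.
#' @param rows Named character vector of equal-length aligned amino-acid
#'   strings (gap `"-"`), including the target row.
#' @param target Name of the target row (default `"target"`).
#' @return A `reference_alignment` object.
#' @export
reference_alignment <- function(gene, rows, target = "target") {
  stopifnot(is.character(rows), !is.null(names(rows)))
  if (length(unique(nchar(rows))) != 1L) {
    stop("alignment rows for '", gene, "' have unequal lengths")
  }
  if (!target %in% names(rows)) {
    stop("target row '", target, "' missing from alignment for ", gene)
  }
  structure(list(gene = gene, rows = rows, target = target,
                 ncol = nchar(rows[[1]])),
            class = "reference_alignment")
}

#' Read a reference alignment from an aligned FASTA file
#'
#' @param path Aligned-FASTA path.
#' @param gene Gene name (default: file name without extension).
#' @param target Name of the target row.
#' @return A [reference_alignment()].
#' @export
read_alignment_fasta <- function(path, gene = NULL, target = "target") {
  ss <- Biostrings::readAAStringSet(path)
  rows <- stats::setNames(as.character(ss), sub("\\s.*$", "", names(ss)))
  reference_alignment(gene %||% sub("\\.[^.]*$", "", basename(path)),
                      rows, target)
}

#' Map target codons to alignment columns
#'
#' Codon i of the target CDS maps to the column holding the i-th non-gap
#' character of the target's aligned row.
#'
#' @param target_cds Nucleotide string of the CDS (frame-corrected; may end
#'   in a complete or incomplete stop).
#' @param alignment A [reference_alignment()].
#' @return Integer vector of 1-based column indices, one per aligned codon.
#' @export
map_codon_sites <- function(target_cds, alignment) {
  aligned <- alignment$rows[[alignment$target]]
  cols <- which(seq_chars(aligned) != "-")
  ncod <- nchar(target_cds) %/% 3L
  ## the aligned row covers the protein; the CDS may add a (possibly
  ## incomplete) terminal stop codon
  if (length(cols) != ncod && length(cols) != ncod - 1L) {
    stop("frameshift: CDS has ", ncod, " codons but target row has ",
         length(cols), " residues")
  }
  cols
}

#' Grade an alignment column by conservation
#'
#' The degree is set by the majority-residue fraction f over non-gap
#' residues: f >= `thresholds[1]` is `highly_conserved`, f >=
#' `thresholds[2]` `conserved`, f >= `thresholds[3]` `weakly_conserved`,
#' else `variable`.  All-gap columns are excluded (`NA`).
#'
#' @param column Character vector of residues (gaps `"-"` allowed).
#' @param thresholds Decreasing numeric vector of three fractions
#'   (default `c(0.9, 0.7, 0.5)`).
#' @return One of the four degree labels, or `NA` for an all-gap column.
#' @export
grade_column <- function(column, thresholds = c(0.9, 0.7, 0.5)) {
  res <- column[column != "-" & column != "X"]
  if (length(res) == 0L) return(NA_character_)
  f <- max(table(res)) / length(res)
  if (f >= thresholds[1]) "highly_conserved"
  else if (f >= thresholds[2]) "conserved"
  else if (f >= thresholds[3]) "weakly_conserved"
  else "variable"
}

#' Tally reference residues for one codon, stratified by degree
#'
#' @param columns List of character vectors: the reference residues (target
#'   excluded) at each site where the codon occurs.
#' @param degrees Degree label per site (from [grade_column()]).
#' @param codon Codon label carried on the result.
#' @return A `conservation_tally`: per-degree residue counts, site counts
#'   and majority fraction.
#' @export
conservation_tally <- function(columns, degrees, codon = NA_character_) {
  keep <- !is.na(degrees)
  columns <- columns[keep]
  degrees <- degrees[keep]
  per_degree <- lapply(DEGREES, function(d) {
    res <- unlist(columns[degrees == d])
    res <- res[res != "-" & res != "X"]
    n_sites <- sum(degrees == d)
    if (length(res) == 0L) {
      return(list(counts = integer(0), n_sites = n_sites,
                  majority_fraction = NA_real_))
    }
    tab <- sort(table(res), decreasing = TRUE)
    list(counts = stats::setNames(as.integer(tab), names(tab)),
         n_sites = n_sites,
         majority_fraction = unname(tab[1] / sum(tab)))
  })
  names(per_degree) <- DEGREES
  structure(list(codon = codon, per_degree = per_degree,
                 n_sites = length(columns)),
            class = "conservation_tally")
}

#' Call the amino-acid assignment of one codon from its tally
#'
#' The call is the majority residue at the most conserved degree with at
#' least one site, provided its pooled fraction reaches `call_threshold`
#' and is not tied; otherwise the codon is `ambiguous`.  An ambiguous codon
#' may fall back to (a) the amino acid of a tRNA whose anticodon complement
#' is the codon, or (b) a donor code's assignment; both fallbacks are
#' flagged.  A codon with no sites is `absent` -- never invented.
#'
#' @param tally A [conservation_tally()].
#' @param call_threshold Minimum pooled majority fraction (default 0.45).
#' @param anticodons Optional [anticodon_set()] for fallback (a).
#' @param base_code Optional [genetic_code()] for fallback (b).
#' @return An `assignment_call`: `codon`, `call` (one-letter amino acid,
#'   `"ambiguous"` or `"absent"`), `support`, `degree`, `fallback`
#'   (`"none"`, `"anticodon"`, `"base_code"` or `"absent"`).
#' @export
call_assignment <- function(tally, call_threshold = 0.45,
                            anticodons = NULL, base_code = NULL) {
  out <- list(codon = tally$codon, call = "ambiguous", support = NA_real_,
              degree = NA_character_, fallback = "none")
  if (tally$n_sites == 0L) {
    out$call <- "absent"
    out$fallback <- "absent"
    return(structure(out, class = "assignment_call"))
  }
  for (d in DEGREES) {
    pd <- tally$per_degree[[d]]
    if (pd$n_sites == 0L || length(pd$counts) == 0L) next
    out$degree <- d
    out$support <- pd$majority_fraction
    top <- names(pd$counts)[pd$counts == max(pd$counts)]
    if (length(top) == 1L && pd$majority_fraction >= call_threshold) {
      out$call <- top
    }
    break
  }
  if (out$call == "ambiguous" && !is.null(anticodons)) {
    hit <- which(anticodons$codon_recognized == tally$codon)
    if (length(hit) == 1L) {
      out$call <- anticodons$aa[hit]
      out$fallback <- "anticodon"
    }
  }
  if (out$call == "ambiguous" && !is.null(base_code)) {
    out$call <- unname(base_code$map[tally$codon])
    out$fallback <- "base_code"
  }
  structure(out, class = "assignment_call")
}

#' Infer a genetic code from reference protein alignments
#'
#' Runs the full conservation pipeline: for each CDS with a reference
#' alignment, codons are mapped to columns, columns graded, and per-codon
#' tallies accumulated over all genes; each codon is then called with
#' [call_assignment()].  Codons left ambiguous or absent inherit the
#' assignment of `base_code` with a fallback flag, so the assembled code is
#' complete and usable by [codon_usage()].
#'
#' @param genome An [annotated_genome()].
#' @param alignments Named list of [reference_alignment()] objects, one per
#'   CDS gene name; genes without an alignment are skipped with a warning.
#' @param thresholds Degree-banding thresholds for [grade_column()].
#' @param call_threshold Minimum support for a direct call.
#' @param base_code Donor [genetic_code()] for unresolved codons (default
#'   invertebrate mitochondrial, table 5).
#' @param anticodons Optional [anticodon_set()] enabling the
#'   anticodon-complement fallback.
#' @return A `code_inference` object: `code` (the assembled
#'   [genetic_code()]), `calls` (data frame: `codon`, `call`, `support`,
#'   `degree`, `fallback`), `n_sites` per codon.
#' @export
infer_code <- function(genome, alignments, thresholds = c(0.9, 0.7, 0.5),
                       call_threshold = 0.45,
                       base_code = genetic_code("5"), anticodons = NULL) {
  genome <- orient_main(genome)
  cds <- features_of_kind(genome, "CDS")
  if (length(cds) == 0L) stop("genome has no CDS features")
  site_cols <- stats::setNames(vector("list", 64L), ALL_CODONS)
  site_degrees <- stats::setNames(vector("list", 64L), ALL_CODONS)
  for (f in cds) {
    aln <- alignments[[f$name]]
    if (is.null(aln)) {
      warning("no reference alignment for gene '", f$name, "'; skipped")
      next
    }
    s <- extract_feature_seq(genome, f)
    cols <- map_codon_sites(s, aln)
    ncod <- length(cols)
    codons <- dna_to_rna(substring(s, 3L * seq_len(ncod) - 2L,
                                   3L * seq_len(ncod)))
    ref_rows <- aln$rows[setdiff(names(aln$rows), aln$target)]
    ref_mat <- do.call(rbind, strsplit(unname(ref_rows), ""))
    for (i in seq_len(ncod)) {
      cod <- codons[i]
      if (!cod %in% ALL_CODONS) next
      column <- ref_mat[, cols[i]]
      site_cols[[cod]] <- c(site_cols[[cod]], list(column))
      site_degrees[[cod]] <- c(site_degrees[[cod]],
                               grade_column(column, thresholds))
    }
  }
  calls <- lapply(ALL_CODONS, function(cod) {
    tally <- conservation_tally(site_cols[[cod]] %||% list(),
                                site_degrees[[cod]] %||% character(0), cod)
    call_assignment(tally, call_threshold, anticodons, base_code = NULL)
  })
  df <- data.frame(
    codon = ALL_CODONS,
    call = vapply(calls, `[[`, character(1), "call"),
    support = vapply(calls, `[[`, numeric(1), "support"),
    degree = vapply(calls, `[[`, character(1), "degree"),
    fallback = vapply(calls, `[[`, character(1), "fallback"),
    n_sites = vapply(ALL_CODONS, function(cod) length(site_cols[[cod]]),
                     integer(1)),
    stringsAsFactors = FALSE)
  ## assemble a complete code: unresolved codons inherit the base code
  map <- base_code$map
  resolved <- !df$call %in% c("ambiguous", "absent")
  map[df$codon[resolved]] <- df$call[resolved]
  df$fallback[!resolved] <- ifelse(df$call[!resolved] == "absent",
                                   "absent", "base_code")
  ## a codon called as stop is only accepted from the base code
  code <- new_genetic_code(paste0("inferred_from_", genome$id), map,
                           base_code$starts)
  structure(list(code = code, calls = df), class = "code_inference")
}

#' @export
print.code_inference <- function(x, ...) {
  direct <- sum(x$calls$fallback == "none")
  cat(sprintf("<code_inference> %s: %d direct calls, %d anticodon, %d base-code, %d absent\n",
              x$code$id, direct, sum(x$calls$fallback == "anticodon"),
              sum(x$calls$fallback == "base_code"),
              sum(x$calls$fallback == "absent")))
  invisible(x)
}
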