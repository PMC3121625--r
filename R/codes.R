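## Genetic codes and codon families.
##
## Codon and anticodon space uses the RNA alphabet (U); the genome modules
## use DNA (T); conversion happens at this module's boundary.  Built-in NCBI
## mitochondrial translation tables come from Biostrings; the Rhabdopleura
## code is the echinoderm table with AAA reassigned to Lys and AGG to Lys
## (AUA = Ile and AGA = Ser as in echinoderms).

ALL_CODONS <- as.vector(outer(outer(RNA_BASES, RNA_BASES, paste0),
                              RNA_BASES, paste0))

CODE_ALIASES <- c(vertebrate = "2", invertebrate = "5", echinoderm = "9",
                  ascidian = "13")

#' Built-in genetic codes
#'
#' @param id `"2"`/`"vertebrate"`, `"5"`/`"invertebrate"`,
#'   `"9"`/`"echinoderm"`, `"13"`/`"ascidian"` (NCBI mitochondrial
#'   translation tables), or `"rhabdopleura"` (echinoderm table with
#'   AAA→Lys and AGG→Lys).
#' @return A `genetic_code` object: `id`, `map` (named character of length
#'   64, RNA codons to one-letter amino acids, `"*"` for stop), `starts`
#'   (start-codon set).
#' @export
genetic_code <- function(id = "rhabdopleura") {
  id <- as.character(id)
  key <- if (id %in% names(CODE_ALIASES)) CODE_ALIASES[[id]] else id
  if (identical(id, "rhabdopleura")) {
    map <- biostrings_code("9")
    map[c("AAA", "AGG")] <- "K"
    starts <- c("AUG", "GUG")
  } else if (key %in% c("2", "5", "9", "13")) {
    map <- biostrings_code(key)
    starts <- c("AUG", "GUG")
  } else {
    stop("unknown genetic code '", id, "'")
  }
  new_genetic_code(id, map, starts)
}

biostrings_code <- function(key) {
  map <- Biostrings::getGeneticCode(key)
  names(map) <- dna_to_rna(names(map))
  map[ALL_CODONS]
}

new_genetic_code <- function(id, map, starts = c("AUG", "GUG")) {
  stopifnot(length(map) == 64L, !is.null(names(map)),
            setequal(names(map), ALL_CODONS))
  map <- map[ALL_CODONS]
  if (!any(map == "*")) stop("a genetic code needs at least one stop codon")
  structure(list(id = id, map = map, starts = starts),
            class = "genetic_code")
}

#' @export
print.genetic_code <- function(x, ...) {
  cat(sprintf("<genetic_code> %s: %d sense codons, stops %s\n", x$id,
              sum(x$map != "*"),
              paste(names(x$map)[x$map == "*"], collapse = ",")))
  invisible(x)
}

#' Read a genetic code from a text file
#'
#' The format mirrors NCBI translation-table notation: a line `id = <label>`
#' followed by `AAs = <64 one-letter amino acids>` in TTT..GGG codon order
#' (stops as `*`), and optionally `Starts = <codon list>`.
#'
#' @param path File path.
#' @return A `genetic_code` object.
#' @export
read_genetic_code <- function(path) {
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  kv <- strsplit(lines, "\\s*=\\s*")
  vals <- stats::setNames(vapply(kv, `[`, character(1), 2),
                          tolower(vapply(kv, `[`, character(1), 1)))
  aas <- gsub("\\s", "", vals[["aas"]])
  if (nchar(aas) != 64L) stop("AAs line must contain 64 letters")
  ## NCBI order: first base slowest over T,C,A,G
  ncbi <- c("U", "C", "A", "G")
  codons <- apply(expand.grid(ncbi, ncbi, ncbi)[, 3:1], 1, paste0,
                  collapse = "")
  map <- stats::setNames(seq_chars(aas), codons)
  starts <- if (!is.na(vals["starts"])) {
    dna_to_rna(strsplit(gsub("\\s", "", vals[["starts"]]), ",")[[1]])
  } else c("AUG", "GUG")
  new_genetic_code(vals[["id"]] %||% "custom", map[ALL_CODONS], starts)
}

#' Codon families of a genetic code
#'
#' A codon family is the set of synonymous codons within one codon box
#' (identical first two bases) under the code in force: a box whose four
#' codons encode one amino acid is a four-fold family; otherwise codons of
#' the box are grouped by amino acid, giving NNY/NNR pairs, three-codon
#' families (e.g. AUH Ile where AUA is Ile), or singletons.  Stops are
#' excluded, so every sense codon belongs to exactly one family.
#'
#' @param code A [genetic_code()].
#' @return A list of `codon_family` objects: `aa`, `codons`, `box`,
#'   `degeneracy`.
#' @export
codon_families <- function(code) {
  fams <- list()
  boxes <- unique(substr(ALL_CODONS, 1, 2))
  for (box in boxes) {
    codons <- ALL_CODONS[substr(ALL_CODONS, 1, 2) == box]
    aas <- code$map[codons]
    sense <- codons[aas != "*"]
    if (length(sense) == 0L) next
    for (aa in unique(code$map[sense])) {
      members <- sense[code$map[sense] == aa]
      fams[[length(fams) + 1L]] <- structure(
        list(aa = aa, codons = members, box = box,
             degeneracy = length(members)),
        class = "codon_family")
    }
  }
  fams
}

## Wobble base of the anticodon with highest versatility for a family,
## determined by the family's third-position content:
##   * third positions all purine (NNR, including singleton NNA/NNG): U,
##     which wobble-pairs with both A and G;
##   * all pyrimidine (NNY or singleton): G, pairing with U and C;
##   * four-fold boxes: U;
##   * three-codon {U,C,A} families (e.g. AUH Ile): G -- the pyrimidines are
##     read by wobble and the A-ending codon by residual mechanisms, the
##     arrangement observed for tRNA-Ile across deuterostomes.
versatile_wobble <- function(third) {
  if (all(third %in% c("A", "G"))) return("U")
  if (all(third %in% c("C", "U"))) return("G")
  if (length(third) == 4L) return("U")
  if (all(third %in% c("C", "U", "A"))) return("G")
  NA_character_
}

#' Anticodon of highest versatility for a codon family
#'
#' Applies the GNN-for-NNY / UNN-for-NNR / UNN-for-four-fold scheme: the
#' anticodon (5'→3') is the wobble base followed by the reverse complement
#' of the family's first two codon bases.  Singleton families are served by
#' the same wobble rule (U for an A/G-ending codon, G for a U/C-ending one)
#' and flagged via the `"singleton"` attribute.
#'
#' @param family A `codon_family` from [codon_families()].
#' @return Anticodon string (RNA, 5'→3'), with attributes `wobble` and
#'   `singleton`.
#' @export
versatile_anticodon <- function(family) {
  third <- substr(family$codons, 3, 3)
  wb <- versatile_wobble(third)
  if (is.na(wb)) {
    stop("no versatile anticodon defined for third positions {",
         paste(sort(unique(third)), collapse = ","), "}")
  }
  ac <- paste0(wb, revcomp_rna(family$box))
  attr(ac, "wobble") <- wb
  attr(ac, "singleton") <- family$degeneracy == 1L
  ac
}

## The codon exactly complementary to an anticodon (both 5'->3').
anticodon_to_codon <- function(anticodon) revcomp_rna(anticodon)

#' Translate a codon vector
#'
#' @param codons Character vector of RNA or DNA codons.
#' @param code A [genetic_code()].
#' @return One-letter amino-acid vector (`"*"` for stops).
#' @export
translate_codons <- function(codons, code) {
  aa <- code$map[dna_to_rna(codons)]
  if (anyNA(aa)) stop("invalid codon(s): ",
                      paste(unique(codons[is.na(aa)]), collapse = ", "))
  unname(aa)
}
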