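## Seeded synthetic mitogenome generator.
##
## The generator emits an annotated circular genome whose stated world
## mirrors a strongly strand-biased metazoan mitogenome: a ~15 kb circle
## with 13 CDS / 2 rRNA / 22 tRNA features all on the main strand, a
## T- and G-rich main-strand composition (T 48%, G 23%, A 18%, C 11% by
## default), a piecewise-linear bias gradient running from a light-strand
## origin (weakest bias) to a heavy-strand origin (strongest bias), codon
## usage drawn amino-acid-first under a chosen genetic code, optional
## planted homopolymer runs in intergenic gaps, and a truth record for
## parameter-recovery tests.  All randomness flows from a single seed; the
## global RNG state is restored on exit.

TRNA_NAMES <- paste0("trn", c("A", "C", "D", "E", "F", "G", "H", "I", "K",
                              "L1", "L2", "M", "N", "P", "Q", "R", "S1",
                              "S2", "T", "V", "W", "Y"))

#' Default gene layout of the generator
#'
#' Thirteen CDS, two rRNAs and 22 tRNAs on one strand, ordered so that the
#' heavy-strand origin falls at the end of ND2 and the light-strand origin
#' between ND5 and CYTB, with the longest intergenic gap (24 bp) between
#' ATP6 and ND6.
#'
#' @return Data frame with columns `name`, `kind`, `length`, `strand`,
#'   `incomplete`, `spacer_after`.
#' @export
default_layout <- function() {
  g <- function(name, kind, length, spacer = 2L, incomplete = FALSE) {
    data.frame(name = name, kind = kind, length = length, strand = "main",
               incomplete = incomplete, spacer_after = spacer,
               stringsAsFactors = FALSE)
  }
  rbind(
    g("COX1", "CDS", 1536L),
    g("trnD", "tRNA", 68L),
    g("rrnS", "rRNA", 842L),
    g("trnV", "tRNA", 68L),
    g("rrnL", "rRNA", 1342L, spacer = 16L),
    g("trnL1", "tRNA", 68L),
    g("COX2", "CDS", 684L),
    g("trnK", "tRNA", 68L),
    g("ATP8", "CDS", 165L),
    g("ATP6", "CDS", 681L, spacer = 24L),
    g("ND6", "CDS", 498L),
    g("trnE", "tRNA", 68L),
    g("ND1", "CDS", 948L),
    g("trnQ", "tRNA", 68L),
    g("ND2", "CDS", 1038L),
    g("trnM", "tRNA", 68L),
    g("trnI", "tRNA", 68L),
    g("COX3", "CDS", 781L, incomplete = TRUE),
    g("trnG", "tRNA", 68L),
    g("ND3", "CDS", 351L),
    g("trnR", "tRNA", 68L),
    g("ND4L", "CDS", 294L),
    g("ND4", "CDS", 1375L, incomplete = TRUE),
    g("trnH", "tRNA", 68L),
    g("trnS1", "tRNA", 68L, spacer = 18L),
    g("ND5", "CDS", 1716L),
    g("trnF", "tRNA", 68L),
    g("trnP", "tRNA", 68L),
    g("trnT", "tRNA", 68L),
    g("CYTB", "CDS", 1137L),
    g("trnW", "tRNA", 68L),
    g("trnA", "tRNA", 68L),
    g("trnC", "tRNA", 68L),
    g("trnL2", "tRNA", 68L),
    g("trnN", "tRNA", 68L),
    g("trnS2", "tRNA", 68L),
    g("trnY", "tRNA", 68L, spacer = 12L))
}

#' Simulation parameters
#'
#' Presets state three worlds: `"rhabdopleura"` (GT-rich main strand,
#' T .48 / G .23 / A .18 / C .11, the Rhabdopleura-style code with AGG as
#' Lys, gradient amplitude 0.5), `"vertebrate"` (AC-rich main strand,
#' A .31 / C .31 / G .13 / T .25, vertebrate mitochondrial code, amplitude
#' 0.3) and `"unbiased"` (uniform composition, invertebrate code, amplitude
#' 0).  Any field can be overridden.
#'
#' @param preset One of `"rhabdopleura"`, `"vertebrate"`, `"unbiased"`.
#' @param layout Gene layout data frame (see [default_layout()]); the
#'   `spacer_after` column gives the intergenic gap following each gene.
#' @param composition Named main-strand base probabilities
#'   (`A`,`C`,`G`,`T`), summing to 1.
#' @param code_id Genetic code for CDS sampling (see [genetic_code()]).
#' @param amplitude Gradient amplitude a in `[0, 1)`: G/T sampling weights
#'   are multiplied by `1 + a * d(p)` with `d` running linearly from -1 at
#'   `oriL` to +1 at `oriH` around the circle.
#' @param oriL,oriH Origin positions (0-based); defaults derived from the
#'   layout (between ND5 and CYTB, and at the end of ND2) when the layout
#'   contains those genes, otherwise the positions at 3/4 and 1/4 of the
#'   genome.
#' @param aa_freqs Optional named amino-acid frequencies for CDS sampling;
#'   default: implied by `composition` under `code_id`.
#' @param synonymous_bias Optional named third-position base weights
#'   (`A`,`C`,`G`,`U`); default: `composition`.
#' @param planted_runs List of `c(base, length, count)` homopolymer runs to
#'   plant in intergenic gaps.
#' @param seed Integer seed; the same seed yields a byte-identical genome.
#' @return A validated `sim_params` object.
#' @export
sim_params <- function(preset = c("rhabdopleura", "vertebrate", "unbiased"),
                       layout = NULL, composition = NULL, code_id = NULL,
                       amplitude = NULL, oriL = NULL, oriH = NULL,
                       aa_freqs = NULL, synonymous_bias = NULL,
                       planted_runs = list(), seed = 1L) {
  preset <- match.arg(preset)
  defaults <- switch(preset,
    rhabdopleura = list(
      composition = c(A = 0.18, C = 0.11, G = 0.23, T = 0.48),
      code_id = "rhabdopleura", amplitude = 0.5),
    vertebrate = list(
      composition = c(A = 0.31, C = 0.31, G = 0.13, T = 0.25),
      code_id = "2", amplitude = 0.3),
    unbiased = list(
      composition = c(A = 0.25, C = 0.25, G = 0.25, T = 0.25),
      code_id = "5", amplitude = 0))
  layout <- layout %||% default_layout()
  composition <- composition %||% defaults$composition
  composition <- composition[DNA_BASES]
  if (anyNA(composition) || abs(sum(composition) - 1) > 1e-8) {
    stop("composition must be named probabilities over A,C,G,T summing to 1")
  }
  code_id <- code_id %||% defaults$code_id
  amplitude <- amplitude %||% defaults$amplitude
  if (amplitude < 0 || amplitude >= 1) stop("amplitude must be in [0, 1)")
  stopifnot(all(c("name", "kind", "length", "strand", "spacer_after")
                %in% names(layout)))
  if (is.null(layout$incomplete)) layout$incomplete <- FALSE
  bad <- layout$kind == "CDS" &
    ifelse(layout$incomplete, layout$length %% 3L == 0L,
           layout$length %% 3L != 0L)
  if (any(bad)) {
    stop("CDS length must be 0 mod 3 (or 1-2 mod 3 when incomplete): ",
         paste(layout$name[bad], collapse = ", "))
  }
  pos <- layout_positions(layout)
  n <- pos$genome_length
  if (is.null(oriL) || is.null(oriH)) {
    if (all(c("ND5", "CYTB", "ND2") %in% layout$name)) {
      nd5_end <- pos$end[layout$name == "ND5"]
      cytb_start <- pos$start[layout$name == "CYTB"]
      oriL <- oriL %||% floor((nd5_end + cytb_start) / 2)
      oriH <- oriH %||% pos$end[layout$name == "ND2"]
    } else {
      oriL <- oriL %||% floor(3 * n / 4)
      oriH <- oriH %||% floor(n / 4)
    }
  }
  for (r in planted_runs) {
    if (length(r) != 3L || !(r[[1]] %in% DNA_BASES)) {
      stop("planted_runs entries must be c(base, length, count)")
    }
  }
  structure(list(preset = preset, layout = layout,
                 composition = composition, code_id = code_id,
                 amplitude = amplitude,
                 oriL = as.integer(oriL) %% n, oriH = as.integer(oriH) %% n,
                 aa_freqs = aa_freqs, synonymous_bias = synonymous_bias,
                 planted_runs = planted_runs, seed = as.integer(seed)),
            class = "sim_params")
}

layout_positions <- function(layout) {
  step <- layout$length + layout$spacer_after
  start <- cumsum(c(0L, step[-nrow(layout)]))
  list(start = start, end = start + layout$length,
       genome_length = sum(step))
}

## Signed single-strandedness proxy: -1 at oriL, +1 at oriH, linear on both
## arcs of the circle.
gradient_d <- function(n, oriL, oriH) {
  p <- seq_len(n) - 1L
  arc_lh <- (oriH - oriL) %% n      # forward arc oriL -> oriH
  arc_hl <- n - arc_lh
  from_l <- (p - oriL) %% n
  ifelse(from_l <= arc_lh,
         -1 + 2 * from_l / arc_lh,
         1 - 2 * (from_l - arc_lh) / arc_hl)
}

## Vectorised base sampling with per-position G/T weight multiplier g.
sample_biased_bases <- function(g, composition) {
  n <- length(g)
  w <- matrix(rep(composition, each = n), nrow = n,
              dimnames = list(NULL, DNA_BASES))
  w[, "G"] <- w[, "G"] * g
  w[, "T"] <- w[, "T"] * g
  w <- w / rowSums(w)
  u <- stats::runif(n)
  idx <- 1L + (u > w[, 1]) + (u > w[, 1] + w[, 2]) +
    (u > w[, 1] + w[, 2] + w[, 3])
  DNA_BASES[idx]
}

## Baseline codon sampling weights (gradient-free): amino-acid-first, then
## synonymous codon by first/second-position composition and third-position
## bias.  Returns a named 64-vector summing to 1 over sense codons.
codon_base_weights <- function(code, composition, aa_freqs = NULL,
                               synonymous_bias = NULL) {
  comp_rna <- stats::setNames(composition[DNA_BASES], RNA_BASES)
  bias <- synonymous_bias %||% comp_rna
  bias <- bias[RNA_BASES]
  if (anyNA(bias)) stop("synonymous_bias must be named over A,C,G,U")
  b1 <- comp_rna[substr(ALL_CODONS, 1, 1)]
  b2 <- comp_rna[substr(ALL_CODONS, 2, 2)]
  b3 <- bias[substr(ALL_CODONS, 3, 3)]
  w <- stats::setNames(as.numeric(b1 * b2 * b3), ALL_CODONS)
  w[code$map == "*"] <- 0
  if (!is.null(aa_freqs)) {
    names(aa_freqs) <- aa_one_letter(names(aa_freqs))
    w_aa <- tapply(w, code$map, sum)
    target <- stats::setNames(rep(0, length(w_aa)), names(w_aa))
    target[names(aa_freqs)] <- aa_freqs
    scale <- ifelse(w_aa > 0, target / w_aa, 0)
    w <- w * scale[code$map]
  }
  if (sum(w) <= 0) stop("no sense codon has positive sampling weight")
  w / sum(w)
}

#' Sample a codon string under a genetic code
#'
#' Codons are drawn amino-acid-first (from `aa_freqs`, by default the
#' frequencies implied by `composition`) and then by synonymous-codon bias
#' on the third position; a terminal stop codon is appended.
#'
#' @param protein_length Number of sense codons to draw.
#' @param code A [genetic_code()].
#' @param aa_freqs Optional named amino-acid frequencies.
#' @param synonymous_bias Optional named third-position weights
#'   (`A`,`C`,`G`,`U`).
#' @param composition Main-strand base probabilities used for the defaults.
#' @return Character vector of RNA codons of length `protein_length + 1`
#'   (terminal stop included).
#' @export
sample_codons <- function(protein_length, code, aa_freqs = NULL,
                          synonymous_bias = NULL,
                          composition = c(A = 0.25, C = 0.25,
                                          G = 0.25, T = 0.25)) {
  if (!is.null(aa_freqs)) {
    names(aa_freqs) <- aa_one_letter(names(aa_freqs))
    missing_aa <- setdiff(names(aa_freqs)[aa_freqs > 0],
                          unique(code$map[code$map != "*"]))
    if (length(missing_aa) > 0L) {
      stop("amino acid(s) with no codon in code ", code$id, ": ",
           paste(missing_aa, collapse = ", "))
    }
  }
  w <- codon_base_weights(code, composition, aa_freqs, synonymous_bias)
  body <- sample(ALL_CODONS, protein_length, replace = TRUE, prob = w)
  stops <- names(code$map)[code$map == "*"]
  comp_rna <- stats::setNames(composition[DNA_BASES], RNA_BASES)
  stop_w <- comp_rna[substr(stops, 3, 3)]
  c(body, sample(stops, 1L, prob = stop_w))
}

## CDS sampling with the origin gradient applied: each codon's weight is
## additionally multiplied by g^(number of G/U bases in the codon), g taken
## at the codon midpoint.
sample_cds <- function(n_codons, code, w_base, g_codon, starts) {
  n_gu <- vapply(strsplit(ALL_CODONS, ""),
                 function(ch) sum(ch %in% c("G", "U")), numeric(1))
  start_w <- w_base[starts]
  if (sum(start_w) <= 0) start_w <- rep(1, length(starts))
  codons <- character(n_codons)
  codons[1] <- sample(starts, 1L, prob = start_w)
  if (n_codons > 1L) {
    for (i in seq.int(2L, n_codons)) {
      w <- w_base * g_codon[i]^n_gu
      codons[i] <- sample(ALL_CODONS, 1L, prob = w)
    }
  }
  codons
}

#' Generate an annotated synthetic mitogenome
#'
#' Deterministic given `params$seed`.  CDS regions are codon strings
#' sampled amino-acid-first under the chosen genetic code (never containing
#' internal stops; genes flagged incomplete end in a bare `T` instead of a
#' full stop); rRNA, tRNA and intergenic regions are drawn base by base
#' from the composition; both region types have their G/T sampling weights
#' multiplied by `1 + amplitude * d(p)` around the two origins; planted
#' homopolymer runs are written into intergenic gaps after sampling.
#'
#' @param params A [sim_params()] object.
#' @return A list with `genome` (an [annotated_genome()]) and `truth` (the
#'   generation record: origins, composition, codon sampling weights,
#'   planted-run registry, code id, seed).
#' @export
generate_genome <- function(params) {
  stopifnot(inherits(params, "sim_params"))
  layout <- params$layout
  pos <- layout_positions(layout)
  ## plant feasibility is checked before any sampling
  gaps <- data.frame(start = pos$end, length = layout$spacer_after)
  gaps <- gaps[gaps$length > 0, , drop = FALSE]
  planted <- plan_runs(params$planted_runs, gaps)
  ## the caller's RNG stream is left untouched
  withr::with_seed(params$seed,
                   generate_genome_impl(params, layout, pos, planted))
}

generate_genome_impl <- function(params, layout, pos, planted) {
  n <- pos$genome_length
  code <- genetic_code(params$code_id)
  d <- if (params$amplitude > 0) gradient_d(n, params$oriL, params$oriH)
       else numeric(n)
  g <- 1 + params$amplitude * d
  comp_rna <- stats::setNames(params$composition[DNA_BASES], RNA_BASES)
  ## In the default path the per-position weights feeding the codon sampler
  ## are calibrated so that the sense-codon marginal reproduces the target
  ## composition: conditioning on "no stop codons" otherwise depletes A
  ## (UAA/UAG carry a lot of it) by ~1% genome-wide.  Explicit aa_freqs or
  ## synonymous_bias state their own world and are used as given.
  if (is.null(params$aa_freqs) && is.null(params$synonymous_bias)) {
    comp_cds <- calibrate_sense_composition(code, params$composition)
    w_base <- codon_base_weights(code, comp_cds,
                                 synonymous_bias =
                                   stats::setNames(comp_cds[DNA_BASES],
                                                   RNA_BASES))
  } else {
    w_base <- codon_base_weights(code, params$composition, params$aa_freqs,
                                 params$synonymous_bias)
  }
  stops <- names(code$map)[code$map == "*"]

  seq_ch <- character(n)
  features <- vector("list", nrow(layout))
  for (i in seq_len(nrow(layout))) {
    s <- pos$start[i]; e <- pos$end[i]
    idx <- seq.int(s + 1L, e)
    if (layout$kind[i] == "CDS") {
      len <- layout$length[i]
      n_cod <- len %/% 3L
      mids <- s + 3L * seq_len(n_cod) - 1L
      g_codon <- g[(mids %% n) + 1L]
      body <- sample_cds(n_cod, code, w_base, g_codon,
                         intersect(code$starts, ALL_CODONS))
      if (layout$incomplete[i]) {
        cds_seq <- paste0(paste(rna_to_dna(body), collapse = ""),
                          strrep("T", len %% 3L))
      } else {
        term <- sample(stops, 1L, prob = comp_rna[substr(stops, 3, 3)])
        cds_seq <- paste(rna_to_dna(c(body[-n_cod], term)), collapse = "")
      }
      seq_ch[idx] <- seq_chars(cds_seq)
    } else {
      seq_ch[idx] <- sample_biased_bases(g[idx], params$composition)
    }
    features[[i]] <- gene_feature(layout$name[i], layout$kind[i],
                                  layout$strand[i], c(s, e))
    if (layout$spacer_after[i] > 0L) {
      sp <- seq.int(e + 1L, e + layout$spacer_after[i])
      sp_idx <- ((sp - 1L) %% n) + 1L
      seq_ch[sp_idx] <- sample_biased_bases(g[sp_idx], params$composition)
    }
  }
  ## write planted runs into their intergenic gaps
  if (nrow(planted) > 0L) {
    for (k in seq_len(nrow(planted))) {
      at <- seq.int(planted$start[k] + 1L,
                    planted$start[k] + planted$length[k])
      seq_ch[((at - 1L) %% n) + 1L] <- planted$base[k]
    }
  }
  genome <- annotated_genome(
    sprintf("SYN_%s_seed%d", params$preset, params$seed),
    paste(seq_ch, collapse = ""), circular = TRUE, features = features)
  truth <- list(seed = params$seed, preset = params$preset,
                genome_length = n, composition = params$composition,
                amplitude = params$amplitude,
                oriL = params$oriL, oriH = params$oriH,
                code_id = params$code_id, codon_probs = w_base,
                planted_runs = planted,
                realized_counts = base_counts(genome$sequence))
  list(genome = genome, truth = truth)
}

## Fixed-point adjustment of a base-probability vector q such that the
## marginal base composition of codons drawn with weight q(c1)q(c2)q(c3)
## over the sense codons of `code` equals `target`.
calibrate_sense_composition <- function(code, target, iters = 80L) {
  sense <- names(code$map)[code$map != "*"]
  pos_base <- lapply(1:3, function(i) rna_to_dna(substr(sense, i, i)))
  q <- target
  for (it in seq_len(iters)) {
    w <- q[pos_base[[1]]] * q[pos_base[[2]]] * q[pos_base[[3]]]
    w <- w / sum(w)
    m <- stats::setNames(numeric(4), DNA_BASES)
    for (i in 1:3) {
      tab <- tapply(w, pos_base[[i]], sum)
      m[names(tab)] <- m[names(tab)] + tab / 3
    }
    q <- q * target / pmax(m, 1e-12)
    q <- q / sum(q)
  }
  q
}

## Assign planted runs to intergenic gaps (first fit, longest runs first);
## errors before any sampling when they cannot all be placed.
plan_runs <- function(planted_runs, gaps) {
  out <- data.frame(base = character(0), length = integer(0),
                    start = integer(0))
  if (length(planted_runs) == 0L) return(out)
  want <- do.call(rbind, lapply(planted_runs, function(r) {
    data.frame(base = r[[1]], length = as.integer(r[[2]]),
               count = as.integer(r[[3]]))
  }))
  want <- want[rep(seq_len(nrow(want)), want$count), c("base", "length")]
  want <- want[order(-want$length), , drop = FALSE]
  free <- gaps
  for (k in seq_len(nrow(want))) {
    fit <- which(free$length >= want$length[k])
    if (length(fit) == 0L) {
      stop("layout overflow: planted run of ", want$length[k],
           " bases does not fit in any remaining intergenic gap")
    }
    j <- fit[1]
    out <- rbind(out, data.frame(base = want$base[k],
                                 length = want$length[k],
                                 start = free$start[j]))
    free$start[j] <- free$start[j] + want$length[k]
    free$length[j] <- free$length[j] - want$length[k]
  }
  out
}

#' Simulate reference protein alignments for a synthetic genome
#'
#' Builds one gapless alignment per CDS: the target row is the translation
#' of the gene under `code`; each of `n_taxa` reference rows keeps the
#' target residue with probability `conservation` (a single value or a
#' range to sample per column) and otherwise substitutes a uniformly random
#' different amino acid.  This emulates the conserved-column structure that
#' conservation-based code inference relies on.
#'
#' @param genome An [annotated_genome()].
#' @param code The [genetic_code()] the genome was generated under.
#' @param n_taxa Number of reference rows (default 56).
#' @param conservation Per-column probability that a reference row retains
#'   the target residue; length-2 numeric = uniform range.
#' @param seed Integer seed.
#' @return Named list of [reference_alignment()] objects, one per CDS.
#' @export
simulate_reference_alignments <- function(genome, code, n_taxa = 56L,
                                          conservation = 0.85, seed = 1L) {
  withr::with_seed(seed,
                   simulate_reference_alignments_impl(genome, code, n_taxa,
                                                      conservation))
}

simulate_reference_alignments_impl <- function(genome, code, n_taxa,
                                               conservation) {
  aas <- setdiff(unique(unname(code$map)), "*")
  out <- list()
  for (f in features_of_kind(genome, "CDS")) {
    s <- extract_feature_seq(genome, f)
    ncod <- nchar(s) %/% 3L
    codons <- substring(s, 3L * seq_len(ncod) - 2L, 3L * seq_len(ncod))
    aa <- translate_codons(codons, code)
    if (aa[length(aa)] == "*") aa <- aa[-length(aa)]
    L <- length(aa)
    cons <- if (length(conservation) == 2L) {
      stats::runif(L, conservation[1], conservation[2])
    } else rep(conservation, L)
    ref <- matrix("", nrow = n_taxa, ncol = L)
    for (j in seq_len(L)) {
      keep <- stats::runif(n_taxa) < cons[j]
      ref[, j] <- ifelse(keep, aa[j],
                         sample(setdiff(aas, aa[j]), n_taxa, replace = TRUE))
    }
    rows <- c(stats::setNames(paste(aa, collapse = ""), "target"),
              stats::setNames(apply(ref, 1L, paste, collapse = ""),
                              paste0("taxon", seq_len(n_taxa))))
    out[[f$name]] <- reference_alignment(f$name, rows, "target")
  }
  out
}
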