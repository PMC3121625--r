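## GenBank flat-file reading and writing.
##
## Only the parts of the format that annotated mitogenome records use are
## supported: a single record, LOCUS topology, CDS/tRNA/rRNA features with
## complement()/join() locations, /gene, /product and /codon_start
## qualifiers, and the ORIGIN sequence block.  None of the pre-installed
## Bioconductor packages parse GenBank flat files, so this is a deliberately
## small hand-written reader with a round-trip contract against
## write_genbank().

#' Read a single-record GenBank flat file
#'
#' @param path Path to a GenBank flat file containing exactly one record.
#' @return An [annotated_genome()]; GenBank 1-based inclusive locations are
#'   converted to 0-based half-open intervals, `complement(...)` locations to
#'   `strand = "opposite"`, and a `join` across the origin of a circular
#'   record to a single wrapping interval.
#' @export
read_genbank <- function(path) {
  lines <- readLines(path, warn = FALSE)
  locus_at <- grep("^LOCUS", lines)
  if (length(locus_at) == 0L) stop("not a GenBank flat file (no LOCUS line)")
  if (length(locus_at) > 1L) {
    stop("multi-record GenBank files are not supported (",
         length(locus_at), " LOCUS lines)")
  }
  locus <- strsplit(trimws(lines[locus_at]), "\\s+")[[1]]
  id <- locus[2]
  circular <- any(tolower(locus) == "circular")

  ## ORIGIN block
  ori_at <- grep("^ORIGIN", lines)
  if (length(ori_at) != 1L) stop("malformed record: expected one ORIGIN line")
  end_at <- grep("^//", lines)
  end_at <- if (length(end_at)) end_at[1] else length(lines) + 1L
  seq_lines <- lines[seq.int(ori_at + 1L, end_at - 1L)]
  sequence <- toupper(gsub("[0-9 ]", "", paste(seq_lines, collapse = "")))
  check_alphabet(sequence, paste0("sequence in ", path))

  ## FEATURES block: feature keys start at column 6, qualifiers at column 22
  feat_at <- grep("^FEATURES", lines)
  features <- list()
  if (length(feat_at) == 1L) {
    block <- lines[seq.int(feat_at + 1L, ori_at - 1L)]
    block <- block[!grepl("^[A-Z]", block)]  # stop at next top-level keyword
    is_key <- grepl("^ {5}\\S", block)
    idx <- cumsum(is_key)
    for (k in seq_len(max(c(idx, 0L)))) {
      chunk <- block[idx == k]
      header <- strsplit(trimws(chunk[1]), "\\s+")[[1]]
      key <- header[1]
      if (!key %in% GENE_KINDS) next
      ## location may continue over lines until the first qualifier
      qual_start <- grep("^ {21}/", chunk)
      loc_lines <- if (length(qual_start)) {
        chunk[seq_len(qual_start[1] - 1L)]
      } else chunk
      loc <- gsub("\\s+", "", paste(c(header[-1],
                                      trimws(loc_lines[-1])), collapse = ""))
      quals <- parse_qualifiers(chunk[grepl("^ {21}", chunk)])
      parsed <- parse_location(loc, nchar(sequence), circular,
                               where = paste0(path, " feature ", k))
      name <- quals[["gene"]] %||% quals[["product"]] %||%
        paste0(tolower(key), k)
      frame <- as.integer(quals[["codon_start"]] %||% "1") - 1L
      features[[length(features) + 1L]] <-
        gene_feature(name, key, parsed$strand, parsed$intervals, frame)
    }
  }
  annotated_genome(id, sequence, circular, features)
}

parse_qualifiers <- function(lines) {
  txt <- trimws(lines)
  out <- list()
  cur <- NULL
  for (l in txt) {
    if (startsWith(l, "/")) {
      kv <- sub("^/", "", l)
      eq <- regexpr("=", kv, fixed = TRUE)
      if (eq > 0) {
        cur <- substr(kv, 1L, eq - 1L)
        out[[cur]] <- gsub('"', "", substr(kv, eq + 1L, nchar(kv)))
      } else {
        cur <- kv
        out[[cur]] <- TRUE
      }
    } else if (!is.null(cur) && is.character(out[[cur]])) {
      out[[cur]] <- paste0(out[[cur]], gsub('"', "", l))
    }
  }
  out
}

parse_location <- function(loc, n, circular, where = "") {
  strand <- "main"
  if (grepl("^complement\\(", loc)) {
    strand <- "opposite"
    loc <- sub("^complement\\((.*)\\)$", "\\1", loc)
  }
  if (grepl("^(join|order)\\(", loc)) {
    loc <- sub("^(join|order)\\((.*)\\)$", "\\2", loc)
  }
  parts <- strsplit(loc, ",", fixed = TRUE)[[1]]
  iv <- t(vapply(parts, function(p) {
    p <- gsub("[<>]", "", p)
    if (grepl("^[0-9]+$", p)) {
      a <- as.numeric(p); b <- a
    } else if (grepl("^[0-9]+\\.\\.[0-9]+$", p)) {
      ab <- as.numeric(strsplit(p, "..", fixed = TRUE)[[1]])
      a <- ab[1]; b <- ab[2]
    } else {
      stop("parse error in ", where, ": unsupported location '", p, "'")
    }
    c(a - 1, b)  # 1-based inclusive -> 0-based half-open
  }, numeric(2)))
  colnames(iv) <- c("start", "end")
  ## merge a join across the circular origin into one wrapping interval
  if (circular && nrow(iv) >= 2L) {
    i <- 1L
    while (i < nrow(iv)) {
      if (iv[i, "end"] == n && iv[i + 1L, "start"] == 0) {
        iv[i, "end"] <- n + iv[i + 1L, "end"]
        iv <- iv[-(i + 1L), , drop = FALSE]
      } else i <- i + 1L
    }
  }
  list(strand = strand, intervals = iv)
}

format_location <- function(feature, n) {
  parts <- apply(feature$intervals, 1L, function(r) {
    s <- r[[1]]; e <- r[[2]]
    if (e > n) {
      c(sprintf("%d..%d", s + 1, n), sprintf("%d..%d", 1, e - n))
    } else {
      sprintf("%d..%d", s + 1, e)
    }
  })
  parts <- unlist(parts)
  loc <- if (length(parts) > 1L) {
    paste0("join(", paste(parts, collapse = ","), ")")
  } else parts
  if (feature$strand == "opposite") loc <- paste0("complement(", loc, ")")
  loc
}

#' Write a genome as a GenBank flat file
#'
#' Emits the subset of the format that [read_genbank()] parses, so
#' `read_genbank(write_genbank(g, f))` reproduces `g` exactly.
#'
#' @param genome An [annotated_genome()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_genbank <- function(genome, path) {
  n <- genome_length(genome)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("LOCUS       %s %d bp    DNA     %s   INV",
                     genome$id, n,
                     if (genome$circular) "circular" else "linear"), con)
  writeLines(sprintf("DEFINITION  %s mitochondrial genome.", genome$id), con)
  writeLines("FEATURES             Location/Qualifiers", con)
  writeLines(sprintf("     source          1..%d", n), con)
  for (f in genome$features) {
    writeLines(sprintf("     %-16s%s", f$kind, format_location(f, n)), con)
    writeLines(sprintf("                     /gene=\"%s\"", f$name), con)
    if (f$kind == "CDS" && f$frame_offset > 0L) {
      writeLines(sprintf("                     /codon_start=%d",
                         f$frame_offset + 1L), con)
    }
  }
  writeLines("ORIGIN", con)
  for (off in seq.int(0L, n - 1L, by = 60L)) {
    chunk <- substr(genome$sequence, off + 1L, min(off + 60L, n))
    tens <- substring(chunk, seq(1L, nchar(chunk), 10L),
                      pmin(seq(10L, nchar(chunk) + 9L, 10L), nchar(chunk)))
    writeLines(sprintf("%9d %s", off + 1L,
                       tolower(paste(tens, collapse = " "))), con)
  }
  writeLines("//", con)
  invisible(path)
}

#' Read a genome from a FASTA file (sequence only, no features)
#'
#' @param path FASTA file with a single sequence.
#' @param circular Assume circular topology (default `TRUE`).
#' @return An [annotated_genome()] with no features.
#' @export
read_fasta_genome <- function(path, circular = TRUE) {
  ss <- Biostrings::readDNAStringSet(path)
  if (length(ss) != 1L) stop("expected exactly one FASTA record, found ",
                             length(ss))
  annotated_genome(sub("\\s.*$", "", names(ss)[1]), as.character(ss[[1]]),
                   circular = circular)
}
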