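# Fixture builders shared across test files; everything is generated in
# code, nothing is downloaded.

# A compact gene layout (~1.7 kb) keeping the genes that origin defaults
# and region statistics rely on.
small_layout <- function(spacer = 4L) {
  data.frame(
    name = c("COX1", "trnD", "rrnS", "ND2", "trnK", "ND5", "CYTB", "trnY"),
    kind = c("CDS", "tRNA", "rRNA", "CDS", "tRNA", "CDS", "CDS", "tRNA"),
    length = c(300L, 68L, 150L, 240L, 68L, 300L, 240L, 68L),
    strand = "main",
    incomplete = FALSE,
    spacer_after = spacer,
    stringsAsFactors = FALSE)
}

small_sim <- function(seed = 1L, ...) {
  generate_genome(sim_params(layout = small_layout(), seed = seed, ...))
}

fixture_path <- function(name) {
  system.file("extdata", name, package = "mitoskew")
}

published_usage <- function(code = genetic_code("rhabdopleura")) {
  read_codon_usage(fixture_path("rhabdopleura_codon_usage.tsv"), code)
}

published_anticodons <- function() {
  read_anticodons(fixture_path("rhabdopleura_anticodons.tsv"))
}

# Hand-written GenBank record used by the parser tests.
toy_genbank_text <- function() {
  c("LOCUS       TOY01 20 bp    DNA     circular   INV",
    "DEFINITION  toy record.",
    "FEATURES             Location/Qualifiers",
    "     source          1..20",
    "     CDS             1..6",
    "                     /gene=\"ATP8\"",
    "     tRNA            complement(8..10)",
    "                     /gene=\"trnK\"",
    "     CDS             join(18..20,1..6)",
    "                     /gene=\"COX1\"",
    "ORIGIN",
    "        1 atgaaatagc cgtacgtacg",
    "//")
}

write_toy_genbank <- function(lines = toy_genbank_text()) {
  path <- withr::local_tempfile(fileext = ".gb",
                                .local_envir = parent.frame())
  writeLines(lines, path)
  path
}
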