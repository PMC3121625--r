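mk_aln <- function(gene, target, refs) {
  reference_alignment(gene, c(target = target,
                              stats::setNames(refs,
                                              paste0("t", seq_along(refs)))))
}

test_that("map_codon_sites tracks gaps and rejects frameshifts", {
  # gapless: codons 1..3 map to columns 1..3
  aln <- mk_aln("g", "MKV", c("MKV", "MRV"))
  expect_equal(map_codon_sites("ATGAAAGTT", aln), 1:3)
  # the CDS may carry a terminal stop codon absent from the protein row
  expect_equal(map_codon_sites("ATGAAAGTTTAA", aln), 1:3)
  # an internal gap column shifts downstream codons by one
  aln2 <- mk_aln("g", "M-KV", c("MAKV", "MGKV"))
  expect_equal(map_codon_sites("ATGAAAGTT", aln2), c(1, 3, 4))
  expect_error(map_codon_sites("ATGAAAGTTACTACT", aln), "frameshift")
})

test_that("grade_column bands by majority fraction and matches the oracle", {
  expect_equal(grade_column(rep("K", 10)), "highly_conserved")
  expect_equal(grade_column(c(rep("K", 63), rep("A", 37))),
               "weakly_conserved")   # f = 0.63
  expect_equal(grade_column(c(rep("K", 75), rep("A", 25))), "conserved")
  expect_equal(grade_column(c("K", "A", "V", "L")), "variable")
  expect_true(is.na(grade_column(c("-", "-"))))
  # gaps are removed before grading
  expect_equal(grade_column(c(rep("K", 9), "-")), "highly_conserved")

  set.seed(17)
  aas <- strsplit("ACDEFGHIKLMNPQRSTVWY-", "")[[1]]
  for (i in 1:200) {
    col <- sample(aas, sample(3:40, 1), replace = TRUE,
                  prob = c(rep(1, 20), 5))
    f <- oracle_majority_fraction(col)
    want <- if (is.na(f)) NA_character_
    else if (f >= 0.9) "highly_conserved"
    else if (f >= 0.7) "conserved"
    else if (f >= 0.5) "weakly_conserved"
    else "variable"
    expect_equal(grade_column(col), want)
  }
})

column_of <- function(freqs, n = 100) {
  # deterministic column with the requested residue fractions
  unlist(Map(function(aa, f) rep(aa, round(f * n)), names(freqs), freqs))
}

test_that("call_assignment calls, abstains and falls back as specified", {
  # 69% Lys at a weakly conserved site -> called Lys
  col <- column_of(c(K = .69, A = .11, V = .10, L = .10))
  tally <- conservation_tally(list(col), grade_column(col), "AAA")
  call <- call_assignment(tally)
  expect_equal(call$call, "K")
  expect_equal(call$degree, "weakly_conserved")
  expect_equal(call$support, 0.69)
  expect_equal(call$fallback, "none")

  # 46% Ser under the default 0.45 threshold -> called Ser
  col2 <- column_of(c(S = .46, A = .20, T = .18, G = .16))
  tally2 <- conservation_tally(list(col2), grade_column(col2), "UCC")
  expect_equal(call_assignment(tally2)$call, "S")

  # 27/24/23 split -> ambiguous; a donor code supplies Leu, flagged
  col3 <- column_of(c(I = .27, F = .24, L = .23, V = .26))
  tally3 <- conservation_tally(list(col3), grade_column(col3), "CUC")
  amb <- call_assignment(tally3)
  expect_equal(amb$call, "ambiguous")
  fb <- call_assignment(tally3, base_code = genetic_code("5"))
  expect_equal(fb$call, "L")
  expect_equal(fb$fallback, "base_code")

  # anticodon-complement fallback: AUC is read by tRNA-Ile/GAU
  tally4 <- conservation_tally(list(col3), grade_column(col3), "AUC")
  fb2 <- call_assignment(tally4, anticodons = anticodon_set("Ile", "GAU"))
  expect_equal(fb2$call, "I")
  expect_equal(fb2$fallback, "anticodon")

  # no sites: absent, never invented
  empty <- conservation_tally(list(), character(0), "CGG")
  expect_equal(call_assignment(empty)$call, "absent")
})

test_that("ties abstain and raising the threshold only retracts calls", {
  col <- column_of(c(K = .5, N = .5))
  tally <- conservation_tally(list(col), grade_column(col), "AAA")
  expect_equal(call_assignment(tally, 0.45)$call, "ambiguous")

  col2 <- column_of(c(K = .6, N = .4))
  tally2 <- conservation_tally(list(col2), grade_column(col2), "AAA")
  prev <- call_assignment(tally2, 0.05)$call
  for (thr in seq(0.1, 0.95, by = 0.05)) {
    cur <- call_assignment(tally2, thr)$call
    expect_true(cur == prev || cur == "ambiguous")
    if (cur == "ambiguous") prev <- "ambiguous" else prev <- cur
  }
})

test_that("infer_code recovers the generating code from faithful alignments", {
  for (seed in c(2, 3)) {
    sim <- generate_genome(sim_params(seed = seed))
    code <- genetic_code("rhabdopleura")
    alns <- simulate_reference_alignments(sim$genome, code, n_taxa = 30,
                                          conservation = 0.85, seed = seed)
    inf <- infer_code(sim$genome, alns, base_code = genetic_code("5"))
    well_sampled <- inf$calls$n_sites >= 5 & inf$calls$fallback == "none"
    expect_gt(sum(well_sampled), 40)
    expect_equal(unname(inf$code$map[inf$calls$codon[well_sampled]]),
                 unname(code$map[inf$calls$codon[well_sampled]]))
    # the planted reassignments are recovered as direct calls
    expect_equal(unname(inf$code$map["AGG"]), "K")
    expect_equal(unname(inf$code$map["AAA"]), "K")
  }
})

test_that("infer_code under an invertebrate-code genome calls AGG Ser and AUA Met", {
  sim <- generate_genome(sim_params(seed = 5, code_id = "5"))
  code5 <- genetic_code("5")
  alns <- simulate_reference_alignments(sim$genome, code5, n_taxa = 30,
                                        conservation = 0.85, seed = 5)
  inf <- infer_code(sim$genome, alns, base_code = genetic_code("2"))
  expect_equal(unname(inf$code$map["AGG"]), "S")
  expect_equal(unname(inf$code$map["AUA"]), "M")
})

test_that("absent codons are reported absent; missing genes are skipped", {
  g <- annotated_genome("TOY", paste0("ATGAAATAA", random_seq(21)), TRUE,
                        list(gene_feature("COX1", "CDS", "main", c(0, 9)),
                             gene_feature("ND1", "CDS", "main", c(12, 21))))
  aln <- mk_aln("COX1", "MK", c("MK", "MK", "MR"))
  expect_warning(inf <- infer_code(g, list(COX1 = aln)), "no reference")
  expect_equal(inf$calls$call[inf$calls$codon == "CGG"], "absent")
  expect_equal(inf$calls$n_sites[inf$calls$codon == "AAA"], 1L)
  # absent codons inherit the base code with a flag
  expect_equal(inf$calls$fallback[inf$calls$codon == "CGG"], "absent")
  expect_equal(unname(inf$code$map["CGG"]), "R")
})
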