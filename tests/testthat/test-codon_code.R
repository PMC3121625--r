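codes_under_test <- c("2", "5", "9", "13", "rhabdopleura")

test_that("built-in codes are complete and the expected variants", {
  for (id in codes_under_test) {
    code <- genetic_code(id)
    expect_equal(length(code$map), 64L)
    expect_gte(sum(code$map == "*"), 1L)
  }
  rh <- genetic_code("rhabdopleura")
  expect_equal(unname(rh$map[c("AUA", "AAA", "AGA", "AGG", "UGA")]),
               c("I", "K", "S", "K", "W"))
  expect_equal(unname(genetic_code("9")$map[c("AUA", "AAA", "AGA", "AGG")]),
               c("I", "N", "S", "S"))
  expect_equal(unname(genetic_code("2")$map[c("AUA", "AGA", "AGG")]),
               c("M", "*", "*"))
})

test_that("codon families partition the sense codons of every code", {
  for (id in codes_under_test) {
    code <- genetic_code(id)
    fams <- codon_families(code)
    claimed <- unlist(lapply(fams, `[[`, "codons"))
    sense <- names(code$map)[code$map != "*"]
    expect_setequal(claimed, sense)
    expect_equal(anyDuplicated(claimed), 0L)
    for (f in fams) {
      expect_true(all(code$map[f$codons] == f$aa))
    }
  }
})

test_that("versatile anticodons follow the GNN/UNN wobble scheme", {
  rh <- genetic_code("rhabdopleura")
  fams <- codon_families(rh)
  by_codons <- function(cods) {
    fams[[which(vapply(fams, function(f) setequal(f$codons, cods),
                       logical(1)))]]
  }
  expect_equal(as.character(versatile_anticodon(
    by_codons(c("UUU", "UUC")))), "GAA")              # Phe, NNY
  expect_equal(as.character(versatile_anticodon(
    by_codons(c("AAA", "AAG")))), "UUU")              # Lys, NNR
  expect_equal(as.character(versatile_anticodon(
    by_codons(c("GUU", "GUC", "GUA", "GUG")))), "UAC") # Val, four-fold
  # three-codon Ile family (AUA reassigned to Ile) keeps the GNN anticodon
  expect_equal(as.character(versatile_anticodon(
    by_codons(c("AUU", "AUC", "AUA")))), "GAU")
  # singleton families follow the wobble rule and carry a flag
  met <- by_codons("AUG")
  expect_equal(as.character(versatile_anticodon(met)), "UAU")
  expect_true(attr(versatile_anticodon(met), "singleton"))
})

test_that("codon usage counts complete in-frame codons including stops", {
  g <- annotated_genome("TOY", paste0("ATGTAA", random_seq(24)), TRUE,
                        list(gene_feature("X", "CDS", "main", c(0, 6))))
  u <- codon_usage(g, genetic_code("5"))
  expect_equal(unname(u$counts[c("AUG", "UAA")]), c(1L, 1L))
  expect_equal(sum(u$counts), 2L)
  expect_equal(u$incomplete_stops, 0L)
})

test_that("usage totals equal the per-CDS codon capacity; incomplete stops tallied", {
  for (seed in 1:3) {
    sim <- generate_genome(sim_params(seed = seed))
    g <- sim$genome
    u <- codon_usage(g, genetic_code("rhabdopleura"))
    capacity <- sum(vapply(features_of_kind(g, "CDS"), function(f) {
      nchar(extract_feature_seq(g, f)) %/% 3L
    }, numeric(1)))
    expect_equal(sum(u$counts), capacity)
    expect_equal(u$incomplete_stops, 2L)  # COX3 and ND4 in the layout
    # 13 genes minus 2 incomplete terminators leaves 11 full stops
    expect_equal(sum(u$counts[u$code$map == "*"]), 11L)
  }
})

test_that("an internal stop raises a warning but is still counted", {
  g <- annotated_genome("TOY", paste0("ATGTAAACTTAA", random_seq(24)), TRUE,
                        list(gene_feature("X", "CDS", "main", c(0, 12))))
  expect_warning(u <- codon_usage(g, genetic_code("5")), "internal stop")
  expect_equal(sum(u$counts), 4L)
})

test_that("aa_composition normalises over sense codons only", {
  code <- genetic_code("rhabdopleura")
  u <- mitoskew:::usage_from_counts(c(AUG = 1, AAA = 1, UAA = 5), code)
  comp <- aa_composition(u)
  expect_equal(unname(comp[c("K", "M")]), c(0.5, 0.5))
  expect_equal(sum(comp), 1, tolerance = 1e-12)
  set.seed(21)
  for (i in 1:5) {
    cnt <- stats::setNames(rpois(64, 20), mitoskew:::ALL_CODONS)
    comp <- aa_composition(mitoskew:::usage_from_counts(cnt, code))
    expect_equal(sum(comp), 1, tolerance = 1e-12)
  }
})

test_that("strandedness classification reproduces the exclusive sets", {
  code <- genetic_code("rhabdopleura")
  for (aa in c("Phe", "Gly", "Val", "Trp")) {
    expect_equal(classify_codon_strandedness(aa, code), "GT_exclusive")
  }
  for (aa in c("Thr", "Pro", "Asn", "His", "Gln")) {
    expect_equal(classify_codon_strandedness(aa, code), "AC_exclusive")
  }
  expect_equal(classify_codon_strandedness("Leu", code), "mixed")
  expect_equal(classify_codon_strandedness("Lys", code), "mixed") # AAR + AGG
  expect_error(classify_codon_strandedness("Xyz", code), "unknown")
  # the three labels cover every encoded amino acid
  aas <- setdiff(unique(unname(code$map)), "*")
  cls <- vapply(aas, classify_codon_strandedness, character(1), code = code)
  expect_true(all(cls %in% c("GT_exclusive", "AC_exclusive", "mixed")))
})

test_that("a GT-biased genome enriches the GT-exclusive amino acids", {
  code <- genetic_code("rhabdopleura")
  biased <- small_sim(seed = 6)$genome
  flat <- generate_genome(sim_params("unbiased", layout = small_layout(),
                                     seed = 6, code_id = "rhabdopleura"))
  f_b <- aa_composition(codon_usage(biased, code))
  f_u <- aa_composition(codon_usage(flat$genome, code))
  gt_set <- c("F", "G", "V", "W")
  expect_gt(sum(f_b[gt_set]), sum(f_u[gt_set], na.rm = TRUE))
})

test_that("the published tRNA set shows exactly three deviations", {
  code <- genetic_code("rhabdopleura")
  usage <- published_usage(code)
  pairing <- classify_pairing(published_anticodons(), code, usage)
  expect_equal(pairing$deviations, 3L)
  fam <- pairing$families
  dev <- fam[fam$classification != "versatile", ]
  # (i) tRNA-Met complements AUG; (ii) tRNA-Lys carries CUU, the complement
  # of AAG, not the versatile UUU; (iii) the reassigned AGG family has no
  # cognate tRNA
  expect_equal(dev$classification[dev$codons == "AUG"], "adapted")
  expect_equal(dev$classification[dev$codons == "AAA,AAG"], "adapted")
  expect_equal(dev$classification[dev$codons == "AGG"], "uncovered")
  expect_match(fam$note[fam$codons == "AGG"], "methylation")
})

test_that("echinoderm-style and fully versatile sets classify as expected", {
  ech <- genetic_code("9")
  vset <- versatile_anticodon_set(ech)
  # swap the four-fold AGN serine anticodon for the methylated GCU observed
  # in echinoderms; the singleton Lys family keeps the versatile UUU
  vset$anticodon[vset$aa == "S" & vset$anticodon == "UCU"] <- "GCU"
  vset$codon_recognized <- mitoskew:::anticodon_to_codon(vset$anticodon)
  usage <- mitoskew:::usage_from_counts(
    stats::setNames(rep(10, 64), mitoskew:::ALL_CODONS), ech)
  pairing <- classify_pairing(vset, ech, usage)
  fam <- pairing$families
  agn <- fam[grepl("AGA", fam$codons), ]
  expect_false(agn$classification == "versatile")
  expect_match(agn$note, "methylation")
  expect_equal(fam$classification[fam$codons == "AAG"], "versatile")

  # a fully versatile synthetic set has zero deviations
  inv <- genetic_code("5")
  pairing2 <- classify_pairing(versatile_anticodon_set(inv), inv,
                               mitoskew:::usage_from_counts(
                                 stats::setNames(rep(1, 64),
                                                 mitoskew:::ALL_CODONS),
                                 inv))
  expect_equal(pairing2$deviations, 0L)
})

test_that("orphan anticodons are rejected", {
  code <- genetic_code("rhabdopleura")
  usage <- published_usage(code)
  bad <- anticodon_set(c("Phe", "Lys"), c("GAA", "CCC"))
  expect_error(classify_pairing(bad, code, usage), "serving no codon family")
})

test_that("adaptation_test flags complements of the most frequent codons", {
  code <- genetic_code("rhabdopleura")
  usage <- published_usage(code)
  ad <- adaptation_test(published_anticodons(), usage)
  # Phe: anticodon GAA recognises UUC (35) while UUU dominates (554)
  expect_false(ad$adapted[ad$aa == "F"])
  # most families of a biased genome are NOT adapted
  expect_lt(mean(ad$adapted, na.rm = TRUE), 0.5)

  # UNN anticodon with an A-dominant family is adapted by construction
  cnt <- stats::setNames(integer(64), mitoskew:::ALL_CODONS)
  cnt[c("AAA", "AAG")] <- c(10L, 1L)
  u2 <- mitoskew:::usage_from_counts(cnt, code)
  ad2 <- adaptation_test(anticodon_set("Lys", "UUU"), u2)
  expect_true(ad2$adapted)

  # brute-force oracle on random usages
  set.seed(31)
  vset <- versatile_anticodon_set(code)
  for (i in 1:5) {
    cnt <- stats::setNames(rpois(64, 30), mitoskew:::ALL_CODONS)
    u3 <- mitoskew:::usage_from_counts(cnt, code)
    ad3 <- adaptation_test(vset, u3)
    for (j in seq_len(nrow(ad3))) {
      fam_codons <- strsplit(ad3$codons[j], ",")[[1]]
      rec <- ad3$recognized[j]
      expect_equal(ad3$adapted[j],
                   rec %in% fam_codons &&
                     cnt[[rec]] == max(cnt[fam_codons]))
    }
  }
})
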