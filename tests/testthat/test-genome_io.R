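test_that("GenBank coordinates, strands and wrapping joins are parsed", {
  g <- read_genbank(write_toy_genbank())
  expect_equal(genome_length(g), 20)
  expect_true(g$circular)
  expect_equal(length(g$features), 3L)

  atp8 <- get_feature(g, "ATP8")
  expect_equal(unname(atp8$intervals[1, ]), c(0, 6))

  trn <- get_feature(g, "trnK")
  expect_equal(trn$strand, "opposite")
  expect_equal(unname(trn$intervals[1, ]), c(7, 10))

  cox1 <- get_feature(g, "COX1")
  expect_equal(nrow(cox1$intervals), 1L)       # canonical wrapping interval
  expect_equal(unname(cox1$intervals[1, ]), c(17, 26))
  expect_equal(feature_length(cox1), 9)
  # manual splice of the two segments
  manual <- paste0(substr(g$sequence, 18, 20), substr(g$sequence, 1, 6))
  expect_equal(extract_feature_seq(g, cox1), manual)
})

test_that("malformed and multi-record files are rejected", {
  two <- c(toy_genbank_text(), toy_genbank_text())
  expect_error(read_genbank(write_toy_genbank(two)), "multi-record")

  bad <- toy_genbank_text()
  bad[12] <- "        1 atgaaatagc cgtwcgtacg"
  expect_error(read_genbank(write_toy_genbank(bad)), "A,C,G,T,N")

  noloc <- toy_genbank_text()[-1]
  expect_error(read_genbank(write_toy_genbank(noloc)), "LOCUS")
})

test_that("GenBank round-trip reproduces the parsed genome exactly", {
  sim <- small_sim(seed = 11)
  path <- withr::local_tempfile(fileext = ".gb")
  write_genbank(sim$genome, path)
  back <- read_genbank(path)
  expect_equal(back, sim$genome)

  # a wrapped, opposite-strand, frame-shifted feature survives the trip
  g2 <- annotated_genome("RT", random_seq(50), TRUE, list(
    gene_feature("ND9", "CDS", "opposite", c(45, 57), frame_offset = 1L)))
  path2 <- withr::local_tempfile(fileext = ".gb")
  write_genbank(g2, path2)
  expect_equal(read_genbank(path2), g2)
})

test_that("extract_feature_seq splices, orients and honours the frame", {
  g <- annotated_genome("TOY", "ACGTACGT", TRUE, list(
    gene_feature("X", "CDS", "main", matrix(c(6, 0, 8, 2), ncol = 2))))
  f <- g$features[[1]]
  expect_equal(extract_feature_seq(g, f), "GTAC")
  f$strand <- "opposite"
  expect_equal(extract_feature_seq(g, f), "GTAC")  # palindromic case

  set.seed(42)
  for (i in 1:10) {
    n <- sample(40:80, 1)
    gg <- annotated_genome("R", random_seq(n), TRUE)
    s <- sample(0:(n - 1), 1)
    len <- sample(3:20, 1)
    fwd <- gene_feature("F", "CDS", "main", c(s, s + len))
    rev <- gene_feature("F", "CDS", "opposite", c(s, s + len))
    expect_equal(extract_feature_seq(gg, rev),
                 revcomp(extract_feature_seq(gg, fwd)))
  }
})

test_that("frame_offset trims leading bases before the first codon", {
  g <- annotated_genome("TOY", "TTATGAAATAAC", FALSE, list(
    gene_feature("X", "CDS", "main", c(1, 10), frame_offset = 1L)))
  expect_equal(extract_feature_seq(g, g$features[[1]]), "ATGAAATA")
  expect_equal(extract_feature_seq(g, g$features[[1]], apply_frame = FALSE),
               "TATGAAATA")
})

test_that("unassigned_regions finds maximal uncovered intervals", {
  g <- annotated_genome("TOY", random_seq(10), TRUE, list(
    gene_feature("A", "CDS", "main", c(0, 4)),
    gene_feature("B", "tRNA", "main", c(6, 9))))
  uas <- unassigned_regions(g)
  expect_equal(uas$regions$start, c(4, 9))
  expect_equal(uas$regions$end, c(6, 10))
  expect_equal(uas$regions$length, c(2, 1))
  expect_equal(uas$regions$upstream, c("A", "B"))
  expect_equal(uas$regions$downstream, c("B", "A"))
  expect_equal(uas$fraction, 0.3)

  full <- annotated_genome("F", random_seq(100), TRUE, list(
    gene_feature("A", "rRNA", "main", c(0, 100))))
  expect_equal(nrow(unassigned_regions(full)$regions), 0L)
  expect_equal(unassigned_regions(full)$fraction, 0)
})

test_that("a gap spanning the origin is reported as one wrapped region", {
  g <- annotated_genome("TOY", random_seq(20), TRUE, list(
    gene_feature("A", "CDS", "main", c(5, 15))))
  uas <- unassigned_regions(g)
  expect_equal(nrow(uas$regions), 1L)
  expect_equal(uas$regions$start, 15)
  expect_equal(uas$regions$end, 25)   # wraps: covers 15..19 and 0..4
  expect_equal(uas$regions$length, 10)
})

test_that("UAS lengths and covered union always partition the genome", {
  for (seed in 1:5) {
    sim <- small_sim(seed = seed)
    g <- sim$genome
    uas <- unassigned_regions(g)
    covered <- sum(mitoskew:::coverage_mask(g, g$features))
    expect_equal(sum(uas$regions$length) + covered, genome_length(g))
  }
})

test_that("the default layout leaves its longest gap between ATP6 and ND6", {
  sim <- generate_genome(sim_params(seed = 3))
  uas <- unassigned_regions(sim$genome)
  top <- uas$regions[which.max(uas$regions$length), ]
  expect_equal(top$length, 24)
  expect_equal(top$upstream, "ATP6")
  expect_equal(top$downstream, "ND6")
  expect_lt(uas$fraction, 0.02)
})

test_that("main_strand and orient_main follow the CDS majority", {
  sim <- small_sim(seed = 5)
  g <- sim$genome
  expect_equal(main_strand(g), "main")
  expect_identical(orient_main(g), g)

  flipped <- annotated_genome(
    g$id, revcomp(g$sequence), TRUE,
    lapply(g$features, function(f) {
      n <- genome_length(g)
      iv <- t(apply(f$intervals, 1, function(r) {
        len <- r[[2]] - r[[1]]
        s <- (n - r[[2]]) %% n
        c(s, s + len)
      }))
      colnames(iv) <- c("start", "end")
      gene_feature(f$name, f$kind, "opposite", iv, f$frame_offset)
    }))
  expect_equal(main_strand(flipped), "opposite")
  back <- orient_main(flipped)
  expect_equal(back$sequence, g$sequence)
  expect_equal(main_strand(back), "main")
  expect_equal(extract_feature_seq(back, get_feature(back, "COX1")),
               extract_feature_seq(g, get_feature(g, "COX1")))
  expect_equal(main_strand(flipped, override = "main"), "main")
})
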