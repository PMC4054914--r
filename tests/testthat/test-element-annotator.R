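test_that("six-frame translation follows the codon table", {
  fr <- six_frame_translate("ATGGATGAC")
  expect_equal(fr[["f1"]], "MDD")
  expect_equal(nchar(fr[["f2"]]), (9 - 1) %/% 3)
  expect_equal(nchar(fr[["f3"]]), (9 - 2) %/% 3)
  ## minus frames equal forward translation of the reverse complement
  s <- "ATGGATGACTTTAAAGGG"
  fr <- six_frame_translate(s)
  fr_rc <- six_frame_translate(revcomp(s))
  expect_equal(fr[["f4"]], fr_rc[["f1"]])
})

test_that("TIR detector matches the brute-force oracle", {
  el <- default_element()
  expect_equal(detect_tirs(el$sequence)$tir_length, 33L)

  ## scrambled ends: no TIR
  scr <- paste0(generate_background_genome(200, 0.5, 5),
                substr(el$sequence, 101, 1400),
                generate_background_genome(200, 0.5, 6))
  expect_null(detect_tirs(scr))

  ## agreement with an independently-coded naive scorer on random elements
  set.seed(77)
  for (k in 1:100) {
    tl <- sample(12:60, 1)
    tir <- paste(sample(c("A", "C", "G", "T"), tl, replace = TRUE),
                 collapse = "")
    mid <- paste(sample(c("A", "C", "G", "T"), sample(50:200, 1),
                        replace = TRUE), collapse = "")
    e <- paste0(tir, mid, revcomp(tir))
    got <- detect_tirs(e)
    oracle <- brute_force_tir(e)
    expect_equal(got$tir_length, oracle$tir_length)
    expect_equal(got$mismatches, oracle$mismatches)
  }
})

test_that("longest-ORF finder agrees with codon-scan enumeration", {
  el <- default_element()
  orf <- find_longest_orf(el$sequence, both_strands = TRUE, min_aa = 100)
  expect_equal(nchar(orf$protein), 338L)
  expect_true(orf$intact)

  ## engineered internal stop shortens the ORF
  broken <- paste0(substr(el$sequence, 1, el$orf$start + 500),
                   "TAG",
                   substr(el$sequence, el$orf$start + 504,
                          nchar(el$sequence)))
  orf_b <- find_longest_orf(broken, both_strands = TRUE, min_aa = 50)
  expect_lt(nchar(orf_b$protein), 338L)

  ## random-sequence agreement with the enumeration oracle
  set.seed(42)
  for (k in 1:50) {
    s <- generate_background_genome(2000, runif(1, 0.3, 0.7), seed = k)
    got <- find_longest_orf(s, both_strands = TRUE, min_aa = 1)
    expect_equal(nchar(got$protein), brute_force_longest_orf(s))
  }
})

test_that("minus-strand ORFs are reported in plus coordinates", {
  el <- default_element()
  rc <- revcomp(el$sequence)
  orf <- find_longest_orf(rc, both_strands = TRUE, min_aa = 100)
  expect_equal(orf$strand, "-")
  expect_equal(nchar(orf$protein), 338L)
  n <- nchar(rc)
  expect_equal(orf$start, n - (el$orf$end) + 1L)
  expect_equal(orf$end, n - (el$orf$start) + 1L)
})

test_that("TSD verification distinguishes planted from shifted intervals", {
  sim <- small_sim()
  copy <- sim$truth[1, ]
  v <- verify_tsd(sim$genome, copy)
  expect_true(v$is_TA)
  shifted <- copy
  shifted$start <- copy$start + 5L
  expect_false(verify_tsd(sim$genome, shifted)$is_TA)
  edge <- copy
  edge$start <- 1L
  expect_error(verify_tsd(sim$genome, edge), "flank")
})

test_that("triad classification round-trips all spacing classes", {
  refs <- triad_reference_set()
  for (cl in c("DD34E", "DD34D", "DD35E", "DD37D", "DD37E", "DD39D")) {
    tp <- generate_transposase(338, cl, seed = 500)
    tri <- locate_triad(tp$protein, refs)
    expect_true(tri$complete)
    expect_equal(tri$class_label, cl)
    expect_equal(tri$spacing23, tp$spacing23)
  }
})

test_that("triad completeness handles fragments and mutations", {
  refs <- triad_reference_set()
  tp <- generate_transposase(338, "DD34E", seed = 501)
  expect_equal(triad_completeness(tp$protein, refs), "Y")
  ## fragment covering only D2..E: first D missing
  frag <- substr(tp$protein, tp$p2 - 10, 338)
  expect_equal(triad_completeness(frag, refs), "N")
  ## fragment covering all three residues
  frag2 <- substr(tp$protein, tp$p1 - 10, tp$p3 + 10)
  expect_equal(triad_completeness(frag2, refs), "Y")
  ## catalytic residue mutated to alanine
  mut <- tp$protein
  substr(mut, tp$p2, tp$p2) <- "A"
  expect_false(locate_triad(mut, refs)$complete)
})

test_that("CDS span arithmetic reproduces the published ORF length", {
  ## the archetypal moss TLE CDS spans 7,186-8,199 on its contig: 338 codons
  expect_equal(cds_span_codons(7186, 8199), 338L)
  ## minus-strand convention: start > end, same span length
  expect_equal(cds_span_codons(162826, 161813), 338L)
})
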