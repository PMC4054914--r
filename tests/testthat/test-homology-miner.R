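test_that("translated search finds every planted transposase locus", {
  sim <- small_sim()
  q <- sim$consensus$famA$triad$protein
  hits <- search_transposase(sim$genome, q)
  ## at least one hit inside each planted copy
  for (i in seq_len(nrow(sim$truth))) {
    inside <- hits$start >= sim$truth$start[i] &
      hits$end <= sim$truth$end[i]
    expect_true(any(inside))
  }
  ## every hit lies inside some planted copy
  for (j in seq_len(nrow(hits))) {
    expect_true(any(hits$start[j] >= sim$truth$start &
                      hits$end[j] <= sim$truth$end))
  }
})

test_that("background genomes yield no hits at the default threshold", {
  q <- small_sim()$consensus$famA$triad$protein
  for (s in 1:20) {
    bg <- generate_background_genome(8000, 0.5, seed = 900 + s)
    expect_equal(nrow(search_transposase(c(chr1 = bg), q)), 0L)
  }
})

test_that("seeded search equals exhaustive Smith-Waterman on small contigs", {
  sim <- small_sim()
  q <- sim$consensus$famA$triad$protein
  g <- sim$genome[["chr1"]]
  mat <- tlemine:::blosum62()
  for (i in c(1, 3, 5)) {
    ## a <= 5 kb contig containing one planted copy
    ctg <- substr(g, max(1, sim$truth$start[i] - 1500),
                  sim$truth$start[i] + 3500)
    hits <- search_transposase(c(c1 = ctg), q)
    expect_gte(nrow(hits), 1L)
    ## oracle: full local alignment of the query against each whole frame
    frames <- six_frame_translate(ctg)
    sw <- max(vapply(frames, function(p) {
      if (nchar(p) < 4) return(-Inf)
      Biostrings::pairwiseAlignment(
        Biostrings::AAString(q),
        Biostrings::AAString(gsub("*", "X", p, fixed = TRUE)),
        type = "local", substitutionMatrix = mat,
        gapOpening = 10, gapExtension = 1, scoreOnly = TRUE)
    }, numeric(1)))
    expect_equal(max(hits$score), sw)
  }
})

test_that("extension recovers exact element boundaries from a hit", {
  sim <- small_sim()
  q <- sim$consensus$famA$triad$protein
  hits <- search_transposase(sim$genome, q)
  cl <- tlemine:::cluster_hits(hits)
  for (i in seq_len(nrow(cl))) {
    el <- extend_to_element(sim$genome, cl[i, ],
                            left_bound = cl$left_bound[i],
                            right_bound = cl$right_bound[i])
    expect_false(is.null(el))
    j <- which(sim$truth$start == el$start)
    expect_length(j, 1L)
    expect_equal(el$end, sim$truth$end[j])
    expect_equal(el$tsd_left, "TA")
    expect_equal(el$tsd_right, "TA")
    expect_equal(el$terminal4_left, "CAGT")
  }
})

test_that("extension ignores regions without TA-flanked inverted repeats", {
  ## random sequence holds no 20-bp inverted repeat at 10% edit tolerance
  bg <- generate_background_genome(12000, 0.5, seed = 55)
  fake_hit <- data.frame(contig = "chr1", strand = "+",
                         start = 6000L, end = 6300L)
  expect_null(extend_to_element(c(chr1 = bg), fake_hit, min_tir = 20L))
})

test_that("nested TA-flanked IR pairs resolve to the best score, then outermost", {
  ## constructed case: an outer 20-bp perfect IR and an inner 14-bp perfect
  ## IR, both TA-flanked; the outer higher-scoring pair must win
  set.seed(8)
  outer_tir <- "GCAGCCTGACGGTCAGACCA"          # 20 bp, no TA inside
  inner_tir <- "CCGGACGTGCGTCC"                # 14 bp
  filler <- generate_background_genome(150, 0.5, seed = 12)
  core <- paste0(outer_tir, "GGGG", "TA", inner_tir, "GGGG",
                 substr(filler, 1, 60), "CCCC", revcomp(inner_tir), "TA",
                 "CCCC", revcomp(outer_tir))
  flank1 <- generate_background_genome(120, 0.5, seed = 13)
  flank2 <- generate_background_genome(120, 0.5, seed = 14)
  g <- paste0(flank1, "TA", core, "TA", flank2)
  start_true <- nchar(flank1) + 3L
  end_true <- start_true + nchar(core) - 1L
  hit <- data.frame(contig = "chr1", strand = "+",
                    start = start_true + 50L, end = end_true - 50L)
  el <- extend_to_element(c(chr1 = g), hit, min_tir = 12L)
  expect_equal(el$start, start_true)
  expect_equal(el$end, end_true)
})

test_that("member retrieval is exact-end anchored with zero tolerance", {
  sim <- small_sim()
  cons <- sim$consensus$famA$sequence
  ## clean copies (p_sub = 0) planted fresh
  g <- generate_background_genome(3e4, 0.5, seed = 61)
  copies <- rep(cons, 5)
  copies[2] <- revcomp(copies[2])  # minus-strand insertion
  planted <- plant_copies(g, copies, seed = 62)
  mem <- retrieve_members(c(chr1 = planted$genome), cons)
  expect_equal(nrow(mem), 5L)
  expect_setequal(mem$start, planted$truth$start)
  expect_setequal(mem$end, planted$truth$end)

  ## one substitution inside the terminal 33-mer: not retrieved
  damaged <- cons
  substr(damaged, 10, 10) <- if (substr(cons, 10, 10) == "A") "C" else "A"
  planted2 <- plant_copies(g, damaged, seed = 63)
  mem2 <- retrieve_members(c(chr1 = planted2$genome), cons)
  expect_equal(nrow(mem2), 0L)

  ## the exemplar retrieves itself
  one <- plant_copies(g, cons, seed = 64)
  self <- retrieve_members(c(chr1 = one$genome), cons)
  expect_equal(nrow(self), 1L)
  expect_equal(self$start, one$truth$start)
})

test_that("full-length flag requires intact termini and coverage", {
  cons <- default_element()$sequence
  undisturbed <- data.frame(seq = cons, stringsAsFactors = FALSE)
  truncated <- data.frame(seq = substr(cons, 1, round(0.6 * nchar(cons))),
                          stringsAsFactors = FALSE)
  both <- rbind(undisturbed, truncated)
  flagged <- flag_full_length(both, cons)
  expect_true(flagged$full_length[1])
  expect_false(flagged$full_length[2])
})
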