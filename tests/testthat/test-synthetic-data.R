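test_that("background genome respects length, composition and seed", {
  g <- generate_background_genome(10000, 0.5, seed = 1)
  expect_equal(nchar(g), 10000L)
  expect_true(all(chars(substr(g, 1, 500)) %in% c("A", "C", "G", "T")))

  at_only <- generate_background_genome(1000, 0, seed = 1)
  expect_true(all(chars(at_only) %in% c("A", "T")))

  expect_identical(generate_background_genome(1000, 0.5, seed = 7),
                   generate_background_genome(1000, 0.5, seed = 7))
  expect_error(generate_background_genome(0, 0.5, 1), "positive")
})

test_that("consensus element has designed structure", {
  el <- default_element()
  expect_equal(nchar(el$sequence), 1584L)
  expect_equal(substr(el$sequence, 1, 4), "CAGT")
  expect_equal(revcomp(substr(el$sequence, 1581, 1584)), "CAGT")
  ## TIR: first 33 bases are the reverse complement of the last 33
  expect_equal(substr(el$sequence, 1, 33),
               substr(revcomp(el$sequence), 1, 33))
  expect_equal(nchar(el$orf$protein), 338L)
  ## triad spacing encoded by the class: 34 residues between D2 and E
  expect_equal(el$triad$spacing23, 34L)
  expect_equal(substr(el$orf$protein, el$triad$p3, el$triad$p3), "E")
  ## ORF interval covers protein + stop codon
  expect_equal(el$orf$end - el$orf$start + 1L, 3L * 339L)
})

test_that("element too short for its ORF is rejected", {
  expect_error(family_spec("x", element_length = 900, protein_length = 338),
               "element_length")
})

test_that("mutate_copy matches its binomial substitution model", {
  el <- default_element()$sequence
  expect_identical(as.character(mutate_copy(el, 0, 0, seed = 3)), el)

  ## observed substitution counts over 200 seeds ~ Binomial(1584, 0.02)
  nsub <- vapply(1:200, function(s)
    attr(mutate_copy(el, 0.02, 0, seed = s), "n_sub"), integer(1))
  mu <- 1584 * 0.02
  sdm <- sqrt(1584 * 0.02 * 0.98) / sqrt(200)
  expect_lt(abs(mean(nsub) - mu), 3 * sdm)

  ## indels change length
  m <- mutate_copy(el, 0, 0.01, seed = 5)
  expect_true(nchar(m) != nchar(el))
  expect_gt(attr(m, "n_indel"), 0L)
})

test_that("divergence of mutated copies recovers the applied rate", {
  el <- default_element()$sequence
  divs <- vapply(1:200, function(s)
    copy_divergence(as.character(mutate_copy(el, 0.02, 0, seed = s)), el),
    numeric(1))
  se <- sd(divs) / sqrt(length(divs))
  expect_lt(abs(mean(divs) - 2.0), 3 * se)
})

test_that("plant_copies duplicates the TA target site", {
  g <- generate_background_genome(2e4, 0.5, seed = 9)
  el <- default_element()$sequence
  out <- plant_copies(g, el, seed = 2)
  expect_equal(nchar(out$genome), nchar(g) + 1584L + 2L)
  tr <- out$truth
  expect_equal(substr(out$genome, tr$start - 2, tr$start - 1), "TA")
  expect_equal(substr(out$genome, tr$end + 1, tr$end + 2), "TA")
  expect_equal(substr(out$genome, tr$start, tr$end), el)

  none <- plant_copies(g, character(0), seed = 2)
  expect_identical(none$genome, g)
  expect_equal(nrow(none$truth), 0L)
})

test_that("simulation is seed-deterministic and truth re-extracts copies", {
  sim <- small_sim()
  cfg <- sim_config(genome_length = 4e4, gc_content = 0.5,
                    families = list(family_spec("famA", n_copies = 8,
                                                p_sub = 0.01, p_indel = 0,
                                                frac_orf_disrupted = 0)),
                    seed = 101L)
  sim2 <- simulate_tle_genome(cfg)
  expect_identical(sim$genome, sim2$genome)
  expect_identical(sim$truth, sim2$truth)

  g <- sim$genome[["chr1"]]
  for (i in seq_len(nrow(sim$truth))) {
    expect_identical(substr(g, sim$truth$start[i], sim$truth$end[i]),
                     if (sim$truth$strand[i] == "+") sim$truth$seq[i]
                     else sim$truth$seq[i])
  }
  ## every planted copy passes TIR detection and TSD verification; the
  ## detected length is exact for mutation-free termini and within a few bp
  ## when a substitution clips the repeat end
  for (i in seq_len(nrow(sim$truth))) {
    tsd <- verify_tsd(sim$genome, sim$truth[i, ])
    expect_true(tsd$is_TA)
    tir <- detect_tirs(sim$truth$seq[i])
    expect_false(is.null(tir))
    expect_lte(abs(tir$tir_length - 33L), 3L)
  }
  ## and exactly the designed length on the mismatch-free consensus
  expect_equal(detect_tirs(sim$consensus$famA$sequence)$tir_length, 33L)
})

test_that("genome length accounting is exact across a full simulation", {
  sim <- small_sim()
  total_copy <- sum(nchar(sim$truth$seq))
  expect_equal(nchar(sim$genome[["chr1"]]),
               4e4 + total_copy + 2L * nrow(sim$truth))
})

test_that("written simulation fixture round-trips through FASTA/BED", {
  sim <- small_sim()
  dir <- withr::local_tempdir()
  write_simulation(sim, dir)
  g <- read_genome_fasta(file.path(dir, "genome.fa"))
  expect_identical(unname(g), unname(sim$genome))
  bed <- rtracklayer::import(file.path(dir, "truth.bed"))
  expect_equal(length(bed), nrow(sim$truth))
  expect_equal(GenomicRanges::start(bed), sim$truth$start)
  expect_equal(GenomicRanges::end(bed), sim$truth$end)
})
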