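test_that("the expression fixture has nine intact-ORF copies", {
  fx <- expr_fixture()
  expect_equal(sum(fx$sim$truth$has_intact_orf), 9L)
  expect_equal(sum(fx$tx$truth$has_full_cds), 9L)
})

test_that("transcripts map to their source copies with intron-aware blocks", {
  fx <- expr_fixture()
  members <- setNames(fx$sim$truth$seq, fx$sim$truth$copy_id)
  matches <- map_transcripts(fx$tx$transcripts, members)
  ## every transcript maps, to the right copy
  tt <- fx$tx$truth
  expect_setequal(matches$transcript_id, tt$transcript_id)
  m <- merge(matches, tt, by = "transcript_id")
  expect_true(all(m$copy_id.x == m$copy_id.y))
  expect_true(all(m$identity >= 99))
  ## spliced transcripts show intron-like internal gaps
  spliced <- m$transcript_id[m$spliced]
  if (length(spliced) > 0)
    expect_true(all(m$n_introns[m$transcript_id %in% spliced] >= 1))
  expect_true(all(m$n_introns[!m$spliced] == 0))
})

test_that("a transcript equal to the CDS maps as one perfect block", {
  fx <- expr_fixture()
  members <- setNames(fx$sim$truth$seq, fx$sim$truth$copy_id)
  intact_id <- fx$sim$truth$copy_id[fx$sim$truth$has_intact_orf][1]
  cons <- fx$sim$consensus$famE
  tx1 <- setNames(substr(members[[intact_id]], cons$orf$start,
                         cons$orf$end), "cds_tx")
  m <- map_transcripts(tx1, members)
  expect_equal(nrow(m), 1L)
  expect_equal(m$copy_id, intact_id)
  expect_equal(m$identity, 100)
  expect_equal(m$n_blocks, 1L)
  expect_equal(m$n_introns, 0L)

  ## unrelated sequence does not map
  rnd <- setNames(generate_background_genome(800, 0.5, 7), "noise_tx")
  expect_equal(nrow(map_transcripts(rnd, members)), 0L)
})

test_that("intact-transposase transcript counting equals the truth table", {
  fx <- expr_fixture()
  members <- setNames(fx$sim$truth$seq, fx$sim$truth$copy_id)
  matches <- map_transcripts(fx$tx$transcripts, members)
  res <- count_intact_transposase_transcripts(matches, fx$tx$transcripts,
                                              family_orf_aa = 338)
  expect_equal(res$count, 9L)
  expect_setequal(res$transcript_ids,
                  fx$tx$truth$transcript_id[fx$tx$truth$has_full_cds])
  ## each intact transcript comes from a distinct copy
  expect_equal(length(res$source_copies), 9L)

  ## invariant to duplicated transcript records and input order
  dup <- c(fx$tx$transcripts, fx$tx$transcripts)
  m2 <- map_transcripts(dup[sample(length(dup))], members)
  r2 <- count_intact_transposase_transcripts(m2, fx$tx$transcripts, 338)
  expect_equal(r2$count, 9L)
})

test_that("small-RNA matching counts exact and near matches only", {
  fx <- expr_fixture()
  ## the no-silencing scenario: zero matching reads
  silent <- make_small_rnas(fx$cds, n_matching = 0, n_random = 30,
                            seed = 601)
  expect_equal(nrow(match_small_rnas(silent, fx$cds)), 0L)

  ## positive control: planted matching reads are found
  act <- make_small_rnas(fx$cds, n_matching = 5, n_random = 30, seed = 602)
  hits <- match_small_rnas(act, fx$cds)
  expect_gte(length(unique(hits$read_id)), 5L)

  ## an exact 21-mer maps at its exact offset
  probe <- setNames(substr(fx$cds, 101, 121), "probe")
  h <- match_small_rnas(probe, fx$cds, max_mismatch = 0)
  expect_equal(h$start, 101L)
  expect_equal(h$strand, "+")

  ## three mismatches exceed the default tolerance of two
  bad <- probe
  substr(bad, 1, 3) <- paste(rev(chars(chartr("ACGT", "TGCA",
                                              substr(bad, 1, 3)))),
                             collapse = "")
  bad2 <- chartr("ACGT", "CATG", probe)  # heavily mutated read
  expect_equal(nrow(match_small_rnas(setNames(bad2, "x"), fx$cds,
                                     max_mismatch = 2)), 0L)
})
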