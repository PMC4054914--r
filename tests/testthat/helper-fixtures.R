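## Shared fixtures, built once per test run and memoized.

.fixture_cache <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache))
    assign(key, force(expr), envir = .fixture_cache)
  get(key, envir = .fixture_cache)
}

## A small simulated genome with one planted family (clean ends, no indels)
## used across miner/annotator/RES/expression tests.
small_sim <- function() {
  memo("small_sim", {
    cfg <- sim_config(
      genome_length = 4e4, gc_content = 0.5,
      families = list(family_spec("famA", n_copies = 8, p_sub = 0.01,
                                  p_indel = 0, frac_orf_disrupted = 0)),
      seed = 101L)
    simulate_tle_genome(cfg)
  })
}

## A clean consensus element of the default design.
default_element <- function() {
  memo("default_element", {
    generate_consensus_element(family_spec("ref"), seed = 202L)
  })
}

## Naive, loop-based TIR scorer used as an independent oracle for
## detect_tirs: same definition, written as a direct double loop over L.
brute_force_tir <- function(element, min_tir = 12L, max_tir = 100L,
                            mismatch_frac = 0.1) {
  n <- nchar(element)
  rc <- revcomp(element)
  best <- NULL
  for (L in min_tir:min(max_tir, n %/% 2L)) {
    mism <- 0L
    for (i in seq_len(L)) {
      if (substr(element, i, i) != substr(rc, i, i)) mism <- mism + 1L
    }
    if (mism <= mismatch_frac * L) {
      score <- L - 3L * mism
      if (is.null(best) || score > best$score)
        best <- list(tir_length = L, mismatches = mism, score = score)
    }
  }
  best
}

## Enumerate every start-to-stop ORF by scanning codons directly (oracle for
## find_longest_orf); returns the longest protein length, 0 if none.
brute_force_longest_orf <- function(element, min_aa = 1L) {
  best <- 0L
  for (seqs in c(element, revcomp(element))) {
    nc <- nchar(seqs)
    for (off in 0:2) {
      i <- off + 1L
      while (i + 2L <= nc) {
        if (substr(seqs, i, i + 2L) == "ATG") {
          j <- i
          len <- 0L
          repeat {
            if (j + 2L > nc) { len <- len + 0L; break }
            cod <- substr(seqs, j, j + 2L)
            if (cod %in% c("TAA", "TAG", "TGA")) break
            len <- len + 1L
            j <- j + 3L
          }
          if (len >= min_aa) best <- max(best, len)
        }
        i <- i + 3L
      }
    }
  }
  best
}

res_sim <- function() {
  memo("res_sim", {
    cfg <- sim_config(
      genome_length = 6e4, gc_content = 0.5,
      families = list(family_spec("famR", n_copies = 15, p_sub = 0.005,
                                  p_indel = 0, frac_orf_disrupted = 0)),
      seed = 301L)
    sim <- simulate_tle_genome(cfg)
    g <- sim$genome[["chr1"]]
    cases <- NULL
    modes <- c("pre_insertion", "excision_footprint", "at_rich")
    for (k in seq_along(modes)) {
      ## plant each mode on its own subset of elements
      sub <- sim$truth[((k - 1) * 5 + 1):(k * 5), ]
      out <- make_res_cases(g, sub, 5, mode = modes[k], seed = 400L + k)
      g <- out$genome
      cases <- rbind(cases, out$cases)
    }
    sim$genome <- c(chr1 = g)
    list(sim = sim, cases = cases)
  })
}


expr_fixture <- function() {
  memo("expr_fixture", {
    ## distinguishable copies (p_sub > 0); keep 9 intact-ORF copies and 3
    ## disrupted ones, mirroring a family with nine active members
    cfg <- sim_config(
      genome_length = 7e4, gc_content = 0.5,
      families = list(family_spec("famE", n_copies = 20, p_sub = 0.01,
                                  p_indel = 0, frac_orf_disrupted = 0.2)),
      seed = 501L)
    sim <- simulate_tle_genome(cfg)
    stopifnot(sum(sim$truth$has_intact_orf) >= 9,
              sum(!sim$truth$has_intact_orf) >= 3)
    keep <- c(which(sim$truth$has_intact_orf)[1:9],
              which(!sim$truth$has_intact_orf)[1:3])
    sim$truth <- sim$truth[sort(keep), ]
    tx <- make_transcripts(sim$truth, design_protein_length = 338,
                           n_per_copy = 1, intron_prob = 0.6, seed = 502L)
    cons <- sim$consensus$famE
    cds <- substr(cons$sequence, cons$orf$start, cons$orf$end)
    list(sim = sim, tx = tx, cds = cds)
  })
}

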