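test_that("center-star MSA handles identity and single indels", {
  m <- c(a = "ACGTACGTAC", b = "ACGTACGTAC")
  msa <- build_msa(m, 1)
  expect_equal(unname(msa$rows[1]), unname(msa$rows[2]))
  expect_false(grepl("-", msa$rows[1], fixed = TRUE))

  m2 <- c(a = "ACGTACGTACGTACGT", b = "ACGTACTACGTACGT")  # one deletion
  msa2 <- build_msa(m2, 1)
  expect_equal(unname(nchar(msa2$rows[1])), unname(nchar(msa2$rows[2])))
  expect_equal(sum(chars(msa2$rows[[2]]) == "-"), 1L)
  ## rows reproduce the input sequences when gaps are stripped
  expect_equal(gsub("-", "", msa2$rows[[2]], fixed = TRUE), unname(m2[2]))
})

test_that("center-star alignment is near the exhaustive 3-way optimum", {
  ## tiny cases solved by brute-force 3-way dynamic programming
  sp_score <- function(rows) {
    cs <- strsplit(rows, "", fixed = TRUE)
    n <- length(cs[[1]])
    tot <- 0
    for (k in seq_len(n)) {
      col <- vapply(cs, `[`, character(1), k)
      for (i in 1:2) for (j in (i + 1):3) {
        tot <- tot + if (col[i] == "-" && col[j] == "-") 0
        else if (col[i] == "-" || col[j] == "-") -1
        else if (col[i] == col[j]) 1 else -1
      }
    }
    tot
  }
  brute_best <- function(x, y, z) {
    ## exhaustive 3-way alignment over all gap placements (tiny strings)
    best <- -Inf
    nx <- nchar(x); ny <- nchar(y); nz <- nchar(z)
    ## recursive DP with memo on (i, j, k)
    memo <- new.env(parent = emptyenv())
    rec <- function(i, j, k) {
      if (i == 0 && j == 0 && k == 0) return(0)
      key <- paste(i, j, k)
      if (!is.null(memo[[key]])) return(memo[[key]])
      sub <- function(a, b) if (a == b) 1 else -1
      v <- -Inf
      cx <- if (i > 0) substr(x, i, i) else ""
      cy <- if (j > 0) substr(y, j, j) else ""
      cz <- if (k > 0) substr(z, k, k) else ""
      if (i > 0 && j > 0 && k > 0)
        v <- max(v, rec(i - 1, j - 1, k - 1) +
                   sub(cx, cy) + sub(cx, cz) + sub(cy, cz))
      if (i > 0 && j > 0) v <- max(v, rec(i - 1, j - 1, k) + sub(cx, cy) - 2)
      if (i > 0 && k > 0) v <- max(v, rec(i - 1, j, k - 1) + sub(cx, cz) - 2)
      if (j > 0 && k > 0) v <- max(v, rec(i, j - 1, k - 1) + sub(cy, cz) - 2)
      if (i > 0) v <- max(v, rec(i - 1, j, k) - 2)
      if (j > 0) v <- max(v, rec(i, j - 1, k) - 2)
      if (k > 0) v <- max(v, rec(i, j, k - 1) - 2)
      memo[[key]] <- v
      v
    }
    rec(nx, ny, nz)
  }
  cases <- list(c("ACGTAC", "ACTAC", "ACGTC"),
                c("GATTACA", "GATACA", "GTTACA"),
                c("CCGGAA", "CCGAA", "CCGGTA"))
  for (cs in cases) {
    msa <- build_msa(setNames(cs, c("x", "y", "z")), 1)
    got <- sp_score(unname(msa$rows))
    opt <- brute_best(cs[1], cs[2], cs[3])
    expect_lte(got, opt)
    expect_gte(got, opt - 4)  # center-star is within a bounded gap
    expect_lte(nchar(msa$rows[1]), max(nchar(cs)) + 2)
  }
})

test_that("consensus follows majority with exemplar tie-break", {
  rows <- c(a = "ACGT", b = "ACGA", c = "ACTA")
  msa <- structure(list(ids = names(rows), rows = rows, exemplar_index = 1L),
                   class = "family_msa")
  ## col4: T,A,A -> A; col3: G,G,T -> G
  expect_equal(consensus_from_msa(msa), "ACGA")
  ## 2-2 tie resolves toward the exemplar residue
  rows2 <- c(a = "AT", b = "AT", c = "AA", d = "AA")
  msa2 <- structure(list(ids = names(rows2), rows = rows2,
                         exemplar_index = 3L), class = "family_msa")
  expect_equal(consensus_from_msa(msa2), "AA")
  ## majority-gap columns are omitted
  rows3 <- c(a = "A-G", b = "A-G", c = "ACG")
  msa3 <- structure(list(ids = names(rows3), rows = rows3,
                         exemplar_index = 1L), class = "family_msa")
  expect_equal(consensus_from_msa(msa3), "AG")
})

test_that("copy divergence is the complement of alignment similarity", {
  cons <- default_element()$sequence
  expect_equal(copy_divergence(cons, cons), 0)
  one_sub <- cons
  substr(one_sub, 500, 500) <- if (substr(cons, 500, 500) == "A") "G" else "A"
  expect_equal(copy_divergence(one_sub, cons), 100 * 1 / nchar(cons))
  expect_error(copy_divergence("", cons), "empty")
})

test_that("divergence profile bins at 0.5% with lower-bin modal ties", {
  p <- divergence_profile(c(1.4, 1.6, 1.4))
  expect_equal(sum(p$bins$count), 3L)
  expect_equal(p$bins$count[p$bins$bin_center == 1.25], 2L)
  expect_equal(p$bins$count[p$bins$bin_center == 1.75], 1L)
  expect_equal(p$modal_bin_center, 1.25)
  expect_equal(p$overall_similarity + p$mean, 100)
  expect_error(divergence_profile(numeric(0)), "no divergence")
  ## tie goes to the lower-divergence bin
  p2 <- divergence_profile(c(0.1, 0.2, 0.6, 0.7))
  expect_equal(p2$modal_bin_center, 0.25)
})

test_that("amplification age is linear in peak and inverse in rate", {
  mk <- function(peak) structure(list(modal_bin_center = peak),
                                 class = "divergence_profile")
  expect_equal(amplification_age(mk(1.5), clock_model(1)), 1.5)
  expect_equal(amplification_age(mk(1.0), clock_model(1)), 1.0)
  expect_equal(amplification_age(mk(0)), 0)
  expect_equal(amplification_age(mk(3.0), clock_model(2)), 1.5)
})

test_that("protein comparison reports identity and positives per column", {
  p <- "MKTAYIAKQR"
  cmp <- interfamily_protein_comparison(p, p)
  expect_equal(cmp$identity_pct, 100)
  expect_equal(cmp$positive_pct, 100)
  expect_equal(cmp$aligned_length, nchar(p))

  cmp2 <- interfamily_protein_comparison("MKKKKKKKKH", "MDDDDDDDDH")
  expect_equal(cmp2$identical, 2L)
  expect_equal(cmp2$aligned_length, 10L)
  ## hand-checked BLOSUM62: K/D scores -1, so positives are only M and H
  expect_equal(cmp2$positives, 2L)
})

test_that("family divergence recovers the generating substitution rate", {
  cons <- default_element()$sequence
  for (p_sub in c(0.01, 0.02, 0.04)) {
    copies <- vapply(1:75, function(s)
      as.character(mutate_copy(cons, p_sub, 0, seed = 3000 + s)),
      character(1))
    names(copies) <- paste0("c", 1:75)
    fam <- analyze_family(copies)
    m <- fam$profile$mean
    expect_gte(m, 0.8 * 100 * p_sub)
    expect_lte(m, 1.05 * 100 * p_sub)
    ## the modal bin (closed) contains the generating rate
    expect_lte(abs(fam$profile$modal_bin_center - 100 * p_sub), 0.25)
  }
})
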