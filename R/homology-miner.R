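## Translated homology search for transposase loci, extension to complete
## TIR/TA-bounded elements, and exact-terminal family retrieval.

## Self-score of a protein segment under BLOSUM62 (perfect-match score).
aa_self_score <- function(protein) {
  m <- blosum62()
  aa <- chars(protein)
  sum(m[cbind(aa, aa)])
}

## Frame-local peptide interval -> genome interval (1-based inclusive,
## plus-strand coordinates). frame in 1..6; n = contig length.
frame_to_genome <- function(frame, p_start, p_end, n) {
  off <- (frame - 1L) %% 3L
  nt1 <- off + 3L * (p_start - 1L) + 1L
  nt2 <- off + 3L * p_end
  if (frame <= 3L) c(nt1, nt2) else c(n - nt2 + 1L, n - nt1 + 1L)
}

#' Seeded six-frame translated search for transposase homology
#'
#' Exact `word_size`-aa words shared between the query protein and each of
#' the six conceptual translation frames seed local BLOSUM62 alignments of
#' the query against a window around each seed cluster. A hit is accepted
#' when its score reaches `min_score_frac` of the query's self-score over
#' the aligned query region; overlapping same-strand hits are merged
#' (union interval, best score).
#'
#' @param genome named character vector of contigs.
#' @param query_protein transposase query (character string, >= word_size aa).
#' @param word_size seed word length in aa.
#' @param min_score_frac acceptance threshold as a fraction of the query
#'   self-score over the aligned region.
#' @param min_score absolute raw-score floor; short spurious word-seeded
#'   alignments in background sequence rarely exceed it.
#' @param gap_opening,gap_extension alignment gap penalties.
#' @return data.frame of hits: contig, frame (1-6), strand, start, end
#'   (1-based inclusive plus-strand genome coordinates), qstart, qend (aa),
#'   score.
#' @export
search_transposase <- function(genome, query_protein, word_size = 4L,
                               min_score_frac = 0.5, min_score = 60,
                               gap_opening = 10, gap_extension = 1) {
  if (length(genome) == 0L || any(nchar(genome) == 0L))
    stop("empty genome")
  if (is.null(query_protein) || nchar(query_protein) < word_size)
    stop("query shorter than word_size")
  qlen <- nchar(query_protein)
  words <- unique(vapply(seq_len(qlen - word_size + 1L),
                         function(i) substr(query_protein, i, i + word_size - 1L),
                         character(1)))
  mat <- blosum62()
  q <- Biostrings::AAString(query_protein)
  hits <- NULL
  for (ctg in names(genome)) {
    n <- nchar(genome[[ctg]])
    frames <- six_frame_translate(genome[[ctg]])
    for (f in 1:6) {
      pep <- frames[[f]]
      if (nchar(pep) < word_size) next
      loc <- stri_locate_all_fixed(pep, words)
      fpos <- unlist(lapply(seq_along(words), function(wi) {
        s <- loc[[wi]][, 1]
        s[!is.na(s)]
      }))
      if (length(fpos) == 0L) next
      fpos <- sort(unique(fpos))
      ## cluster seeds separated by less than ~1.5 query lengths
      brk <- c(0L, which(diff(fpos) > 1.5 * qlen), length(fpos))
      pep_x <- gsub("*", "X", pep, fixed = TRUE)
      for (ci in seq_len(length(brk) - 1L)) {
        cl <- fpos[(brk[ci] + 1L):brk[ci + 1L]]
        w0 <- max(1L, min(cl) - qlen - 10L)
        w1 <- min(nchar(pep), max(cl) + qlen + 10L)
        aln <- Biostrings::pairwiseAlignment(
          q, Biostrings::AAString(substr(pep_x, w0, w1)),
          type = "local", substitutionMatrix = mat,
          gapOpening = gap_opening, gapExtension = gap_extension)
        sc <- Biostrings::score(aln)
        qr <- as.data.frame(Biostrings::pattern(aln)@range)
        sr <- as.data.frame(Biostrings::subject(aln)@range)
        if (qr$width < word_size) next
        self <- aa_self_score(substr(query_protein, qr$start, qr$end))
        if (sc < min_score_frac * self || sc < min_score) next
        gi <- frame_to_genome(f, w0 + sr$start - 1L, w0 + sr$end - 1L, n)
        hits <- rbind(hits, data.frame(
          contig = ctg, frame = f,
          strand = if (f <= 3L) "+" else "-",
          start = gi[1], end = gi[2],
          qstart = qr$start, qend = qr$end, score = sc,
          stringsAsFactors = FALSE))
      }
    }
  }
  if (is.null(hits)) {
    return(data.frame(contig = character(0), frame = integer(0),
                      strand = character(0), start = integer(0),
                      end = integer(0), qstart = integer(0),
                      qend = integer(0), score = numeric(0)))
  }
  merge_hits(hits)
}

## Merge overlapping same-contig, same-strand hits: union interval,
## maximum score. Deterministic (sorted by contig, strand, start).
merge_hits <- function(hits) {
  out <- NULL
  for (key in unique(paste(hits$contig, hits$strand))) {
    h <- hits[paste(hits$contig, hits$strand) == key, , drop = FALSE]
    h <- h[order(h$start, h$end), , drop = FALSE]
    cur <- h[1, , drop = FALSE]
    for (i in seq_len(nrow(h))[-1]) {
      if (h$start[i] <= cur$end) {
        cur$end <- max(cur$end, h$end[i])
        if (h$score[i] > cur$score) {
          cur$score <- h$score[i]
          cur$frame <- h$frame[i]
          cur$qstart <- h$qstart[i]; cur$qend <- h$qend[i]
        }
      } else {
        out <- rbind(out, cur)
        cur <- h[i, , drop = FALSE]
      }
    }
    out <- rbind(out, cur)
  }
  out <- out[order(out$contig, out$start, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  out
}

## Best qualifying TIR for the element slice: maximize L - 3*editdist over
## L in [min_tir, max_tir] with edit distance <= frac*L between prefix(L)
## and revcomp(suffix(L)) (edit distance tolerates indels within the TIR).
## A pair whose pairing continues essentially unbroken beyond the chosen L
## is rejected: that is an inverted duplication, not a *terminal* repeat.
ir_pair_score <- function(el, min_tir, max_tir, frac) {
  n <- nchar(el)
  hi <- min(max_tir, n %/% 2L)
  if (hi < min_tir) return(NULL)
  pmax_len <- min(hi + 18L, n %/% 2L)
  p <- substr(el, 1L, pmax_len)
  s <- substr(revcomp(el), 1L, pmax_len)
  ## an indel inside the repeat shifts the two arms; comparing equal-length
  ## windows would double-charge the shift, so minimize over a small length
  ## offset of the prefix arm
  dist_at <- function(L) {
    dls <- -3:3
    dls <- dls[L + dls >= 1L & L + dls <= pmax_len]
    min(vapply(dls, function(dl)
      utils::adist(substr(p, 1L, L + dl), substr(s, 1L, L))[1L, 1L],
      numeric(1)))
  }
  dists <- vapply(seq_len(hi), dist_at, numeric(1))
  L <- seq_len(hi)
  valid <- L >= min_tir & dists <= frac * L
  if (!any(valid)) return(NULL)
  score <- L - 3L * dists
  cand <- which(valid)
  best <- cand[which.max(score[cand])]
  ## beyond a true terminus the sequence is unrelated (~75% mismatch per
  ## position); homologous continuation (a long inverted duplication, e.g.
  ## two family copies on opposite strands) stays far below that
  probe <- min(best + 15L, n %/% 2L)
  if (probe - best >= 6L) {
    dprobe <- dist_at(probe)
    if (dprobe - dists[best] <= 0.5 * (probe - best)) return(NULL)
  }
  list(tir_length = best, mismatches = unname(dists[best]),
       score = score[best])
}

#' Extend an alignment hit to a complete TIR/TA-bounded element
#'
#' Scans outward from the hit for the best-scoring inverted-repeat pair
#' whose proposed termini are both immediately flanked by genomic "TA".
#' Candidate right termini are found by matching the reverse complement of
#' each candidate left terminus's first `seed_len` bases with up to
#' `seed_mm` mismatches. Returned boundaries exclude the TSDs. Ties in IR
#' score go to the outermost pair.
#'
#' @param genome named character vector of contigs.
#' @param hit one row of [search_transposase()] output.
#' @param max_extension maximum scan distance beyond the hit, bp.
#' @param min_tir,max_tir TIR length search bounds, bp. `max_tir` is kept
#'   near the typical Tc1/mariner TIR range: inverted pairing that continues
#'   essentially unbroken past the chosen length is rejected as an inverted
#'   duplication (e.g. the genome-scale inverted repeat formed by two
#'   neighboring copies on opposite strands), not a terminal repeat.
#' @param tir_mismatch_frac tolerated TIR mismatch fraction.
#' @param seed_len,seed_mm terminus pairing seed length / edit budget.
#' @param left_bound,right_bound optional genome coordinates the element may
#'   not extend beyond (e.g. the neighboring transposase loci: an element
#'   carries one transposase, so its termini cannot lie beyond the adjacent
#'   hit cluster).
#' @return one-row data.frame (an element copy: contig, start, end, strand,
#'   seq, tir_length, tir_mismatches, terminal4_left/right, tsd_left/right)
#'   or NULL if no qualifying pair exists.
#' @export
extend_to_element <- function(genome, hit, max_extension = 5000L,
                              min_tir = 12L, max_tir = 45L,
                              tir_mismatch_frac = 0.1,
                              seed_len = 12L, seed_mm = 3L,
                              left_bound = NULL, right_bound = NULL) {
  g <- genome[[hit$contig]]
  n <- nchar(g)
  if (is.null(left_bound) || is.na(left_bound)) left_bound <- 1L
  if (is.null(right_bound) || is.na(right_bound)) right_bound <- n
  ws <- max(1L, hit$start - max_extension, left_bound)
  we <- min(n, hit$end + max_extension, right_bound)
  R <- substr(g, ws, we)
  hs <- hit$start - ws + 1L
  he <- hit$end - ws + 1L
  ta <- stri_locate_all_fixed(R, "TA")[[1]][, 1]
  ta <- ta[!is.na(ta)]
  lefts <- ta + 2L
  lefts <- lefts[lefts <= hs & lefts + 2L * min_tir - 1L <= nchar(R)]
  rights <- ta - 1L
  rights <- rights[rights >= he & rights >= seed_len &
                     rights <= nchar(R) - 2L]
  if (length(lefts) == 0L || length(rights) == 0L) return(NULL)
  ## seed: edit distance between every left prefix seed and the reverse
  ## complement of every right suffix seed, in one vectorized call
  lp <- substring(R, lefts, lefts + seed_len - 1L)
  rp <- stringi::stri_reverse(chartr("ACGT", "TGCA",
                                     substring(R, rights - seed_len + 1L,
                                               rights)))
  D <- utils::adist(lp, rp)
  idx <- which(D <= seed_mm, arr.ind = TRUE)
  best <- NULL
  for (k in seq_len(nrow(idx))) {
    a <- lefts[idx[k, 1L]]
    b <- rights[idx[k, 2L]]
    if (b <= a + 2L * min_tir - 2L) next
    sc <- ir_pair_score(substr(R, a, b), min_tir, max_tir,
                        tir_mismatch_frac)
    if (is.null(sc)) next
    if (is.null(best) || sc$score > best$score ||
        (sc$score == best$score && (b - a) > (best$b - best$a))) {
      best <- c(sc, list(a = a, b = b))
    }
  }
  if (is.null(best)) return(NULL)
  el <- substr(R, best$a, best$b)
  ## store the element in its own orientation (hit strand); TA TSDs and the
  ## TIR property are orientation-symmetric
  if (hit$strand == "-") el <- revcomp(el)
  data.frame(contig = hit$contig,
             start = ws + best$a - 1L, end = ws + best$b - 1L,
             strand = hit$strand, seq = el,
             tir_length = best$tir_length,
             tir_mismatches = best$mismatches,
             terminal4_left = substr(el, 1L, 4L),
             terminal4_right = substr(el, nchar(el) - 3L, nchar(el)),
             tsd_left = substr(g, ws + best$a - 3L, ws + best$a - 2L),
             tsd_right = substr(g, ws + best$b, ws + best$b + 1L),
             stringsAsFactors = FALSE)
}

#' Retrieve family members by exact terminal sequences
#'
#' Finds all occurrences of the exemplar's terminal `end_len`-mers (and
#' their reverse complements) with `end_mismatch` tolerated mismatches
#' (default zero), pairs them in consistent orientation within
#' `[min_len_frac, max_len_frac]` times the exemplar length, and emits each
#' pairing as a member. Overlapping pairings are resolved greedily by
#' proximity of the implied length to the exemplar length.
#'
#' @param genome named character vector of contigs.
#' @param exemplar element copy row (needs `seq`) or a DNA string.
#' @param end_len terminal anchor length, bp (default 33, the TIR length).
#' @param end_mismatch mismatches tolerated in the terminal anchors.
#' @param min_len_frac,max_len_frac member length bounds relative to the
#'   exemplar.
#' @return data.frame of members in the same layout as
#'   [extend_to_element()], with a `strand` column giving the member's
#'   orientation relative to the exemplar.
#' @export
retrieve_members <- function(genome, exemplar, end_len = 33L,
                             end_mismatch = 0L, min_len_frac = 0.3,
                             max_len_frac = 1.5) {
  ex <- if (is.character(exemplar)) exemplar else exemplar$seq
  xl <- nchar(ex)
  stopifnot(xl >= end_len)
  lend <- substr(ex, 1L, end_len)
  rend <- substr(ex, xl - end_len + 1L, xl)
  find <- function(pat, g) {
    m <- Biostrings::matchPattern(Biostrings::DNAString(pat),
                                  Biostrings::DNAString(g),
                                  max.mismatch = end_mismatch)
    as.data.frame(m@ranges)
  }
  out <- NULL
  for (ctg in names(genome)) {
    g <- genome[[ctg]]
    cand <- NULL
    lp <- find(lend, g); rp <- find(rend, g)
    if (nrow(lp) && nrow(rp)) {
      for (s in lp$start) for (e in rp$end) {
        len <- e - s + 1L
        if (len >= min_len_frac * xl && len <= max_len_frac * xl)
          cand <- rbind(cand, data.frame(start = s, end = e, strand = "+"))
      }
    }
    lm <- find(revcomp(lend), g); rm_ <- find(revcomp(rend), g)
    if (nrow(lm) && nrow(rm_)) {
      for (s in rm_$start) for (e in lm$end) {
        len <- e - s + 1L
        if (len >= min_len_frac * xl && len <= max_len_frac * xl)
          cand <- rbind(cand, data.frame(start = s, end = e, strand = "-"))
      }
    }
    if (is.null(cand)) next
    ## drop orientation duplicates (palindromic anchors give both strands)
    cand <- cand[!duplicated(cand[, c("start", "end")]), , drop = FALSE]
    cand <- cand[order(abs((cand$end - cand$start + 1L) - xl),
                       cand$start), , drop = FALSE]
    taken <- NULL
    for (i in seq_len(nrow(cand))) {
      s <- cand$start[i]; e <- cand$end[i]
      if (!is.null(taken) &&
          any(pmax(taken$start, s) <= pmin(taken$end, e))) next
      taken <- rbind(taken, cand[i, , drop = FALSE])
    }
    for (i in seq_len(nrow(taken))) {
      s <- taken$start[i]; e <- taken$end[i]
      sl <- substr(g, s, e)
      el <- if (taken$strand[i] == "+") sl else revcomp(sl)
      tir <- tryCatch(
        ir_pair_score(el, 12L, 100L, 0.1),
        error = function(e) NULL)
      tsd_l <- if (s >= 3L) substr(g, s - 2L, s - 1L) else NA_character_
      tsd_r <- if (e + 2L <= nchar(g)) substr(g, e + 1L, e + 2L)
               else NA_character_
      if (taken$strand[i] == "-") { tmp <- tsd_l; tsd_l <- revcomp_or_na(tsd_r); tsd_r <- revcomp_or_na(tmp) }
      out <- rbind(out, data.frame(
        contig = ctg, start = s, end = e, strand = taken$strand[i],
        seq = el,
        tir_length = if (is.null(tir)) NA_integer_ else tir$tir_length,
        tir_mismatches = if (is.null(tir)) NA_integer_ else tir$mismatches,
        terminal4_left = substr(el, 1L, 4L),
        terminal4_right = substr(el, nchar(el) - 3L, nchar(el)),
        tsd_left = tsd_l, tsd_right = tsd_r,
        stringsAsFactors = FALSE))
    }
  }
  if (is.null(out))
    out <- empty_members()
  rownames(out) <- NULL
  out
}

revcomp_or_na <- function(x) if (is.na(x)) NA_character_ else revcomp(x)

empty_members <- function() {
  data.frame(contig = character(0), start = integer(0), end = integer(0),
             strand = character(0), seq = character(0),
             tir_length = integer(0), tir_mismatches = integer(0),
             terminal4_left = character(0), terminal4_right = character(0),
             tsd_left = character(0), tsd_right = character(0),
             stringsAsFactors = FALSE)
}

#' Retrieve family members by consensus-anchored terminus scanning
#'
#' Generalization of exact-terminal retrieval to decayed termini: every
#' TA-preceded genome position whose following `anchor` bp are within
#' `max_edit_frac * anchor` edits of the consensus left terminus is a
#' candidate element start (symmetrically for ends; reverse-complement
#' anchors capture minus-strand copies). Starts and ends are paired in
#' matching orientation within `[min_len_frac, max_len_frac]` times the
#' consensus length, preferring pairs with the best summed anchor edit
#' distance (ties by implied length closest to the consensus); overlapping
#' pairings are resolved greedily.
#'
#' @param genome named character vector of contigs.
#' @param consensus family consensus sequence.
#' @param anchor terminus anchor length in bp; it must extend well past
#'   the TIR so that the two termini and the two orientations cannot be
#'   confused (the TIR itself is shared by all four).
#' @param max_edit_frac edit-distance acceptance threshold as a fraction of
#'   `anchor`.
#' @param min_len_frac,max_len_frac member length bounds relative to the
#'   consensus.
#' @return member data.frame in the [extend_to_element()] layout.
#' @export
anchor_scan_members <- function(genome, consensus, anchor = 100L,
                                max_edit_frac = 0.25, min_len_frac = 0.3,
                                max_len_frac = 1.5) {
  nc <- nchar(consensus)
  stopifnot(nc >= 2L * anchor)
  cl <- substr(consensus, 1L, anchor)
  cr <- substr(consensus, nc - anchor + 1L, nc)
  rc_cl <- revcomp(cl)
  rc_cr <- revcomp(cr)
  thr <- max_edit_frac * anchor
  ## refined edit distance minimized over a small window-length offset
  refine_d <- function(g, pos, ref, leftish) {
    min(vapply(-4:4, function(dl) {
      if (leftish) {
        e <- pos + anchor - 1L + dl
        if (e > nchar(g) || pos < 1L) return(Inf)
        utils::adist(ref, substr(g, pos, e))[1L, 1L]
      } else {
        s <- pos - anchor + 1L - dl
        if (s < 1L || pos > nchar(g)) return(Inf)
        utils::adist(ref, substr(g, s, pos))[1L, 1L]
      }
    }, numeric(1)))
  }
  out <- NULL
  for (ctg in names(genome)) {
    g <- genome[[ctg]]
    n <- nchar(g)
    ta <- stri_locate_all_fixed(g, "TA")[[1]][, 1]
    ta <- ta[!is.na(ta)]
    starts <- ta + 2L
    starts <- starts[starts + anchor - 1L <= n]
    ends <- ta - 1L
    ends <- ends[ends >= anchor]
    swin <- substring(g, starts, starts + anchor - 1L)
    ewin <- substring(g, ends - anchor + 1L, ends)
    cand <- NULL
    for (orient in c("+", "-")) {
      lref <- if (orient == "+") cl else rc_cr
      rref <- if (orient == "+") cr else rc_cl
      ls <- starts[utils::adist(lref, swin)[1L, ] <= thr + 4]
      re <- ends[utils::adist(rref, ewin)[1L, ] <= thr + 4]
      if (length(ls) == 0L || length(re) == 0L) next
      dl <- vapply(ls, refine_d, numeric(1), g = g, ref = lref,
                   leftish = TRUE)
      dr <- vapply(re, refine_d, numeric(1), g = g, ref = rref,
                   leftish = FALSE)
      ls <- ls[dl <= thr]; dl <- dl[dl <= thr]
      re <- re[dr <= thr]; dr <- dr[dr <= thr]
      for (i in seq_along(ls)) {
        len <- re - ls[i] + 1L
        ok <- which(len >= min_len_frac * nc & len <= max_len_frac * nc)
        for (j in ok) {
          cand <- rbind(cand, data.frame(
            start = ls[i], end = re[j], strand = orient,
            d = dl[i] + dr[j], lendev = abs(len[j] - nc)))
        }
      }
    }
    if (is.null(cand)) next
    cand <- cand[!duplicated(cand[, c("start", "end")]), , drop = FALSE]
    cand <- cand[order(cand$d, cand$lendev, cand$start), , drop = FALSE]
    taken <- NULL
    for (i in seq_len(nrow(cand))) {
      if (!is.null(taken) &&
          any(pmax(taken$start, cand$start[i]) <=
                pmin(taken$end, cand$end[i]))) next
      taken <- rbind(taken, cand[i, , drop = FALSE])
    }
    for (i in seq_len(nrow(taken))) {
      s <- taken$start[i]; e <- taken$end[i]
      sl <- substr(g, s, e)
      el <- if (taken$strand[i] == "+") sl else revcomp(sl)
      tir <- tryCatch(ir_pair_score(el, 12L, 100L, 0.1),
                      error = function(err) NULL)
      out <- rbind(out, data.frame(
        contig = ctg, start = s, end = e, strand = taken$strand[i],
        seq = el,
        tir_length = if (is.null(tir)) NA_integer_ else tir$tir_length,
        tir_mismatches = if (is.null(tir)) NA_integer_ else tir$mismatches,
        terminal4_left = substr(el, 1L, 4L),
        terminal4_right = substr(el, nchar(el) - 3L, nchar(el)),
        tsd_left = if (s >= 3L) substr(g, s - 2L, s - 1L) else NA_character_,
        tsd_right = if (e + 2L <= nchar(g)) substr(g, e + 1L, e + 2L)
                    else NA_character_,
        stringsAsFactors = FALSE))
    }
  }
  if (is.null(out)) out <- empty_members()
  rownames(out) <- NULL
  out
}

#' Flag full-length members against a family consensus
#'
#' A member is full length when both terminal 4-mers match the consensus
#' termini exactly and its global alignment to the consensus covers at
#' least `min_coverage` of consensus positions.
#'
#' @param members member data.frame (needs `seq`).
#' @param consensus consensus DNA string.
#' @param min_coverage required consensus coverage fraction.
#' @return `members` with a logical `full_length` column.
#' @export
flag_full_length <- function(members, consensus, min_coverage = 0.9) {
  t4l <- substr(consensus, 1L, 4L)
  t4r <- substr(consensus, nchar(consensus) - 3L, nchar(consensus))
  mat <- dna_submat()
  full <- logical(nrow(members))
  for (i in seq_len(nrow(members))) {
    sq <- members$seq[i]
    ends_ok <- substr(sq, 1L, 4L) == t4l &&
      substr(sq, nchar(sq) - 3L, nchar(sq)) == t4r
    if (!ends_ok) { full[i] <- FALSE; next }
    aln <- Biostrings::pairwiseAlignment(
      Biostrings::DNAString(sq), Biostrings::DNAString(consensus),
      type = "global", substitutionMatrix = mat,
      gapOpening = 8, gapExtension = 2)
    rows <- alignment_rows(aln)
    cov <- sum(rows$p != "-" & rows$s != "-") / nchar(consensus)
    full[i] <- cov >= min_coverage
  }
  members$full_length <- full
  members
}
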