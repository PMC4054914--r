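## Related-empty-site, transcript and small-RNA fixtures derived from a
## simulated genome (companions to simulate_tle_genome).

#' Plant related-empty-site (RES) loci for selected elements
#'
#' Appends, at new loci near the contig end, copies of selected elements'
#' flank pairs joined by a single "TA" (`pre_insertion`), joined by "TA" plus
#' 1-10 extra bases (`excision_footprint`), or — for `at_rich` — first
#' rewrites the element's own genomic flanks as >= 80% A/T simple repeats and
#' then appends the matching empty locus, so the case is discoverable by
#' flank homology.
#'
#' @param genome single DNA character string (one contig).
#' @param truth truth data.frame from [simulate_tle_genome()].
#' @param n number of cases to plant (<= nrow(truth)).
#' @param mode one of "pre_insertion", "excision_footprint", "at_rich".
#' @param seed integer seed.
#' @param flank_len flank length in bp copied to the empty locus.
#' @return list with modified `genome` and `cases` data.frame
#'   (copy_id, mode, junction, locus start/end, 1-based inclusive).
#' @export
make_res_cases <- function(genome, truth, n,
                           mode = c("pre_insertion", "excision_footprint",
                                    "at_rich"),
                           seed = 1L, flank_len = 100L) {
  mode <- match.arg(mode)
  if (nrow(truth) == 0L) stop("truth is empty")
  if (n > nrow(truth)) stop("n exceeds available elements")
  with_seed(seed, {
    idx <- sample.int(nrow(truth), n)
    cases <- NULL
    for (i in idx) {
      st <- truth$start[i]; en <- truth$end[i]
      lf <- substr(genome, st - 2L - flank_len, st - 3L)
      rf <- substr(genome, en + 3L, en + 2L + flank_len)
      junction <- "TA"
      if (mode == "excision_footprint") {
        junction <- paste0("TA", random_dna(sample.int(10L, 1L)))
      } else if (mode == "at_rich") {
        unit <- sample(c("AT", "AAT", "ATT", "AATT"), 1L)
        mk_flank <- function() {
          f <- chars(strtrim(strrep(unit, flank_len), flank_len))
          k <- max(1L, round(0.05 * flank_len))
          at <- sample.int(flank_len, k)
          f[at] <- sample(DNA_BASES, k, replace = TRUE)
          paste(f, collapse = "")
        }
        lf <- mk_flank(); rf <- mk_flank()
        ## rewrite the element's genomic flanks (outside the TSD TAs)
        genome <- paste0(substr(genome, 1L, st - 3L - flank_len), lf,
                         substr(genome, st - 2L, en + 2L), rf,
                         substr(genome, en + 3L + flank_len, nchar(genome)))
      }
      locus <- paste0(lf, junction, rf)
      spacer <- random_dna(100L)
      locus_start <- nchar(genome) + nchar(spacer) + 1L
      genome <- paste0(genome, spacer, locus)
      cases <- rbind(cases, data.frame(
        copy_id = truth$copy_id[i], mode = mode, junction = junction,
        locus_start = locus_start,
        locus_end = locus_start + nchar(locus) - 1L,
        stringsAsFactors = FALSE))
    }
    list(genome = genome, cases = cases)
  })
}

#' Generate transcripts from element copies
#'
#' Every copy with an intact ORF yields one transcript covering its full CDS
#' (no intron); additional transcripts are random element slices, spliced
#' (one internal segment deleted) with probability `intron_prob`.
#'
#' @param truth truth data.frame from [simulate_tle_genome()] (uses `seq`,
#'   `copy_id`, `has_intact_orf`).
#' @param design_protein_length designed transposase length in aa, used for
#'   the full-CDS truth call.
#' @param n_per_copy transcripts per copy in addition to the full-CDS one.
#' @param intron_prob probability that an extra transcript is spliced.
#' @param seed integer seed.
#' @return list with `transcripts` (named character vector) and `truth`
#'   data.frame (transcript_id, copy_id, spliced, has_full_cds).
#' @export
make_transcripts <- function(truth, design_protein_length,
                             n_per_copy = 1L, intron_prob = 0.5, seed = 1L) {
  with_seed(seed, {
    tx <- character(0)
    rows <- NULL
    thr <- ceiling(0.95 * design_protein_length)
    for (i in seq_len(nrow(truth))) {
      el <- truth$seq[i]
      n <- nchar(el)
      mk <- function(sequence, spliced) {
        id <- sprintf("%s_t%02d", truth$copy_id[i], length(tx) + 1L)
        orf <- find_longest_orf(sequence, both_strands = TRUE, min_aa = 50L)
        full <- !is.null(orf) && nchar(orf$protein) >= thr
        tx[[id]] <<- sequence
        rows <<- rbind(rows, data.frame(
          transcript_id = id, copy_id = truth$copy_id[i],
          spliced = spliced, has_full_cds = full, stringsAsFactors = FALSE))
      }
      if (isTRUE(truth$has_intact_orf[i])) {
        orf <- find_longest_orf(el, both_strands = TRUE, min_aa = 50L)
        u5 <- sample.int(30L, 1L); u3 <- sample.int(30L, 1L)
        st <- max(1L, orf$start - u5); en <- min(n, orf$end + u3)
        sl <- substr(el, st, en)
        if (orf$strand == "-") sl <- revcomp(sl)
        mk(sl, spliced = FALSE)
      }
      for (k in seq_len(n_per_copy)) {
        len <- sample(400:900, 1L)
        st <- sample.int(max(1L, n - len), 1L)
        sl <- substr(el, st, min(n, st + len - 1L))
        spliced <- runif(1) < intron_prob && nchar(sl) > 320L
        if (spliced) {
          ist <- sample(100:(nchar(sl) - 220L), 1L)
          ilen <- sample(60:150, 1L)
          sl <- paste0(substr(sl, 1L, ist - 1L),
                       substr(sl, ist + ilen, nchar(sl)))
        }
        mk(sl, spliced = spliced)
      }
    }
    list(transcripts = unlist(tx), truth = rows)
  })
}

#' Generate small-RNA reads with and without matches to a CDS
#'
#' Matching reads are exact substrings of the CDS or its reverse complement;
#' background reads are random sequence. Read lengths are drawn uniformly
#' from `len_range`.
#'
#' @param cds CDS DNA string.
#' @param n_matching number of CDS-derived reads.
#' @param n_random number of background reads.
#' @param len_range integer vector of allowed read lengths.
#' @param seed integer seed.
#' @return named character vector of reads.
#' @export
make_small_rnas <- function(cds, n_matching, n_random,
                            len_range = 21:24, seed = 1L) {
  with_seed(seed, {
    reads <- character(0)
    for (i in seq_len(n_matching)) {
      len <- sample(len_range, 1L)
      st <- sample.int(nchar(cds) - len + 1L, 1L)
      r <- substr(cds, st, st + len - 1L)
      if (runif(1) < 0.5) r <- revcomp(r)
      reads[sprintf("srna_m%03d", i)] <- r
    }
    for (i in seq_len(n_random)) {
      len <- sample(len_range, 1L)
      reads[sprintf("srna_r%03d", i)] <- random_dna(len)
    }
    reads
  })
}

#' Write simulation outputs to a directory
#'
#' Writes the genome FASTA, the truth table as BED6 (0-based half-open,
#' name = family:copy_id) plus a TSV with the extra truth fields, and any
#' transcript / small-RNA FASTAs.
#'
#' @param sim output of [simulate_tle_genome()].
#' @param dir output directory (created if needed).
#' @param transcripts optional named character vector.
#' @param small_rnas optional named character vector.
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(sim, dir, transcripts = NULL, small_rnas = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(sim$genome),
                              file.path(dir, "genome.fa"))
  tr <- sim$truth
  gr <- GenomicRanges::GRanges(
    seqnames = tr$contig,
    ranges = IRanges::IRanges(start = tr$start, end = tr$end),
    strand = tr$strand,
    name = paste(tr$family, tr$copy_id, sep = ":"),
    score = 0L)
  rtracklayer::export(gr, file.path(dir, "truth.bed"), format = "BED")
  write.table(tr[, setdiff(names(tr), "seq")],
              file.path(dir, "truth.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(transcripts))
    Biostrings::writeXStringSet(Biostrings::DNAStringSet(transcripts),
                                file.path(dir, "transcripts.fa"))
  if (!is.null(small_rnas))
    Biostrings::writeXStringSet(Biostrings::DNAStringSet(small_rnas),
                                file.path(dir, "small_rnas.fa"))
  invisible(dir)
}
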