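## Transcript-to-element mapping, intact-transposase transcript counting,
## and small-RNA matching against the transposase CDS.

#' Map transcripts to element copies
#'
#' Each transcript is aligned to every member with the transcript global and
#' the member local ("global-local"), so that spliced-out introns appear as
#' long transcript-row gaps. Maximal runs of aligned columns of at least
#' `min_block` bp form the matched blocks; transcript-row gap runs of at
#' least `min_intron` bp are intron-like gaps. The best member is the one
#' maximizing matched identities; ties are reported as ambiguous.
#'
#' @param transcripts named character vector of transcript sequences
#'   (duplicates by id + sequence are removed).
#' @param members named character vector of member sequences.
#' @param min_identity minimum identity (%) over matched blocks for a match
#'   to be reported.
#' @param min_block minimum matched block length in bp.
#' @param min_intron minimum transcript-row gap length counted as an intron.
#' @return data.frame: transcript_id, copy_id, n_blocks, n_introns,
#'   identity, matched_bp, ambiguous.
#' @export
map_transcripts <- function(transcripts, members, min_identity = 95,
                            min_block = 20L, min_intron = 20L) {
  dup <- duplicated(paste(names(transcripts), transcripts))
  transcripts <- transcripts[!dup]
  ## bring members to one family orientation (minus-strand copies may be
  ## supplied as genomic plus-strand slices)
  members <- vapply(members, orient_to_exemplar, character(1),
                    exemplar = members[[1L]])
  mat <- dna_submat()
  out <- NULL
  for (ti in seq_along(transcripts)) {
    ## transcripts from minus-strand ORFs arrive in mRNA sense; orient each
    ## one to the member set before aligning
    tx <- orient_to_exemplar(transcripts[[ti]], members[[1L]])
    best <- NULL
    scores <- numeric(length(members))
    stats_list <- vector("list", length(members))
    for (mi in seq_along(members)) {
      aln <- Biostrings::pairwiseAlignment(
        Biostrings::DNAString(tx), Biostrings::DNAString(members[[mi]]),
        type = "global-local", substitutionMatrix = mat,
        gapOpening = 10, gapExtension = 0.2)
      rows <- alignment_rows(aln)
      aligned <- rows$p != "-" & rows$s != "-"
      r <- rle(aligned)
      blocks <- sum(r$values & r$lengths >= min_block)
      matched_bp <- sum(r$lengths[r$values & r$lengths >= min_block])
      ident_bp <- sum(aligned & rows$p == rows$s)
      tgaps <- rle(rows$p == "-")
      introns <- sum(tgaps$values & tgaps$lengths >= min_intron)
      identity <- if (sum(aligned)) 100 * ident_bp / sum(aligned) else 0
      scores[mi] <- ident_bp
      stats_list[[mi]] <- list(blocks = blocks, matched_bp = matched_bp,
                               introns = introns, identity = identity)
    }
    top <- max(scores)
    winners <- which(scores == top)
    mi <- winners[1L]
    st <- stats_list[[mi]]
    if (st$identity < min_identity || st$blocks == 0L) next
    out <- rbind(out, data.frame(
      transcript_id = names(transcripts)[ti],
      copy_id = names(members)[mi],
      n_blocks = st$blocks, n_introns = st$introns,
      identity = st$identity, matched_bp = st$matched_bp,
      ambiguous = length(winners) > 1L,
      stringsAsFactors = FALSE))
  }
  if (is.null(out)) {
    out <- data.frame(transcript_id = character(0), copy_id = character(0),
                      n_blocks = integer(0), n_introns = integer(0),
                      identity = numeric(0), matched_bp = integer(0),
                      ambiguous = logical(0), stringsAsFactors = FALSE)
  }
  out
}

#' Does a transcript encode a full-length intact transposase?
#'
#' Operationalized as: the transcript's longest ORF is intact and at least
#' `frac` of the family ORF length.
#'
#' @param transcript transcript DNA string.
#' @param family_orf_aa family (modal or designed) transposase length in aa.
#' @param frac required fraction of the family ORF length.
#' @return logical.
#' @export
encodes_full_transposase <- function(transcript, family_orf_aa,
                                     frac = 0.95) {
  orf <- find_longest_orf(transcript, both_strands = TRUE, min_aa = 50L)
  !is.null(orf) && nchar(orf$protein) >= ceiling(frac * family_orf_aa)
}

#' Count transcripts encoding an intact full-length transposase
#'
#' Counts mapped transcripts whose sequence encodes the full transposase,
#' and cross-references them to their source copies (each transcript maps to
#' its best copy; the copy list is deduplicated, mirroring removal of
#' redundancy by locus cross-reference).
#'
#' @param matches output of [map_transcripts()].
#' @param transcripts the named transcript vector used for mapping.
#' @param family_orf_aa family transposase length in aa.
#' @return list: `count`, `transcript_ids`, `source_copies` (unique).
#' @export
count_intact_transposase_transcripts <- function(matches, transcripts,
                                                 family_orf_aa) {
  if (nrow(matches) == 0L)
    return(list(count = 0L, transcript_ids = character(0),
                source_copies = character(0)))
  full <- vapply(matches$transcript_id, function(id)
    encodes_full_transposase(transcripts[[id]], family_orf_aa), logical(1))
  ids <- matches$transcript_id[full]
  list(count = length(ids), transcript_ids = ids,
       source_copies = unique(matches$copy_id[full]))
}

#' Match small-RNA reads against a transposase CDS
#'
#' Reports every position where a read matches the CDS on either strand
#' with at most `max_mismatch` mismatches.
#'
#' @param reads named character vector of small-RNA reads.
#' @param cds CDS DNA string.
#' @param max_mismatch mismatches tolerated per read.
#' @return data.frame: read_id, strand, start, end (1-based CDS
#'   coordinates), mismatches.
#' @export
match_small_rnas <- function(reads, cds, max_mismatch = 2L) {
  subj <- Biostrings::DNAString(cds)
  out <- NULL
  for (ri in seq_along(reads)) {
    for (strand in c("+", "-")) {
      pat <- if (strand == "+") reads[[ri]] else revcomp(reads[[ri]])
      m <- Biostrings::matchPattern(Biostrings::DNAString(pat), subj,
                                    max.mismatch = max_mismatch)
      if (length(m) == 0L) next
      st <- IRanges::start(m@ranges)
      for (k in seq_along(st)) {
        mm <- Biostrings::neditStartingAt(Biostrings::DNAString(pat), subj,
                                          starting.at = st[k])
        out <- rbind(out, data.frame(
          read_id = names(reads)[ri], strand = strand, start = st[k],
          end = IRanges::end(m@ranges)[k], mismatches = mm,
          stringsAsFactors = FALSE))
      }
    }
  }
  if (is.null(out)) {
    out <- data.frame(read_id = character(0), strand = character(0),
                      start = integer(0), end = integer(0),
                      mismatches = integer(0), stringsAsFactors = FALSE)
  }
  out
}
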