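## Related empty sites: paralogous loci carrying an insertion's flanks but
## not the element — evidence of the pre-insertion state or of excision.

#' Extract the flanking sequences of an element copy
#'
#' Flanks exclude the TA target-site duplications (left flank ends just
#' before the left TA; right flank starts just after the right TA).
#'
#' @param genome named character vector of contigs.
#' @param copy list/row with `contig`, `start`, `end` (1-based inclusive).
#' @param L flank length in bp (> 0); flanks running off the contig are
#'   truncated with a warning.
#' @return list with `left` and `right` flank strings.
#' @export
extract_flanks <- function(genome, copy, L = 100L) {
  if (L <= 0L) stop("flank length must be positive")
  g <- genome[[copy$contig]]
  ls <- copy$start - 2L - L
  if (ls < 1L) {
    warning("left flank truncated at contig start")
    ls <- 1L
  }
  re <- copy$end + 2L + L
  if (re > nchar(g)) {
    warning("right flank truncated at contig end")
    re <- nchar(g)
  }
  list(left = substr(g, ls, copy$start - 3L),
       right = substr(g, copy$end + 3L, re))
}

## Fraction of A/T bases.
at_fraction <- function(x) mean(chars(x) %in% c("A", "T"))

## Shannon entropy (bits) of overlapping dinucleotides.
dinucleotide_entropy <- function(x) {
  if (nchar(x) < 2L) return(0)
  d <- substring(x, 1:(nchar(x) - 1L), 2:nchar(x))
  p <- table(d) / length(d)
  -sum(p * log2(p))
}

## Does the junction look like a tandem duplication of a short (1-4 bp)
## microsatellite unit, e.g. "TATA" = duplicated "TA"?
has_microsat_duplication <- function(junction) {
  n <- nchar(junction)
  for (u in 1:4) {
    if (n == 2L * u &&
        substr(junction, 1L, u) == substr(junction, u + 1L, 2L * u))
      return(TRUE)
  }
  FALSE
}

#' Classify a related empty site
#'
#' AT-rich simple-repeat context takes precedence: flanks with A/T fraction
#' at or above `at_threshold` and dinucleotide entropy below
#' `entropy_threshold` are called `at_rich_repeat` (such matches likely
#' reflect repeat homology rather than a specific pre-insertion paralog).
#' Otherwise a junction of exactly "TA" marks the pre-insertion state; a
#' junction of "TA" plus 1-10 extra bases marks an excision footprint;
#' anything else is `none`.
#'
#' @param record list/row with `junction`, `at_fraction` and `entropy` (of
#'   the query flanks).
#' @param at_threshold A/T fraction required for the simple-repeat call.
#' @param entropy_threshold dinucleotide entropy bound in bits; random DNA
#'   sits near 3.9 bits while short-unit simple repeats, even with a few
#'   percent of point mutations, stay below ~2.7.
#' @return one of "at_rich_repeat", "pre_insertion", "excision_footprint",
#'   "none".
#' @export
classify_res <- function(record, at_threshold = 0.8,
                         entropy_threshold = 3.0) {
  if (!is.na(record$at_fraction) && record$at_fraction >= at_threshold &&
      !is.na(record$entropy) && record$entropy < entropy_threshold)
    return("at_rich_repeat")
  jn <- record$junction
  if (jn == "TA") return("pre_insertion")
  if (startsWith(jn, "TA") && nchar(jn) >= 3L && nchar(jn) <= 12L)
    return("excision_footprint")
  "none"
}

#' Search the genome for related empty sites of one element
#'
#' Both flanks are matched against the genome allowing a
#' `1 - min_identity` mismatch fraction; co-linear left/right matches
#' separated by 0-`max_junction` bp define a candidate RES, classified by
#' [classify_res()]. Matches overlapping the element's own locus (with its
#' flanks) or any interval in `exclude` are discarded; near-duplicate
#' records from repetitive flanks are collapsed to the best identity per
#' locus.
#'
#' @param genome named character vector of contigs.
#' @param flanks list with `left`/`right` from [extract_flanks()].
#' @param self_locus optional list/row with `contig`, `start`, `end` of the
#'   element itself.
#' @param exclude optional data.frame (contig, start, end) of intervals RES
#'   matches may not overlap, e.g. all annotated family members.
#' @param min_identity minimum flank match identity (fraction).
#' @param max_junction maximum junction length in bp.
#' @param at_threshold,entropy_threshold passed to [classify_res()].
#' @return data.frame of RES records: contig, left/right match intervals,
#'   junction, identity, at_fraction, entropy, class, microsat_dup.
#' @export
search_res <- function(genome, flanks, self_locus = NULL, exclude = NULL,
                       min_identity = 0.8, max_junction = 50L,
                       at_threshold = 0.8, entropy_threshold = 3.0) {
  Ll <- nchar(flanks$left); Lr <- nchar(flanks$right)
  at <- at_fraction(paste0(flanks$left, flanks$right))
  ent <- dinucleotide_entropy(paste0(flanks$left, flanks$right))
  lp <- Biostrings::DNAString(flanks$left)
  rp <- Biostrings::DNAString(flanks$right)
  out <- NULL
  for (ctg in names(genome)) {
    g <- Biostrings::DNAString(genome[[ctg]])
    ml <- Biostrings::matchPattern(lp, g,
                                   max.mismatch = floor((1 - min_identity) * Ll))
    mr <- Biostrings::matchPattern(rp, g,
                                   max.mismatch = floor((1 - min_identity) * Lr))
    if (length(ml) == 0L || length(mr) == 0L) next
    lst <- IRanges::start(ml@ranges); led <- IRanges::end(ml@ranges)
    rst <- IRanges::start(mr@ranges); red <- IRanges::end(mr@ranges)
    for (i in seq_along(lst)) {
      js <- which(rst > led[i] & rst <= led[i] + max_junction + 1L)
      for (j in js) {
        cand_start <- lst[i]; cand_end <- red[j]
        if (!is.null(self_locus) && ctg == self_locus$contig &&
            max(self_locus$start - 2L - Ll, cand_start) <=
            min(self_locus$end + 2L + Lr, cand_end)) next
        if (!is.null(exclude) &&
            any(exclude$contig == ctg &
                pmax(exclude$start, cand_start) <= pmin(exclude$end, cand_end)))
          next
        junction <- if (rst[j] == led[i] + 1L) "" else
          substr(genome[[ctg]], led[i] + 1L, rst[j] - 1L)
        id_l <- 1 - Biostrings::neditStartingAt(lp, g, starting.at = lst[i]) / Ll
        id_r <- 1 - Biostrings::neditStartingAt(rp, g, starting.at = rst[j]) / Lr
        rec <- data.frame(contig = ctg,
                          left_start = lst[i], left_end = led[i],
                          right_start = rst[j], right_end = red[j],
                          junction = junction,
                          identity = 100 * (id_l + id_r) / 2,
                          at_fraction = at, entropy = ent,
                          stringsAsFactors = FALSE)
        rec$class <- classify_res(rec, at_threshold, entropy_threshold)
        rec$microsat_dup <- has_microsat_duplication(junction)
        out <- rbind(out, rec)
      }
    }
  }
  if (is.null(out)) return(empty_res_records())
  ## collapse near-duplicate loci (repetitive flanks): best identity wins
  out <- out[order(-out$identity, out$contig, out$left_start), , drop = FALSE]
  keep <- logical(nrow(out))
  for (i in seq_len(nrow(out))) {
    mid <- (out$left_start[i] + out$right_end[i]) / 2
    prev <- which(keep & out$contig == out$contig[i])
    if (!length(prev) ||
        all(abs((out$left_start[prev] + out$right_end[prev]) / 2 - mid) > 50))
      keep[i] <- TRUE
  }
  out <- out[keep, , drop = FALSE]
  out <- out[order(out$contig, out$left_start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

empty_res_records <- function() {
  data.frame(contig = character(0), left_start = integer(0),
             left_end = integer(0), right_start = integer(0),
             right_end = integer(0), junction = character(0),
             identity = numeric(0), at_fraction = numeric(0),
             entropy = numeric(0), class = character(0),
             microsat_dup = logical(0), stringsAsFactors = FALSE)
}

#' Find and classify RESs for every member of a family
#'
#' @param genome named character vector of contigs.
#' @param members member data.frame (contig, start, end; optional copy_id).
#' @param L flank length in bp.
#' @param ... passed to [search_res()].
#' @return data.frame of RES records with a `copy_id` column.
#' @export
family_res_report <- function(genome, members, L = 100L, ...) {
  ids <- if ("copy_id" %in% names(members)) members$copy_id
         else sprintf("copy%03d", seq_len(nrow(members)))
  out <- NULL
  for (i in seq_len(nrow(members))) {
    fl <- suppressWarnings(extract_flanks(genome, members[i, ], L))
    res <- search_res(genome, fl, self_locus = members[i, ],
                      exclude = members[, c("contig", "start", "end")], ...)
    if (nrow(res)) {
      res <- cbind(copy_id = ids[i], res, stringsAsFactors = FALSE)
      out <- rbind(out, res)
    }
  }
  if (is.null(out))
    out <- cbind(copy_id = character(0), empty_res_records())
  out
}
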