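## Family alignment, consensus, divergence profiles, and molecular-clock
## dating of amplification bursts.

#' Center-star multiple alignment of family members
#'
#' Each member is globally aligned to the exemplar (center); alignments are
#' merged by propagating, for every exemplar position, the maximum insertion
#' length observed in any member ("once a gap, always a gap"). Deterministic
#' for fixed inputs.
#'
#' @param members character vector of DNA (or protein) sequences; names are
#'   used as row ids.
#' @param exemplar_index index of the center sequence.
#' @param type "dna" or "protein" (chooses the substitution matrix).
#' @return list of class `family_msa`: `ids`, `rows` (equal-length aligned
#'   strings), `exemplar_index`.
#' @export
build_msa <- function(members, exemplar_index = 1L, type = c("dna", "protein")) {
  type <- match.arg(type)
  if (length(members) < 2L) stop("need at least 2 members")
  ids <- names(members)
  if (is.null(ids)) ids <- paste0("m", seq_along(members))
  mat <- if (type == "dna") dna_submat() else blosum62()
  as_x <- if (type == "dna") Biostrings::DNAString else Biostrings::AAString
  center <- members[[exemplar_index]]
  m <- nchar(center)
  others <- setdiff(seq_along(members), exemplar_index)
  ## per member: aligned char per center position + insertions after pos 0..m
  per <- vector("list", length(members))
  per[[exemplar_index]] <- list(al = chars(center),
                                ins = rep("", m + 1L))
  for (i in others) {
    aln <- Biostrings::pairwiseAlignment(
      as_x(members[[i]]), as_x(center), type = "global",
      substitutionMatrix = mat, gapOpening = 8, gapExtension = 2)
    rows <- alignment_rows(aln)
    al <- character(m); ins <- rep("", m + 1L)
    spos <- 0L
    for (k in seq_along(rows$s)) {
      if (rows$s[k] == "-") {
        ins[spos + 1L] <- paste0(ins[spos + 1L], rows$p[k])
      } else {
        spos <- spos + 1L
        al[spos] <- rows$p[k]
      }
    }
    per[[i]] <- list(al = al, ins = ins)
  }
  maxins <- do.call(pmax, c(lapply(per, function(x) nchar(x$ins)),
                            list(rep(0L, m + 1L))))
  pad <- function(s, w) paste0(s, strrep("-", w - nchar(s)))
  rows_out <- vapply(per, function(x) {
    pieces <- character(2L * m + 1L)
    pieces[1L] <- pad(x$ins[1L], maxins[1L])
    for (j in seq_len(m)) {
      pieces[2L * j] <- x$al[j]
      pieces[2L * j + 1L] <- pad(x$ins[j + 1L], maxins[j + 1L])
    }
    paste(pieces, collapse = "")
  }, character(1))
  stopifnot(length(unique(nchar(rows_out))) == 1L)
  structure(list(ids = ids, rows = setNames(rows_out, ids),
                 exemplar_index = exemplar_index),
            class = "family_msa")
}

#' Majority consensus from a family alignment
#'
#' Per-column majority base; columns whose majority character is a gap are
#' omitted; base ties are broken toward the exemplar's residue when it is
#' among the tied bases, otherwise alphabetically.
#'
#' @param msa a `family_msa` from [build_msa()].
#' @return consensus sequence (character string, no gaps).
#' @export
consensus_from_msa <- function(msa) {
  m <- do.call(rbind, strsplit(msa$rows, "", fixed = TRUE))
  n <- nrow(m)
  ex <- m[msa$exemplar_index, ]
  cons <- character(0)
  for (j in seq_len(ncol(m))) {
    col <- m[, j]
    gaps <- sum(col == "-")
    if (gaps > n / 2) next
    tab <- table(col[col != "-"])
    top <- names(tab)[tab == max(tab)]
    cons <- c(cons, if (ex[j] %in% top) ex[j] else sort(top)[1L])
  }
  paste(cons, collapse = "")
}

#' Divergence of one copy from the family consensus
#'
#' Global pairwise alignment; similarity is identities over alignment
#' columns after trimming terminal-gap columns (internal gap columns count
#' as mismatches); divergence is its complement in percent.
#'
#' @param copy,consensus DNA character strings.
#' @return divergence in percent.
#' @export
copy_divergence <- function(copy, consensus) {
  if (nchar(copy) == 0L || nchar(consensus) == 0L)
    stop("empty sequence")
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(copy), Biostrings::DNAString(consensus),
    type = "global", substitutionMatrix = dna_submat(),
    gapOpening = 8, gapExtension = 2)
  rows <- alignment_rows(aln)
  tr <- trim_terminal_gaps(rows$p, rows$s)
  ncol <- length(tr$p)
  if (ncol == 0L) stop("alignment empty after trimming")
  ident <- sum(tr$p == tr$s & tr$p != "-")
  100 - 100 * ident / ncol
}

#' Summarize a family's divergence distribution
#'
#' Bins individual divergences into 0.5% bins `[0, 0.5), [0.5, 1.0), ...`,
#' and reports mean, SD, SE, the binned histogram, the modal bin (ties to
#' the lower divergence) and the overall similarity (100 - mean).
#'
#' @param divs numeric vector of per-copy divergences in percent.
#' @param bin_width histogram bin width in percentage points.
#' @return list of class `divergence_profile`: `divs`, `n`, `mean`, `sd`,
#'   `se`, `bins` (data.frame bin_center, count), `modal_bin_center`,
#'   `overall_similarity`.
#' @export
divergence_profile <- function(divs, bin_width = 0.5) {
  if (length(divs) == 0L) stop("no divergence values")
  stopifnot(all(divs >= 0), all(divs <= 100))
  idx <- pmin(floor(divs / bin_width), floor(100 / bin_width) - 1L)
  all_idx <- 0:max(idx)
  counts <- vapply(all_idx, function(k) sum(idx == k), integer(1))
  centers <- (all_idx + 0.5) * bin_width
  modal <- centers[which.max(counts)]  # first max = lower divergence
  m <- mean(divs); s <- stats::sd(divs)
  structure(list(divs = divs, n = length(divs), mean = m, sd = s,
                 se = if (length(divs) > 1L) s / sqrt(length(divs)) else NA_real_,
                 bins = data.frame(bin_center = centers, count = counts),
                 modal_bin_center = modal,
                 overall_similarity = 100 - m),
            class = "divergence_profile")
}

#' Molecular clock model
#'
#' @param rate percent sequence divergence per million years (> 0);
#'   default 1, the rate commonly adopted for moss TE dating.
#' @return list of class `clock_model`.
#' @export
clock_model <- function(rate = 1.0) {
  stopifnot(rate > 0)
  structure(list(rate = rate), class = "clock_model")
}

#' Date the amplification burst of a family
#'
#' The age of the dominant amplification burst is the modal divergence bin
#' center divided by the clock rate.
#'
#' @param profile a [divergence_profile()].
#' @param clock a [clock_model()].
#' @return age in million years.
#' @export
amplification_age <- function(profile, clock = clock_model()) {
  profile$modal_bin_center / clock$rate
}

#' Compare two transposase proteins
#'
#' Global BLOSUM62 alignment; identity is identical pairs over alignment
#' columns; positives are residue pairs with a positive substitution score
#' over alignment columns.
#'
#' @param proteinA,proteinB protein character strings.
#' @return list: identity_pct, identical, positive_pct, positives,
#'   aligned_length (alignment columns).
#' @export
interfamily_protein_comparison <- function(proteinA, proteinB) {
  mat <- blosum62()
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(proteinA), Biostrings::AAString(proteinB),
    type = "global", substitutionMatrix = mat,
    gapOpening = 10, gapExtension = 1)
  rows <- alignment_rows(aln)
  ncol <- length(rows$p)
  both <- rows$p != "-" & rows$s != "-"
  ident <- sum(both & rows$p == rows$s)
  pos <- sum(both & mat[cbind(rows$p[both], rows$s[both])] > 0)
  list(identity_pct = 100 * ident / ncol, identical = ident,
       positive_pct = 100 * pos / ncol, positives = pos,
       aligned_length = ncol)
}

#' Full divergence analysis of a retrieved family
#'
#' Builds the center-star alignment, derives the consensus, computes each
#' member's divergence from the consensus, and dates the modal burst.
#'
#' @param members named character vector of member sequences.
#' @param exemplar_index center sequence for the alignment.
#' @param clock a [clock_model()].
#' @return list: `msa`, `consensus`, `profile`, `age_myr`.
#' @export
analyze_family <- function(members, exemplar_index = 1L,
                           clock = clock_model()) {
  msa <- build_msa(members, exemplar_index)
  cons <- consensus_from_msa(msa)
  divs <- vapply(members, copy_divergence, numeric(1), consensus = cons)
  prof <- divergence_profile(divs)
  list(msa = msa, consensus = cons, profile = prof,
       age_myr = amplification_age(prof, clock))
}
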