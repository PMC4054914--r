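## Element characterization: TIR pair, TSD verification, ORF discovery,
## and catalytic-triad location/classification.

#' Six-frame conceptual translation
#'
#' Frames 1-3 are read from the plus strand at offsets 0/1/2; frames 4-6
#' from the reverse complement at offsets 0/1/2. Ambiguous codons translate
#' to X; stop codons are retained as `*` markers.
#'
#' @param contig DNA character string.
#' @return named character vector of 6 peptides (`f1`..`f6`).
#' @export
six_frame_translate <- function(contig) {
  rc <- revcomp(contig)
  setNames(c(vapply(0:2, function(o) translate_frame(contig, o), character(1)),
             vapply(0:2, function(o) translate_frame(rc, o), character(1))),
           paste0("f", 1:6))
}

#' Detect the terminal inverted repeat of an element
#'
#' Finds the TIR length L in `[min_tir, max_tir]` maximizing the pairing
#' score `matches - 2 * mismatches` between the element prefix of length L
#' and the reverse complement of its suffix of length L, subject to
#' `mismatches <= mismatch_frac * L`. Ties go to the smaller L (a repeat is
#' not extended by non-pairing sequence).
#'
#' @param element DNA character string (length >= 2 * min_tir).
#' @param min_tir,max_tir TIR length search range in bp.
#' @param mismatch_frac maximum tolerated mismatch fraction within the TIR.
#' @return list with `tir_length` and `mismatches`, or NULL if no length in
#'   range qualifies.
#' @export
detect_tirs <- function(element, min_tir = 12L, max_tir = 100L,
                        mismatch_frac = 0.1) {
  n <- nchar(element)
  if (n < 2L * min_tir) stop("element shorter than 2 * min_tir")
  hi <- min(max_tir, n %/% 2L)
  a <- chars(substr(element, 1L, hi))
  b <- chars(substr(revcomp(element), 1L, hi))
  mism <- cumsum(a != b)
  L <- seq_len(hi)
  valid <- L >= min_tir & mism <= mismatch_frac * L
  if (!any(valid)) return(NULL)
  score <- L - 3L * mism
  cand <- which(valid)
  best <- cand[which.max(score[cand])]  # which.max takes the first = smaller L
  list(tir_length = best, mismatches = unname(mism[best]))
}

#' Verify the TA target-site duplication of a genomic copy
#'
#' @param genome named character vector of contigs.
#' @param copy list or one-row data.frame with `contig`, `start`, `end`
#'   (1-based inclusive, element interval excluding the TSDs).
#' @return list with `left`, `right` (2-mers) and `is_TA`.
#' @export
verify_tsd <- function(genome, copy) {
  g <- genome[[copy$contig]]
  if (copy$start - 2L < 1L || copy$end + 2L > nchar(g))
    stop("flank unavailable: copy at contig edge")
  left <- substr(g, copy$start - 2L, copy$start - 1L)
  right <- substr(g, copy$end + 1L, copy$end + 2L)
  list(left = left, right = right, is_TA = left == "TA" && right == "TA")
}

#' Find the longest open reading frame of an element
#'
#' Scans all three (or six) frames for start-to-stop ORFs; an ORF reaching
#' the end of a frame without a stop codon is reported with
#' `stop_terminated = FALSE`. Ties are broken toward the lower start
#' coordinate, then the plus strand.
#'
#' @param element DNA character string.
#' @param both_strands scan the reverse complement too.
#' @param min_aa minimum protein length in aa.
#' @return list with 1-based inclusive `start`/`end` (plus-strand element
#'   coordinates, covering the codons and the stop codon when present),
#'   `strand`, `protein`, `stop_terminated` and `intact`; NULL if no ORF of
#'   at least `min_aa` exists.
#' @export
find_longest_orf <- function(element, both_strands = TRUE, min_aa = 100L) {
  n <- nchar(element)
  best <- NULL
  consider <- function(cand) {
    if (is.null(cand)) return()
    if (is.null(best) ||
        nchar(cand$protein) > nchar(best$protein) ||
        (nchar(cand$protein) == nchar(best$protein) &&
         (cand$start < best$start ||
          (cand$start == best$start && cand$strand == "+" &&
           best$strand == "-")))) best <<- cand
  }
  scan_strand <- function(dna, strand) {
    for (off in 0:2) {
      pep <- translate_frame(dna, off)
      if (nchar(pep) == 0L) next
      pc <- chars(pep)
      stops <- c(which(pc == "*"), length(pc) + 1L)
      seg_start <- 1L
      for (sp in stops) {
        seg <- pc[seg_start:(sp - 1L)]
        m <- which(seg == "M")
        if (length(m) > 0L) {
          aa1 <- seg_start + m[1L] - 1L          # first M, peptide coords
          prot <- paste(pc[aa1:(sp - 1L)], collapse = "")
          terminated <- sp <= length(pc)
          nt1 <- off + 3L * (aa1 - 1L) + 1L      # strand-local coords
          nt2 <- off + 3L * (sp - 1L) + ifelse(terminated, 3L, 0L)
          if (strand == "+") {
            st <- nt1; en <- nt2
          } else {
            st <- n - nt2 + 1L; en <- n - nt1 + 1L
          }
          consider(list(start = st, end = en, strand = strand,
                        protein = prot, stop_terminated = terminated))
        }
        seg_start <- sp + 1L
        if (seg_start > length(pc)) break
      }
    }
  }
  scan_strand(element, "+")
  if (both_strands) scan_strand(revcomp(element), "-")
  if (is.null(best) || nchar(best$protein) < min_aa) return(NULL)
  best$intact <- best$stop_terminated && nchar(best$protein) >= min_aa
  best
}

#' Synthetic transposase reference set for triad mapping
#'
#' Reads the packaged synthetic reference transposases (one designed
#' exemplar per spacing class DD34E, DD34D, DD35E, DD37D, DD37E, DD39D)
#' together with their annotated triad positions. These are generated
#' proteins sharing the designer's conserved blocks, not database sequences;
#' users can supply their own annotated references in the same format.
#'
#' @param fasta,tsv optional paths overriding the packaged files (FASTA of
#'   proteins; TSV with columns name, p1, p2, p3, class).
#' @return data.frame with columns name, protein, p1, p2, p3, class.
#' @export
triad_reference_set <- function(fasta = NULL, tsv = NULL) {
  if (is.null(fasta))
    fasta <- system.file("extdata", "synthetic_transposase_refs.fasta",
                         package = "tlemine", mustWork = TRUE)
  if (is.null(tsv))
    tsv <- system.file("extdata", "synthetic_transposase_refs.tsv",
                       package = "tlemine", mustWork = TRUE)
  aa <- Biostrings::readAAStringSet(fasta)
  meta <- read.table(tsv, header = TRUE, sep = "\t",
                     stringsAsFactors = FALSE)
  meta$protein <- as.character(aa)[meta$name]
  meta[, c("name", "protein", "p1", "p2", "p3", "class")]
}

## Map 1-based subject (reference) positions through a local pairwise
## alignment to pattern (query) positions; NA where unaligned or gapped.
map_through_alignment <- function(aln, subject_positions) {
  rows <- alignment_rows(aln)
  qpos <- Biostrings::start(Biostrings::pattern(aln)) - 1L
  spos <- Biostrings::start(Biostrings::subject(aln)) - 1L
  out <- rep(NA_integer_, length(subject_positions))
  for (k in seq_along(rows$p)) {
    if (rows$p[k] != "-") qpos <- qpos + 1L
    if (rows$s[k] != "-") {
      spos <- spos + 1L
      hit <- which(subject_positions == spos)
      if (length(hit) && rows$p[k] != "-") out[hit] <- qpos
    }
  }
  out
}

#' Locate the catalytic triad of a transposase by reference anchoring
#'
#' Aligns the protein to the best-scoring annotated reference (local
#' alignment, BLOSUM62) and maps the reference's three catalytic positions
#' through the alignment. The annotation is complete when all three map to
#' aspartate/aspartate/(aspartate or glutamate).
#'
#' @param protein query protein character string.
#' @param references data.frame as from [triad_reference_set()].
#' @return list with query triad positions `p1`, `p2`, `p3` (1-based, NA if
#'   unmapped), the mapped `residues`, `spacing12`, `spacing23`,
#'   `class_label` (NA unless complete), `complete`, and the `reference`
#'   name used.
#' @export
locate_triad <- function(protein, references = triad_reference_set()) {
  stopifnot(nrow(references) >= 1L)
  mat <- blosum62()
  q <- Biostrings::AAString(protein)
  best <- NULL
  for (i in seq_len(nrow(references))) {
    aln <- Biostrings::pairwiseAlignment(
      q, Biostrings::AAString(references$protein[i]),
      type = "local", substitutionMatrix = mat,
      gapOpening = 10, gapExtension = 1)
    if (is.null(best) || Biostrings::score(aln) > best$score)
      best <- list(aln = aln, i = i, score = Biostrings::score(aln))
  }
  ref <- references[best$i, ]
  pos <- map_through_alignment(best$aln, c(ref$p1, ref$p2, ref$p3))
  res <- rep(NA_character_, 3L)
  ok <- !is.na(pos)
  res[ok] <- vapply(pos[ok], function(p) substr(protein, p, p), character(1))
  complete <- all(ok) && res[1] == "D" && res[2] == "D" &&
    res[3] %in% c("D", "E") && pos[1] < pos[2] && pos[2] < pos[3]
  s12 <- if (all(ok)) pos[2] - pos[1] - 1L else NA_integer_
  s23 <- if (all(ok)) pos[3] - pos[2] - 1L else NA_integer_
  list(p1 = pos[1], p2 = pos[2], p3 = pos[3], residues = res,
       spacing12 = s12, spacing23 = s23,
       class_label = if (complete) paste0("DD", s23, res[3]) else NA_character_,
       complete = complete, reference = ref$name)
}

#' Is the catalytic triad complete on a (possibly fragmentary) protein?
#'
#' Returns "Y" iff all three catalytic residues map through the reference
#' alignment, are acidic (D/D/[DE]), and the spacing between the second and
#' third residues lies in 31-39 (the known Tc1/mariner spacing range).
#'
#' @inheritParams locate_triad
#' @return "Y" or "N".
#' @export
triad_completeness <- function(protein, references = triad_reference_set()) {
  t <- locate_triad(protein, references)
  if (t$complete && !is.na(t$spacing23) && t$spacing23 >= 31L &&
      t$spacing23 <= 39L) "Y" else "N"
}

#' Annotate one element copy
#'
#' Produces a Table-1-style annotation row: TIR length, TSD, ORF coordinates
#' (1-based inclusive in element coordinates; minus-strand ORFs have
#' start > end), protein length, triad class, triad completeness.
#'
#' @param element element DNA string (TSD excluded).
#' @param id element identifier for the report.
#' @param references triad reference set.
#' @param min_orf_aa minimum ORF length in aa.
#' @return one-row data.frame.
#' @export
annotate_element <- function(element, id = "element",
                             references = triad_reference_set(),
                             min_orf_aa = 100L) {
  tir <- tryCatch(detect_tirs(element), error = function(e) NULL)
  orf <- find_longest_orf(element, both_strands = TRUE, min_aa = min_orf_aa)
  if (is.null(orf)) {
    return(data.frame(id = id,
                      tir_len = if (is.null(tir)) NA_integer_ else tir$tir_length,
                      orf_start = NA_integer_, orf_end = NA_integer_,
                      protein_length = NA_integer_,
                      triad_class = NA_character_, triad_complete = "N",
                      stringsAsFactors = FALSE))
  }
  tri <- locate_triad(orf$protein, references)
  os <- if (orf$strand == "+") orf$start else orf$end
  oe <- if (orf$strand == "+") orf$end else orf$start
  data.frame(id = id,
             tir_len = if (is.null(tir)) NA_integer_ else tir$tir_length,
             orf_start = os, orf_end = oe,
             protein_length = nchar(orf$protein),
             triad_class = tri$class_label,
             triad_complete = triad_completeness(orf$protein, references),
             stringsAsFactors = FALSE)
}

#' Codon count of a 1-based inclusive CDS span
#'
#' For a CDS reported as 1-based inclusive coordinates (minus-strand spans
#' have start > end), the span length divided by three gives the codon
#' count. Whether a printed span includes the terminating stop codon varies
#' between reports, so both the codon count and the translated length
#' (one less when the stop is included) are worth inspecting.
#'
#' @param start,end 1-based inclusive CDS coordinates.
#' @return number of codons in the span.
#' @export
cds_span_codons <- function(start, end) {
  len <- abs(end - start) + 1L
  if (len %% 3L != 0L) warning("CDS span not divisible by 3")
  len %/% 3L
}
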