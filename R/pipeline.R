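## Stage orchestration: simulate / mine / family / res / express / phylo /
## survey, with file I/O and run manifests.

#' Read a (multi-)FASTA genome as a named character vector
#'
#' @param path FASTA file.
#' @return named character vector of contig sequences.
#' @export
read_genome_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  setNames(as.character(x), sub("\\s.*$", "", names(x)))
}

## Orient seq to match the exemplar using shared 12-mer counts (cheap,
## alignment-free; TIR termini are palindromic so interior k-mers decide).
orient_to_exemplar <- function(seq, exemplar, k = 12L) {
  kmers <- function(s) {
    if (nchar(s) < k) return(character(0))
    unique(substring(s, 1:(nchar(s) - k + 1L), k:nchar(s)))
  }
  ex <- kmers(exemplar)
  fwd <- length(intersect(kmers(seq), ex))
  rev <- length(intersect(kmers(revcomp(seq)), ex))
  if (rev > fwd) revcomp(seq) else seq
}

## Group hits into per-element clusters (same contig, gap <= max_gap;
## a disrupted or frameshifted transposase yields several nearby hits for
## one element) and record the neighboring clusters as extension bounds.
cluster_hits <- function(hits, max_gap = 350L) {
  if (nrow(hits) == 0L) {
    hits$left_bound <- integer(0)
    hits$right_bound <- integer(0)
    return(hits)
  }
  out <- NULL
  for (ctg in unique(hits$contig)) {
    h <- hits[hits$contig == ctg, , drop = FALSE]
    h <- h[order(h$start), , drop = FALSE]
    grp <- cumsum(c(1L, as.integer(h$start[-1L] > cummax(h$end)[-nrow(h)] +
                                     max_gap)))
    cl <- do.call(rbind, lapply(split(h, grp), function(x) {
      b <- x[which.max(x$score), , drop = FALSE]  # representative hit
      b$start <- min(x$start); b$end <- max(x$end)
      b
    }))
    cl <- cl[order(cl$start), , drop = FALSE]
    k <- nrow(cl)
    cl$left_bound <- c(NA_integer_, cl$end[-k] + 1L)
    cl$right_bound <- c(cl$start[-1L] - 1L, NA_integer_)
    out <- rbind(out, cl)
  }
  rownames(out) <- NULL
  out
}

## Consensus-anchored boundary refinement: among TA-preceded candidate
## starts (and TA-followed candidate ends) around a hit cluster, pick the
## orientation-consistent pair whose flanks best match the consensus
## termini (minimum edit distance over `anchor` bp, minimized over a small
## window-length offset so indel shifts are not double-charged), with the
## implied length within [0.3, 1.5] x the consensus length. This calls
## exact boundaries even when a copy's own TIR has decayed beyond de-novo
## detection.
refine_boundaries <- function(genome, hit, consensus, anchor = 100L,
                              max_edit_frac = 0.3, max_extension = 5000L,
                              left_bound = NULL, right_bound = NULL) {
  g <- genome[[hit$contig]]
  n <- nchar(g)
  nc <- nchar(consensus)
  anchor <- min(anchor, nc %/% 2L)
  if (is.null(left_bound) || is.na(left_bound)) left_bound <- 1L
  if (is.null(right_bound) || is.na(right_bound)) right_bound <- n
  ws <- max(1L, hit$start - max_extension, left_bound)
  we <- min(n, hit$end + max_extension, right_bound)
  R <- substr(g, ws, we)
  hs <- hit$start - ws + 1L
  he <- hit$end - ws + 1L
  ta <- stri_locate_all_fixed(R, "TA")[[1]][, 1]
  ta <- ta[!is.na(ta)]
  cl <- substr(consensus, 1L, anchor)
  cr <- substr(consensus, nc - anchor + 1L, nc)
  score_side <- function(cands, ref, leftish) {
    vapply(cands, function(x)
      min(vapply(-4:4, function(dl) {
        if (leftish) {
          e <- x + anchor - 1L + dl
          if (e > nchar(R)) return(Inf)
          utils::adist(ref, substr(R, x, e))[1L, 1L]
        } else {
          s0 <- x - anchor + 1L - dl
          if (s0 < 1L) return(Inf)
          utils::adist(ref, substr(R, s0, x))[1L, 1L]
        }
      }, numeric(1))), numeric(1))
  }
  lefts <- ta[ta + 2L <= hs] + 2L
  rights <- ta[ta - 1L >= he] - 1L
  if (length(lefts) == 0L || length(rights) == 0L) return(NULL)
  best <- NULL
  for (orient in c("+", "-")) {
    lref <- if (orient == "+") cl else revcomp(cr)
    rref <- if (orient == "+") cr else revcomp(cl)
    dl <- score_side(lefts, lref, TRUE)
    dr <- score_side(rights, rref, FALSE)
    okl <- dl <= max_edit_frac * anchor
    okr <- dr <= max_edit_frac * anchor
    if (!any(okl) || !any(okr)) next
    for (i in which(okl)) for (j in which(okr)) {
      len <- rights[j] - lefts[i] + 1L
      if (len < 0.3 * nc || len > 1.5 * nc) next
      d <- dl[i] + dr[j]
      if (is.null(best) || d < best$d ||
          (d == best$d && abs(len - nc) < abs(best$len - nc)))
        best <- list(a = lefts[i], b = rights[j], d = d, len = len)
    }
  }
  if (is.null(best)) return(NULL)
  list(start = ws + best$a - 1L, end = ws + best$b - 1L)
}

#' Mine a genome for TLE copies of one family
#'
#' Two-stage miner. Stage 1: translated homology search, hit clustering,
#' and de-novo extension of each cluster to a TIR/TA-bounded element; a
#' provisional consensus is built from these candidates. Stage 2: every
#' cluster's boundaries are refined by anchoring the consensus termini
#' (minimum-edit TA-preceded/TA-followed positions), which calls exact
#' boundaries even for copies whose own TIRs have decayed; exact-terminal
#' member retrieval against the consensus adds ORF-free copies. The final
#' member set is re-aligned, the consensus rebuilt, members flagged for
#' full length and intact ORF. Stage counts (hits, candidates, members,
#' full-length, intact-ORF) are reported via `message()`.
#'
#' @param genome named character vector of contigs.
#' @param query_protein transposase query protein.
#' @param min_score_frac,max_extension,end_len tuning knobs passed through
#'   to the stage functions.
#' @param min_orf_aa minimum ORF length for annotation.
#' @return list: `hits`, `members` (data.frame with copy_id, coordinates,
#'   full_length, orf_aa, orf_intact), `consensus`, `msa`, `profile`,
#'   `age_myr`, `family_orf_aa`.
#' @export
mine_elements <- function(genome, query_protein, min_score_frac = 0.5,
                          max_extension = 5000L, end_len = 33L,
                          min_orf_aa = 100L) {
  hits <- search_transposase(genome, query_protein,
                             min_score_frac = min_score_frac)
  message("hits: ", nrow(hits))
  clusters <- cluster_hits(hits)
  stage1 <- vector("list", nrow(clusters))
  cand <- NULL
  for (i in seq_len(nrow(clusters))) {
    el <- extend_to_element(genome, clusters[i, ],
                            max_extension = max_extension,
                            left_bound = clusters$left_bound[i],
                            right_bound = clusters$right_bound[i])
    stage1[[i]] <- el
    if (!is.null(el)) cand <- rbind(cand, el)
  }
  message("candidates: ", if (is.null(cand)) 0L else nrow(cand))
  if (is.null(cand) || nrow(cand) == 0L) {
    return(list(hits = hits, members = cbind(copy_id = character(0),
                                             empty_members()),
                consensus = NULL, msa = NULL, profile = NULL,
                age_myr = NA_real_, family_orf_aa = NA_integer_))
  }
  ## provisional consensus from the de-novo candidates
  lens <- cand$end - cand$start + 1L
  exi <- order(abs(lens - stats::median(lens)), cand$start)[1L]
  exseq <- cand$seq[exi]
  cons0 <- if (nrow(cand) >= 2L) {
    seqs0 <- vapply(cand$seq, orient_to_exemplar, character(1),
                    exemplar = exseq, USE.NAMES = FALSE)
    consensus_from_msa(build_msa(setNames(seqs0, seq_along(seqs0)), exi))
  } else exseq
  ## stage 2: consensus-anchored member discovery across the whole genome
  ## (robust to decayed termini and to copies whose transposase yielded no
  ## hit), then per-cluster boundary refinement for anything left over
  members <- anchor_scan_members(genome, cons0)
  covered <- function(ctg, st, en) {
    nrow(members) > 0L && any(members$contig == ctg &
                                pmax(members$start, st) <=
                                  pmin(members$end, en))
  }
  for (i in seq_len(nrow(clusters))) {
    if (covered(clusters$contig[i], clusters$start[i], clusters$end[i]))
      next
    rb <- refine_boundaries(genome, clusters[i, ], cons0,
                            max_extension = max_extension,
                            left_bound = clusters$left_bound[i],
                            right_bound = clusters$right_bound[i])
    if (is.null(rb) && is.null(stage1[[i]])) next
    st <- if (is.null(rb)) stage1[[i]]$start else rb$start
    en <- if (is.null(rb)) stage1[[i]]$end else rb$end
    g <- genome[[clusters$contig[i]]]
    sq <- orient_to_exemplar(substr(g, st, en), cons0)
    tir <- tryCatch(detect_tirs(sq), error = function(e) NULL)
    members <- rbind(members, data.frame(
      contig = clusters$contig[i], start = st, end = en,
      strand = clusters$strand[i], seq = sq,
      tir_length = if (is.null(tir)) NA_integer_ else tir$tir_length,
      tir_mismatches = if (is.null(tir)) NA_integer_ else tir$mismatches,
      terminal4_left = substr(sq, 1L, 4L),
      terminal4_right = substr(sq, nchar(sq) - 3L, nchar(sq)),
      tsd_left = if (st >= 3L) substr(g, st - 2L, st - 1L) else NA_character_,
      tsd_right = if (en + 2L <= nchar(g)) substr(g, en + 1L, en + 2L)
                  else NA_character_,
      stringsAsFactors = FALSE))
  }
  ## exact-terminal retrieval against the consensus adds anything missed
  extra <- retrieve_members(genome, cons0, end_len = end_len)
  for (i in seq_len(nrow(extra))) {
    if (!covered(extra$contig[i], extra$start[i], extra$end[i])) {
      e <- extra[i, , drop = FALSE]
      e$seq <- orient_to_exemplar(e$seq, cons0)
      members <- rbind(members, e[, names(members)])
    }
  }
  members <- members[order(members$contig, members$start), , drop = FALSE]
  rownames(members) <- NULL
  members$copy_id <- sprintf("copy%03d", seq_len(nrow(members)))
  message("members: ", nrow(members))
  fam <- NULL
  if (nrow(members) >= 2L) {
    seqs <- setNames(members$seq, members$copy_id)
    lens <- nchar(members$seq)
    exi2 <- order(abs(lens - nchar(cons0)), members$start)[1L]
    fam <- analyze_family(seqs, exemplar_index = exi2)
    members <- flag_full_length(members, fam$consensus)
  } else {
    members$full_length <- NA
  }
  final_cons <- if (is.null(fam)) cons0 else fam$consensus
  orf_aa <- integer(nrow(members))
  for (i in seq_len(nrow(members))) {
    orf <- find_longest_orf(members$seq[i], both_strands = TRUE,
                            min_aa = min_orf_aa)
    orf_aa[i] <- if (is.null(orf)) 0L else nchar(orf$protein)
  }
  members$orf_aa <- orf_aa
  cons_orf <- find_longest_orf(final_cons, both_strands = TRUE,
                               min_aa = min_orf_aa)
  family_orf_aa <- if (!is.null(cons_orf)) nchar(cons_orf$protein) else {
    tab <- table(orf_aa[orf_aa > 0L])
    if (length(tab)) max(as.integer(names(tab)[tab == max(tab)]))
    else NA_integer_
  }
  members$orf_intact <- !is.na(family_orf_aa) &
    orf_aa >= ceiling(0.95 * family_orf_aa)
  message("full-length: ", sum(members$full_length, na.rm = TRUE))
  message("intact-ORF: ", sum(members$orf_intact))
  list(hits = hits, members = members,
       consensus = final_cons,
       msa = if (is.null(fam)) NULL else fam$msa,
       profile = if (is.null(fam)) NULL else fam$profile,
       age_myr = if (is.null(fam)) NA_real_ else fam$age_myr,
       family_orf_aa = family_orf_aa)
}

#' Export mined members as GFF3 and FASTA
#'
#' GFF3 rows have type `terminal_inverted_repeat_element`, 1-based inclusive
#' coordinates and attributes family / tsd / tir_len / full_length.
#'
#' @param members member data.frame from [mine_elements()].
#' @param family family name for the GFF3 attribute.
#' @param gff3,fasta output paths (NULL to skip either).
#' @return invisible NULL.
#' @export
export_members <- function(members, family = "TLE", gff3 = NULL,
                           fasta = NULL) {
  if (!is.null(gff3)) {
    gr <- GenomicRanges::GRanges(
      seqnames = members$contig,
      ranges = IRanges::IRanges(members$start, members$end),
      strand = members$strand)
    gr$source <- "tlemine"
    gr$type <- "terminal_inverted_repeat_element"
    gr$ID <- members$copy_id
    gr$family <- family
    gr$tsd <- paste0(members$tsd_left, "/", members$tsd_right)
    gr$tir_len <- members$tir_length
    gr$full_length <- members$full_length
    rtracklayer::export(gr, gff3, format = "GFF3")
  }
  if (!is.null(fasta)) {
    Biostrings::writeXStringSet(
      Biostrings::DNAStringSet(setNames(members$seq, members$copy_id)),
      fasta)
  }
  invisible(NULL)
}

write_manifest <- function(dir, stage, inputs, params, seed = NULL) {
  jsonlite::write_json(
    list(stage = stage, inputs = inputs, params = params, seed = seed),
    file.path(dir, paste0(stage, "_manifest.json")),
    auto_unbox = TRUE, digits = NA, null = "null")
}

#' Run the simulation stage and write its fixture directory
#'
#' @param config a [sim_config()].
#' @param dir output directory.
#' @return the simulation object, invisibly.
#' @export
run_simulate <- function(config, dir) {
  sim <- simulate_tle_genome(config)
  write_simulation(sim, dir)
  write_manifest(dir, "simulate",
                 inputs = list(),
                 params = list(genome_length = config$genome_length,
                               gc_content = config$gc_content,
                               n_families = length(config$families),
                               n_res_sites = config$n_res_sites),
                 seed = config$seed)
  invisible(sim)
}

#' Run the mining stage from files
#'
#' @param genome_fa genome FASTA path.
#' @param query_fa transposase query protein FASTA path (first record used).
#' @param dir output directory (members GFF3 + FASTA + manifest).
#' @param ... passed to [mine_elements()].
#' @return the [mine_elements()] result, invisibly.
#' @export
run_mine <- function(genome_fa, query_fa, dir, ...) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  genome <- read_genome_fasta(genome_fa)
  q <- as.character(Biostrings::readAAStringSet(query_fa))[[1L]]
  res <- mine_elements(genome, q, ...)
  export_members(res$members, gff3 = file.path(dir, "members.gff3"),
                 fasta = file.path(dir, "members.fa"))
  write_manifest(dir, "mine", inputs = list(genome = genome_fa,
                                            query = query_fa),
                 params = list(...))
  invisible(res)
}

#' Run the family-dynamics stage and write summary tables
#'
#' Writes per-copy divergences, the 0.5%-binned histogram, and a one-row
#' family summary (n, mean, sd, se, overall similarity, modal bin, age).
#'
#' @param members named character vector of member sequences (or FASTA path).
#' @param dir output directory.
#' @param clock a [clock_model()].
#' @return the [analyze_family()] result, invisibly.
#' @export
run_family <- function(members, dir, clock = clock_model()) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (is.character(members) && length(members) == 1L && file.exists(members))
    members <- setNames(as.character(Biostrings::readDNAStringSet(members)),
                        NULL)
  fam <- analyze_family(members, clock = clock)
  p <- fam$profile
  write.table(data.frame(copy_id = names(members), divergence = p$divs),
              file.path(dir, "divergence.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(p$bins, file.path(dir, "histogram.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(data.frame(n = p$n, mean = p$mean, sd = p$sd, se = p$se,
                         overall_similarity = p$overall_similarity,
                         modal_bin_center = p$modal_bin_center,
                         age_myr = fam$age_myr),
              file.path(dir, "family_summary.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write_manifest(dir, "family", inputs = list(n_members = length(members)),
                 params = list(rate = clock$rate))
  invisible(fam)
}

#' Run the RES stage and write the report
#'
#' @param genome named character vector (or FASTA path).
#' @param members member data.frame (contig, start, end, copy_id).
#' @param dir output directory.
#' @param ... passed to [family_res_report()].
#' @return the RES data.frame, invisibly.
#' @export
run_res <- function(genome, members, dir, ...) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (is.character(genome) && length(genome) == 1L && file.exists(genome))
    genome <- read_genome_fasta(genome)
  res <- family_res_report(genome, members, ...)
  write.table(res, file.path(dir, "res_report.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write_manifest(dir, "res", inputs = list(n_members = nrow(members)),
                 params = list())
  invisible(res)
}

#' Run the expression stage and write reports
#'
#' @param members named character vector of member sequences.
#' @param transcripts named character vector of transcripts.
#' @param small_rnas named character vector of small-RNA reads (or NULL).
#' @param cds transposase CDS for small-RNA matching (or NULL).
#' @param family_orf_aa family transposase length in aa.
#' @param dir output directory.
#' @return list(`matches`, `intact`, `srna_hits`), invisibly.
#' @export
run_express <- function(members, transcripts, small_rnas = NULL, cds = NULL,
                        family_orf_aa, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  matches <- map_transcripts(transcripts, members)
  intact <- count_intact_transposase_transcripts(matches, transcripts,
                                                 family_orf_aa)
  matches$full_transposase <- ifelse(
    matches$transcript_id %in% intact$transcript_ids, "Y", "N")
  write.table(matches, file.path(dir, "transcript_report.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  srna <- NULL
  if (!is.null(small_rnas) && !is.null(cds)) {
    srna <- match_small_rnas(small_rnas, cds)
    write.table(srna, file.path(dir, "small_rna_hits.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  }
  write_manifest(dir, "express",
                 inputs = list(n_transcripts = length(transcripts),
                               n_small_rnas = length(small_rnas)),
                 params = list(family_orf_aa = family_orf_aa))
  invisible(list(matches = matches, intact = intact, srna_hits = srna))
}

#' Run the phylogeny stage and write the Newick tree
#'
#' @param proteins named character vector of transposase proteins.
#' @param dir output directory.
#' @param n_replicates bootstrap replicates.
#' @param seed integer seed.
#' @return the [bootstrap_nj()] result, invisibly.
#' @export
run_phylo <- function(proteins, dir, n_replicates = 1000L, seed = 1L) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  res <- bootstrap_nj(proteins, n_replicates = n_replicates, seed = seed)
  write_tree_newick(res$tree, file.path(dir, "transposases.nwk"))
  write.table(as.data.frame(res$distances),
              file.path(dir, "distances.tsv"), sep = "\t", quote = FALSE)
  write_manifest(dir, "phylo", inputs = list(n_proteins = length(proteins)),
                 params = list(n_replicates = n_replicates), seed = seed)
  invisible(res)
}

#' Survey genomes for transposase fragments (Table-1-style)
#'
#' For each merged homology hit locus, the longest ORF of the surrounding
#' region is located, reported in 1-based inclusive genome coordinates
#' (minus-strand CDS rows have start > end), and its conceptual translation
#' is checked for a complete DD34E-type triad. An element call (TIR/TA
#' extension) is attempted but optional — fragments are allowed.
#'
#' @param genome named character vector of contigs.
#' @param query_protein transposase query.
#' @param organism organism label for the rows.
#' @param references triad reference set.
#' @param pad bp of context around each hit scanned for the ORF.
#' @param min_orf_aa minimum reported ORF length.
#' @return data.frame of survey rows: element, organism, accession,
#'   orf_start, orf_end, triad_complete, has_element_call.
#' @export
run_survey <- function(genome, query_protein, organism = "",
                       references = triad_reference_set(), pad = 3000L,
                       min_orf_aa = 100L) {
  hits <- search_transposase(genome, query_protein)
  out <- NULL
  for (i in seq_len(nrow(hits))) {
    h <- hits[i, ]
    g <- genome[[h$contig]]
    rs <- max(1L, h$start - pad)
    re <- min(nchar(g), h$end + pad)
    region <- substr(g, rs, re)
    orf <- find_longest_orf(region, both_strands = TRUE, min_aa = min_orf_aa)
    if (is.null(orf)) next
    el <- extend_to_element(genome, h)
    gs <- rs + orf$start - 1L
    ge <- rs + orf$end - 1L
    if (orf$strand == "-") { tmp <- gs; gs <- ge; ge <- tmp }
    out <- rbind(out, data.frame(
      element = sprintf("%s_hit%02d", h$contig, i),
      organism = organism, accession = h$contig,
      orf_start = gs, orf_end = ge,
      triad_complete = triad_completeness(orf$protein, references),
      has_element_call = !is.null(el),
      stringsAsFactors = FALSE))
  }
  if (is.null(out)) {
    out <- data.frame(element = character(0), organism = character(0),
                      accession = character(0), orf_start = integer(0),
                      orf_end = integer(0), triad_complete = character(0),
                      has_element_call = logical(0), stringsAsFactors = FALSE)
  }
  ## merge duplicate rows per ORF locus
  out <- out[!duplicated(out[, c("accession", "orf_start", "orf_end")]), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}
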