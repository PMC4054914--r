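## Synthetic genomes with planted Tc1-like elements and full ground truth.
##
## The generator emulates the signal structure the mining pipeline assumes:
## a random background genome, element families whose consensus carries
## terminal inverted repeats (TIRs) starting with 5'-CAGT, an internal
## transposase ORF with a DDE/D catalytic triad, copies diverged by
## substitutions and short indels, insertion at genomic "TA" sites with
## target-site duplication, related empty sites, transcripts and small RNAs.

## Fixed conserved blocks flanking the catalytic residues of generated
## transposases. Real Tc1/mariner transposases carry conserved motifs around
## the triad; embedding fixed blocks makes reference-anchored triad mapping
## meaningful on generated proteins.
TRIAD_BLOCKS <- list(
  nterm = "MGKT",
  pre1 = "WVPHEL", post1 = "TGRN",
  pre2 = "KIGLWG", post2 = "AVQH",
  pre3 = "SFQTNN", post3 = "GRLT"
)

## 4-bp buffer placed just inside each terminus; G opposite G can never pair,
## so the designed TIR length is the unique score-maximal inverted repeat.
TIR_BUFFER <- "GGGG"

#' Specify a synthetic TLE family
#'
#' @param name family name.
#' @param element_length consensus element length in bp.
#' @param tir_length TIR length in bp (>= nchar(terminal_motif)).
#' @param terminal_motif 4-nt terminal sequence (default "CAGT", the
#'   Tc1-family terminus; elements end with its reverse complement).
#' @param protein_length transposase length in amino acids.
#' @param triad_class catalytic triad label, e.g. "DD34E" (pattern
#'   `DD<k>{D|E}` where k is the residue count between the second and third
#'   catalytic residues).
#' @param n_copies number of copies to plant.
#' @param p_sub per-site substitution probability applied to each copy.
#' @param p_indel per-site indel event probability (lengths 1-3, uniform).
#' @param frac_orf_disrupted fraction of copies receiving a targeted internal
#'   stop codon before divergence is applied.
#' @return a `family_spec` list.
#' @export
family_spec <- function(name, element_length = 1584L, tir_length = 33L,
                        terminal_motif = "CAGT", protein_length = 338L,
                        triad_class = "DD34E", n_copies = 10L,
                        p_sub = 0.02, p_indel = 0,
                        frac_orf_disrupted = 0) {
  stopifnot(nchar(terminal_motif) == 4L,
            tir_length >= nchar(terminal_motif),
            element_length >= 2L * tir_length + 3L * (protein_length + 1L),
            p_sub >= 0, p_sub < 1, p_indel >= 0, p_indel < 1,
            frac_orf_disrupted >= 0, frac_orf_disrupted <= 1)
  parse_triad_class(triad_class)  # validates pattern
  structure(list(name = name, element_length = as.integer(element_length),
                 tir_length = as.integer(tir_length),
                 terminal_motif = toupper(terminal_motif),
                 protein_length = as.integer(protein_length),
                 triad_class = triad_class, n_copies = as.integer(n_copies),
                 p_sub = p_sub, p_indel = p_indel,
                 frac_orf_disrupted = frac_orf_disrupted),
            class = "family_spec")
}

#' Simulation configuration
#'
#' @param genome_length background genome length in bp.
#' @param gc_content background GC fraction in [0, 1].
#' @param families list of [family_spec()] objects.
#' @param n_res_sites number of related-empty-site loci to plant (spread over
#'   modes pre_insertion / excision_footprint / at_rich).
#' @param seed integer seed; fully determines all outputs.
#' @return a `sim_config` list.
#' @export
sim_config <- function(genome_length = 2e5, gc_content = 0.5,
                       families = list(family_spec("fam1")),
                       n_res_sites = 0L, seed = 1L) {
  stopifnot(genome_length > 0, gc_content >= 0, gc_content <= 1)
  structure(list(genome_length = as.integer(genome_length),
                 gc_content = gc_content, families = families,
                 n_res_sites = as.integer(n_res_sites),
                 seed = as.integer(seed)),
            class = "sim_config")
}

parse_triad_class <- function(label) {
  m <- regmatches(label, regexec("^DD([0-9]+)([DE])$", label))[[1]]
  if (length(m) != 3L)
    stop("triad_class must match DD<k>{D|E}, got: ", label)
  list(spacing23 = as.integer(m[2]), res3 = m[3])
}

#' Generate an i.i.d. background genome
#'
#' @param length genome length in bp (> 0).
#' @param gc GC fraction; P(G) + P(C) = gc, split evenly (likewise A/T).
#' @param seed integer seed.
#' @return a single DNA character string.
#' @export
generate_background_genome <- function(length, gc = 0.5, seed = 1L) {
  if (length <= 0) stop("genome length must be positive")
  with_seed(seed, random_dna(length, gc))
}

#' Design a transposase protein with a DDE/D catalytic triad
#'
#' The protein is random sequence except for a fixed N-terminus and fixed
#' conserved blocks surrounding each catalytic residue (mimicking the
#' conserved motifs of real Tc1/mariner transposases). The triad spacing is
#' encoded by `triad_class`: the third residue sits `k` residues after the
#' second, with a fixed 76-residue spacing between the first and second.
#' All output proteins are synthetic designs, not database sequences.
#'
#' @param protein_length total length in aa (>= 170 for default spacing).
#' @param triad_class e.g. "DD34E".
#' @param seed integer seed.
#' @param spacing12 residues between the first and second catalytic D.
#' @return list with `protein`, 1-based triad positions `p1`, `p2`, `p3`,
#'   `spacing12`, `spacing23`, and `class`.
#' @export
generate_transposase <- function(protein_length, triad_class = "DD34E",
                                 seed = 1L, spacing12 = 76L) {
  tc <- parse_triad_class(triad_class)
  p3 <- protein_length - 39L
  p2 <- p3 - tc$spacing23 - 1L
  p1 <- p2 - spacing12 - 1L
  if (p1 < 12L)
    stop("protein_length too short for triad spacing of ", triad_class)
  with_seed(seed, {
    aa <- sample(AA20, protein_length, replace = TRUE)
    put <- function(aa, s, at) {
      aa[at:(at + nchar(s) - 1L)] <- chars(s)
      aa
    }
    aa <- put(aa, TRIAD_BLOCKS$nterm, 1L)
    aa <- put(aa, TRIAD_BLOCKS$pre1, p1 - 6L); aa <- put(aa, TRIAD_BLOCKS$post1, p1 + 1L)
    aa <- put(aa, TRIAD_BLOCKS$pre2, p2 - 6L); aa <- put(aa, TRIAD_BLOCKS$post2, p2 + 1L)
    aa <- put(aa, TRIAD_BLOCKS$pre3, p3 - 6L); aa <- put(aa, TRIAD_BLOCKS$post3, p3 + 1L)
    aa[p1] <- "D"; aa[p2] <- "D"; aa[p3] <- tc$res3
    list(protein = paste(aa, collapse = ""), p1 = p1, p2 = p2, p3 = p3,
         spacing12 = p2 - p1 - 1L, spacing23 = p3 - p2 - 1L,
         class = triad_class)
  })
}

#' Generate a family consensus element
#'
#' Builds `TIR + buffer + 5'UTR + CDS(+stop) + 3'UTR + buffer + revcomp(TIR)`
#' where the TIR starts with the terminal motif. A fixed non-pairing 4-bp
#' buffer inside each terminus guarantees the designed TIR length is the
#' score-maximal inverted repeat. UTRs are resampled until the designed ORF
#' is the single longest ORF on either strand.
#'
#' @param spec a [family_spec()].
#' @param seed integer seed.
#' @return list with `sequence`, `tir_length`, `orf` (1-based `start`, `end`
#'   including the stop codon, `strand`, `protein`), and `triad`
#'   (as returned by [generate_transposase()]).
#' @export
generate_consensus_element <- function(spec, seed = 1L) {
  tl <- spec$tir_length
  cds_len <- 3L * (spec$protein_length + 1L)
  fixed_len <- 2L * tl + 2L * nchar(TIR_BUFFER) + cds_len
  spacer_total <- spec$element_length - fixed_len
  if (spacer_total < 0L)
    stop("element_length too short for TIRs + buffers + ORF")
  u5 <- spacer_total %/% 2L
  u3 <- spacer_total - u5
  with_seed(seed, {
    ltir <- paste0(spec$terminal_motif, random_dna(tl - 4L))
    rtir <- revcomp(ltir)
    triad <- generate_transposase(spec$protein_length, spec$triad_class,
                                  seed = sample.int(2^30, 1L))
    cds <- paste0(encode_protein(triad$protein),
                  sample(c("TAA", "TAG", "TGA"), 1L))
    for (try in 1:100) {
      utr5 <- random_dna(u5)
      utr3 <- random_dna(u3)
      el <- paste0(ltir, TIR_BUFFER, utr5, cds, utr3, TIR_BUFFER, rtir)
      orf_start <- tl + nchar(TIR_BUFFER) + u5 + 1L
      orf <- find_longest_orf(el, both_strands = TRUE, min_aa = 50L)
      if (!is.null(orf) && orf$strand == "+" && orf$start == orf_start &&
          orf$protein == triad$protein) {
        return(list(sequence = el, tir_length = tl,
                    orf = list(start = orf_start,
                               end = orf_start + cds_len - 1L,
                               strand = "+", protein = triad$protein),
                    triad = triad))
      }
    }
    stop("could not place UTRs such that the designed ORF is longest")
  })
}

#' Mutate a copy by substitutions and short indels
#'
#' Each site is substituted independently with probability `p_sub` (uniform
#' over the three other bases); indel events occur per site at rate `p_indel`
#' with lengths 1-3 (uniform) and insertion/deletion equiprobable.
#'
#' @param consensus DNA character string.
#' @param p_sub per-site substitution probability.
#' @param p_indel per-site indel event probability.
#' @param seed integer seed.
#' @return mutated DNA string with attributes `n_sub` and `n_indel`.
#' @export
mutate_copy <- function(consensus, p_sub, p_indel = 0, seed = 1L) {
  stopifnot(p_sub >= 0, p_sub < 1, p_indel >= 0, p_indel < 1)
  with_seed(seed, {
    x <- chars(consensus)
    n <- length(x)
    hit <- which(runif(n) < p_sub)
    for (i in hit) x[i] <- sample(setdiff(DNA_BASES, x[i]), 1L)
    n_indel <- 0L
    if (p_indel > 0) {
      ev <- which(runif(n) < p_indel)
      n_indel <- length(ev)
      for (i in rev(ev)) {  # right-to-left keeps earlier indices valid
        len <- sample.int(3L, 1L)
        if (runif(1) < 0.5) {                       # deletion
          x <- x[-(i:min(i + len - 1L, length(x)))]
        } else {                                    # insertion before i
          x <- append(x, sample(DNA_BASES, len, replace = TRUE), after = i - 1L)
        }
      }
    }
    structure(paste(x, collapse = ""), n_sub = length(hit), n_indel = n_indel)
  })
}

## Introduce a single internal stop codon into the copy's CDS (in consensus
## coordinates; call before mutate_copy so coordinates are exact).
disrupt_orf <- function(element, orf_start, orf_end) {
  n_codons <- (orf_end - orf_start + 1L) %/% 3L
  ## keep the stop in the first 85% of the CDS so the truncated product is
  ## unambiguously non-functional (no >=95%-length fragment remains)
  k <- sample.int(floor(0.85 * n_codons) - 1L, 1L) + 1L
  at <- orf_start + 3L * (k - 1L)
  paste0(substr(element, 1L, at - 1L), "TAG",
         substr(element, at + 3L, nchar(element)))
}

#' Plant element copies at genomic TA sites with target-site duplication
#'
#' Each copy is inserted at a distinct genomic "TA", which is duplicated so
#' the element is flanked by TA on both sides. Insertion sites are kept
#' >= `min_gap` bp apart and away from the contig ends so that flanks are
#' unique and extractable.
#'
#' @param genome DNA character string.
#' @param copies character vector of copy sequences (already mutated and/or
#'   reverse-complemented for minus-strand insertions).
#' @param seed integer seed.
#' @param min_gap minimum distance between chosen TA sites in bp.
#' @param contig contig name recorded in the truth table.
#' @return list with `genome` (grown by `sum(nchar(copies) + 2)`) and
#'   `truth` data.frame with 1-based inclusive `start`/`end` per copy.
#' @export
plant_copies <- function(genome, copies, seed = 1L, min_gap = 400L,
                         contig = "chr1") {
  if (length(copies) == 0L)
    return(list(genome = genome,
                truth = data.frame(contig = character(0),
                                   start = integer(0), end = integer(0))))
  ta <- stri_locate_all_fixed(genome, "TA")[[1]][, 1]
  ta <- ta[!is.na(ta)]
  ta <- ta[ta > 200L & ta < nchar(genome) - 200L]
  with_seed(seed, {
    chosen <- integer(0)
    for (cand in sample(ta)) {
      if (all(abs(cand - chosen) >= min_gap)) chosen <- c(chosen, cand)
      if (length(chosen) == length(copies)) break
    }
    if (length(chosen) < length(copies))
      stop("insufficient spaced TA sites for ", length(copies), " copies")
    chosen <- sort(chosen)
    lens <- nchar(copies)
    offset <- c(0, cumsum(lens + 2L))[seq_along(copies)]
    pieces <- character(0)
    prev <- 1L
    for (i in seq_along(chosen)) {
      s <- chosen[i]
      pieces <- c(pieces, substr(genome, prev, s + 1L), copies[i], "TA")
      prev <- s + 2L
    }
    pieces <- c(pieces, substr(genome, prev, nchar(genome)))
    out <- paste(pieces, collapse = "")
    start <- chosen + 2L + offset
    truth <- data.frame(contig = contig, start = start,
                        end = start + lens - 1L,
                        stringsAsFactors = FALSE)
    stopifnot(nchar(out) == nchar(genome) + sum(lens + 2L))
    list(genome = out, truth = truth)
  })
}

#' Simulate a genome with planted TLE families and ground truth
#'
#' For each family the consensus is generated, a fraction of copies receives
#' a targeted internal stop codon, every copy is independently mutated, and
#' copies are planted at TA sites on a random strand (P = 0.5 each).
#' `has_intact_orf` is determined operationally on the mutated copy (longest
#' ORF >= 0.95 x the designed protein length), since random substitutions can
#' themselves create premature stops; `is_full_length` requires both terminal
#' 4-mers intact and >= 90% of the consensus length.
#'
#' @param config a [sim_config()].
#' @return list with `genome` (named character vector of contigs), `truth`
#'   data.frame (one row per planted copy, including the planted sequence),
#'   and `consensus` (per-family output of [generate_consensus_element()]).
#' @export
simulate_tle_genome <- function(config) {
  genome <- generate_background_genome(config$genome_length,
                                       config$gc_content, config$seed)
  truth <- NULL
  consensus <- list()
  all_copies <- character(0)
  meta <- NULL
  for (fi in seq_along(config$families)) {
    spec <- config$families[[fi]]
    cons <- generate_consensus_element(spec, child_seed(config$seed, 100L + fi))
    consensus[[spec$name]] <- cons
    n <- spec$n_copies
    n_disrupt <- round(spec$frac_orf_disrupted * n)
    fam_seed <- child_seed(config$seed, 200L + fi)
    fam <- with_seed(fam_seed, {
      disrupted <- seq_len(n) %in% sample.int(n, n_disrupt)
      strand <- ifelse(runif(n) < 0.5, "+", "-")
      copy_seeds <- sample.int(2^30, n)
      list(disrupted = disrupted, strand = strand, copy_seeds = copy_seeds)
    })
    copies <- character(n)
    div <- numeric(n)
    full <- logical(n)
    intact <- logical(n)
    for (i in seq_len(n)) {
      base <- cons$sequence
      if (fam$disrupted[i])
        base <- with_seed(child_seed(fam$copy_seeds[i], 1L),
                          disrupt_orf(base, cons$orf$start, cons$orf$end))
      cp <- mutate_copy(base, spec$p_sub, spec$p_indel, fam$copy_seeds[i])
      div[i] <- 100 * attr(cp, "n_sub") / nchar(cons$sequence)
      cp <- as.character(cp)
      full[i] <- startsWith(cp, spec$terminal_motif) &&
        endsWith(cp, revcomp(spec$terminal_motif)) &&
        nchar(cp) >= 0.9 * nchar(cons$sequence)
      orf <- find_longest_orf(cp, both_strands = TRUE, min_aa = 50L)
      intact[i] <- !is.null(orf) &&
        nchar(orf$protein) >= ceiling(0.95 * spec$protein_length)
      copies[i] <- if (fam$strand[i] == "+") cp else revcomp(cp)
    }
    fam_meta <- data.frame(
      family = spec$name,
      copy_id = sprintf("%s_c%03d", spec$name, seq_len(n)),
      strand = fam$strand, applied_divergence = div,
      is_full_length = full, has_intact_orf = intact,
      seq = copies, stringsAsFactors = FALSE)
    meta <- rbind(meta, fam_meta)
    all_copies <- c(all_copies, copies)
  }
  planted <- plant_copies(genome, all_copies,
                          seed = child_seed(config$seed, 999L))
  ## plant_copies places copies[i] at the i-th leftmost chosen site, so truth
  ## rows align with the copy order directly
  truth <- cbind(meta, planted$truth)
  rownames(truth) <- NULL
  truth <- truth[, c("family", "copy_id", "contig", "start", "end", "strand",
                     "applied_divergence", "is_full_length", "has_intact_orf",
                     "seq")]
  list(genome = c(chr1 = planted$genome), truth = truth,
       consensus = consensus)
}
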