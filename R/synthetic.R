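#' Element template for synthetic piggyBac-like elements
#'
#' Describes the structural layout of a piggyBac-like element (PLE) used by
#' [build_element()]: terminal inverted repeats (ITRs), asymmetrically placed
#' subterminal inverted repeats, a single transposase ORF with catalytic
#' aspartates (the "DDD" motif), and CAAT / TATA / polyadenylation signal
#' motifs. Defaults reproduce the 2406 bp element characterized in the rice
#' stem borer *Chilo suppressalis*: 13 bp ITRs `CCCAGATTAGCCT`, 25 bp
#' subterminal repeats, a 505-codon transposase with aspartates at residues
#' 268, 346, 447 and 450, and TTAA target-site duplications on insertion.
#'
#' All positions are 0-based; `orf_offset` is the nucleotide offset of the
#' ORF's ATG from the element start, so the ORF occupies the half-open
#' interval `[orf_offset, orf_offset + 3 * (orf_codons + 1))` (stop codon
#' included).
#'
#' @param total_length Element length in bases (ITR start to ITR end).
#' @param itr_seq 13-base ITR sequence (5' copy; the 3' end carries its
#'   reverse complement).
#' @param subterminal_seq 25-base subterminal repeat sequence.
#' @param subterminal_offsets Integer pair: offset of the 5' subterminal copy
#'   from the element start, and of the 3' copy (reverse complement) from the
#'   element end. Unequal values give the asymmetric placement seen in real
#'   elements.
#' @param orf_codons Number of codons excluding the stop.
#' @param orf_offset 0-based offset of the ORF start codon.
#' @param ddd_positions Four 1-based residue indices that must be aspartate.
#' @param signal_offsets Named list of 0-based starts for the `caat`, `tata`
#'   and `polya` (AATAAA) motifs.
#' @return An object of class `element_template`.
#' @export
#' @examples
#' tpl <- element_template()
#' tpl$total_length
element_template <- function(total_length = 2406L,
                             itr_seq = "CCCAGATTAGCCT",
                             subterminal_seq = "GCCTTATCCGAAGTCATAGGTCAAC",
                             subterminal_offsets = c(31L, 60L),
                             orf_codons = 505L,
                             orf_offset = 613L,
                             ddd_positions = c(268L, 346L, 447L, 450L),
                             signal_offsets = list(caat = 391L, tata = 477L,
                                                   polya = 2187L)) {
  itr_seq <- as_dna(itr_seq, arg = "itr_seq")
  subterminal_seq <- as_dna(subterminal_seq, arg = "subterminal_seq")
  if (nchar(itr_seq) != 13L) stop("`itr_seq` must be 13 bases", call. = FALSE)
  if (nchar(subterminal_seq) != 25L)
    stop("`subterminal_seq` must be 25 bases", call. = FALSE)
  total_length <- as.integer(total_length)
  orf_codons <- as.integer(orf_codons)
  orf_offset <- as.integer(orf_offset)
  orf_nt <- 3L * (orf_codons + 1L)
  if (orf_offset + orf_nt > total_length)
    stop(sprintf("ORF (%d nt at offset %d) does not fit in total_length %d",
                 orf_nt, orf_offset, total_length), call. = FALSE)
  if (any(ddd_positions < 1L) || any(ddd_positions > orf_codons))
    stop("all `ddd_positions` must lie in [1, orf_codons]", call. = FALSE)
  tpl <- structure(list(
    total_length = total_length,
    itr_seq = itr_seq,
    subterminal_seq = subterminal_seq,
    subterminal_offsets = as.integer(subterminal_offsets),
    orf_codons = orf_codons,
    orf_offset = orf_offset,
    ddd_positions = as.integer(sort(ddd_positions)),
    signal_offsets = lapply(signal_offsets, as.integer)
  ), class = "element_template")
  validate_template_layout(tpl)
  tpl
}

# Reserved intervals of a template (0-based half-open), used both for
# feasibility checking and for element construction.
template_layout <- function(tpl) {
  n <- tpl$total_length
  orf_nt <- 3L * (tpl$orf_codons + 1L)
  list(
    itr_left = c(0L, 13L),
    itr_right = c(n - 13L, n),
    sub_left = c(tpl$subterminal_offsets[1], tpl$subterminal_offsets[1] + 25L),
    sub_right = c(n - tpl$subterminal_offsets[2] - 25L,
                  n - tpl$subterminal_offsets[2]),
    orf_guard = c(tpl$orf_offset - 3L, tpl$orf_offset),  # in-frame stop
    orf = c(tpl$orf_offset, tpl$orf_offset + orf_nt),
    caat = c(tpl$signal_offsets$caat, tpl$signal_offsets$caat + 4L),
    tata = c(tpl$signal_offsets$tata, tpl$signal_offsets$tata + 4L),
    polya = c(tpl$signal_offsets$polya, tpl$signal_offsets$polya + 6L)
  )
}

validate_template_layout <- function(tpl) {
  lay <- template_layout(tpl)
  nm <- names(lay)
  for (a in seq_along(lay)) {
    iv <- lay[[a]]
    if (iv[1] < 0L || iv[2] > tpl$total_length)
      stop(sprintf("template part `%s` [%d, %d) falls outside the element",
                   nm[a], iv[1], iv[2]), call. = FALSE)
    for (b in seq_len(a - 1L)) {
      jv <- lay[[b]]
      if (iv[1] < jv[2] && jv[1] < iv[2])
        stop(sprintf("template parts `%s` and `%s` overlap ([%d,%d) vs [%d,%d))",
                     nm[a], nm[b], iv[1], iv[2], jv[1], jv[2]), call. = FALSE)
    }
  }
  invisible(tpl)
}

#' @export
print.element_template <- function(x, ...) {
  cat(sprintf("<element_template> %d bp, ITR %s, ORF %d codons at offset %d\n",
              x$total_length, x$itr_seq, x$orf_codons, x$orf_offset))
  invisible(x)
}

#' Build a synthetic piggyBac-like element sequence
#'
#' Constructs a DNA sequence realizing an [element_template()]: the ITR at
#' the 5' end and its reverse complement at the 3' end, subterminal inverted
#' repeats at their stated offsets, a single ATG-to-stop ORF of
#' `orf_codons` codons with aspartate (GAT/GAC) at the template's DDD
#' positions, and literal CAAT, TATA and AATAAA motifs. An in-frame stop is
#' placed immediately upstream of the ORF so the annotated ORF starts exactly
#' at the planted ATG. All remaining positions are i.i.d. uniform bases.
#'
#' @param template An [element_template()].
#' @param seed Integer seed; identical seeds give identical sequences.
#' @return DNA string of length `template$total_length`.
#' @export
#' @examples
#' e <- build_element(element_template(), seed = 1)
#' nchar(e)                 # 2406
#' substr(e, 1, 13)         # the ITR
build_element <- function(template, seed = 1L) {
  stopifnot(inherits(template, "element_template"))
  validate_template_layout(template)
  lay <- template_layout(template)
  with_seed(seed, {
    x <- sample(DNA_BASES, template$total_length, replace = TRUE)
    put <- function(iv, s) {
      x[(iv[1] + 1L):iv[2]] <<- strsplit(s, "", fixed = TRUE)[[1]]
    }
    put(lay$itr_left, template$itr_seq)
    put(lay$itr_right, revcomp(template$itr_seq))
    put(lay$sub_left, template$subterminal_seq)
    put(lay$sub_right, revcomp(template$subterminal_seq))
    # ORF: ATG + random non-stop codons + TAA, catalytic aspartates planted
    codon_pool <- apply(expand.grid(DNA_BASES, DNA_BASES, DNA_BASES), 1, paste,
                        collapse = "")
    codon_pool <- setdiff(codon_pool, STOP_CODONS)
    body <- sample(codon_pool, template$orf_codons - 1L, replace = TRUE)
    codons <- c("ATG", body, "TAA")
    asp <- sample(c("GAT", "GAC"), length(template$ddd_positions), replace = TRUE)
    codons[template$ddd_positions] <- asp
    codons[1L] <- "ATG"  # residue 1 stays the initiator
    put(lay$orf, paste(codons, collapse = ""))
    put(lay$orf_guard, "TAA")
    put(lay$caat, "CAAT")
    put(lay$tata, "TATA")
    put(lay$polya, "AATAAA")
    paste(x, collapse = "")
  })
}

#' Insert an element into a genome at a TTAA-class target site
#'
#' Models piggyBac "cut-and-paste" insertion: the 4-base target motif at
#' `position` is duplicated so that it flanks the element on both sides.
#'
#' @param genome Host DNA string.
#' @param position 0-based start of the target tetranucleotide in `genome`.
#' @param element Element DNA string (may be empty, giving a pure target
#'   duplication).
#' @param tsd 4-base target motif expected at `position` (default `TTAA`).
#' @return The genome with the insertion; its length is
#'   `nchar(genome) + nchar(element) + 4`.
#' @export
#' @examples
#' plant_insertion("GGTTAAGG", 2, "CCC", "TTAA")  # "GGTTAACCCTTAAGG"
plant_insertion <- function(genome, position, element, tsd = "TTAA") {
  genome <- as_dna(genome, arg = "genome")
  if (nzchar(element)) element <- as_dna(element, arg = "element")
  tsd <- as_dna(tsd, arg = "tsd")
  if (nchar(tsd) != 4L) stop("`tsd` must be 4 bases", call. = FALSE)
  position <- as.integer(position)
  found <- substr(genome, position + 1L, position + 4L)
  if (found != tsd)
    stop(sprintf("target mismatch at position %d: found %s, expected %s",
                 position, found, tsd), call. = FALSE)
  paste0(substr(genome, 1L, position + 4L), element, tsd,
         substr(genome, position + 5L, nchar(genome)))
}

#' Per-region mutation rates for element copies
#'
#' Rates are per base per copy, applied independently to the 5' region
#' outside the ORF, the ORF, and the 3' region outside the ORF. An alignment
#' column is a variant position as soon as any one of the copies mutates
#' there, so with `k` copies per set the expected variation rate is roughly
#' `k` times the per-copy rate. The defaults are calibrated for the 4-copy
#' sets of the field study so that the expected per-region variation rates
#' match the observed magnitudes (0.0062 / 0.0053 / 0.0113 for 5'/ORF/3'),
#' with the indel rate concentrated in the 3' region where the variability
#' hotspot and most indels lie. Indel lengths are drawn from a geometric
#' distribution truncated to `{1, ..., indel_max}` so that indels of three
#' or more bases (special variation positions) occur.
#'
#' @param sub Named numeric: substitution rate per base for `five_prime`,
#'   `orf`, `three_prime`.
#' @param indel Named numeric: indel initiation rate per base, same names.
#' @param indel_max Maximum indel length (default 11, the largest observed).
#' @param indel_geom_p Success probability of the truncated geometric length
#'   distribution (mean length about 2.5, covering the observed 2-11 base
#'   events).
#' @return Object of class `mutation_rates`.
#' @export
mutation_rates <- function(sub = c(five_prime = 0.00143, orf = 0.00128,
                                   three_prime = 0.00233),
                           indel = c(five_prime = 5e-05, orf = 2e-05,
                                     three_prime = 2e-04),
                           indel_max = 11L, indel_geom_p = 0.4) {
  regions <- c("five_prime", "orf", "three_prime")
  sub <- sub[regions]; indel <- indel[regions]
  if (any(is.na(sub)) || any(is.na(indel)) || any(sub < 0) || any(indel < 0))
    stop("rates must be non-negative and named five_prime/orf/three_prime",
         call. = FALSE)
  structure(list(sub = sub, indel = indel, indel_max = as.integer(indel_max),
                 indel_geom_p = indel_geom_p),
            class = "mutation_rates")
}

# region index (1=5', 2=ORF, 3=3') for each 0-based position
region_of <- function(n, orf_span) {
  r <- rep.int(3L, n)
  pos <- seq_len(n) - 1L
  r[pos < orf_span[2]] <- 2L
  r[pos < orf_span[1]] <- 1L
  r
}

rtrunc_geom <- function(n, p, max_len) {
  pmin(stats::rgeom(n, p) + 1L, max_len)
}

#' Mutate an element copy with region-specific rates
#'
#' Draws substitutions and indels per position at the configured per-region
#' rates and applies them, returning the mutated sequence together with the
#' exact list of introduced mutations (positions in the coordinates of the
#' input element).
#'
#' @param element Element DNA string.
#' @param orf_span 0-based half-open ORF interval within the element.
#' @param rates A [mutation_rates()] object.
#' @param seed Integer seed.
#' @return List with `seq` (mutated DNA string) and `mutations` (data frame
#'   with `position` (0-based), `type` in `sub`/`ins`/`del`, `length`, `ref`,
#'   `alt`, `region`).
#' @export
mutate_copy <- function(element, orf_span, rates = mutation_rates(), seed = 1L) {
  element <- as_dna(element, arg = "element")
  n <- nchar(element)
  orf_span <- check_interval(orf_span, n, "orf_span")
  stopifnot(inherits(rates, "mutation_rates"))
  with_seed(seed, {
    ev <- draw_mutation_events(n, orf_span, rates)
    apply_mutation_events(element, ev)
  })
}

# Draw mutation events for one copy; positions 0-based in template coords.
# Assumes an active RNG stream.
draw_mutation_events <- function(n, orf_span, rates) {
  reg <- region_of(n, orf_span)
  sub_hit <- which(stats::runif(n) < rates$sub[reg])
  indel_hit <- which(stats::runif(n) < rates$indel[reg])
  ev <- data.frame(position = integer(0), type = character(0),
                   length = integer(0), region = integer(0))
  if (length(sub_hit))
    ev <- rbind(ev, data.frame(position = sub_hit - 1L, type = "sub",
                               length = 1L, region = reg[sub_hit]))
  if (length(indel_hit)) {
    kind <- ifelse(stats::runif(length(indel_hit)) < 0.5, "ins", "del")
    len <- rtrunc_geom(length(indel_hit), rates$indel_geom_p, rates$indel_max)
    ev <- rbind(ev, data.frame(position = indel_hit - 1L, type = kind,
                               length = len, region = reg[indel_hit]))
  }
  ev <- ev[order(ev$position), , drop = FALSE]
  rownames(ev) <- NULL
  # materialize substitution targets and insertion sequences now, so the
  # event list fully determines the mutated copy
  ev$alt <- rep(NA_character_, nrow(ev))
  for (i in seq_len(nrow(ev))) {
    if (ev$type[i] == "sub") {
      ev$alt[i] <- sample(DNA_BASES, 1L)  # replaced later if equal to ref
    } else if (ev$type[i] == "ins") {
      ev$alt[i] <- paste(sample(DNA_BASES, ev$length[i], replace = TRUE),
                         collapse = "")
    }
  }
  ev
}

apply_mutation_events <- function(element, ev) {
  xc <- strsplit(element, "", fixed = TRUE)[[1]]
  n <- length(xc)
  ev$ref <- rep(NA_character_, nrow(ev))
  for (i in seq_len(nrow(ev))) {
    if (ev$type[i] == "sub") {
      ref <- xc[ev$position[i] + 1L]
      ev$ref[i] <- ref
      if (ev$alt[i] == ref)  # resample deterministically: next base cyclically
        ev$alt[i] <- DNA_BASES[match(ref, DNA_BASES) %% 4L + 1L]
    } else if (ev$type[i] == "del") {
      to <- min(ev$position[i] + ev$length[i], n)
      ev$ref[i] <- paste(xc[(ev$position[i] + 1L):to], collapse = "")
      ev$length[i] <- to - ev$position[i]
    }
  }
  # apply right-to-left so earlier coordinates stay valid
  out <- xc
  for (i in rev(seq_len(nrow(ev)))) {
    p <- ev$position[i]
    if (ev$type[i] == "sub") {
      out[p + 1L] <- ev$alt[i]
    } else if (ev$type[i] == "del") {
      out <- out[-((p + 1L):(p + ev$length[i]))]
    } else {
      ins <- strsplit(ev$alt[i], "", fixed = TRUE)[[1]]
      out <- append(out, ins, after = p)
    }
  }
  list(seq = paste(out, collapse = ""),
       mutations = ev[, c("position", "type", "length", "ref", "alt", "region")])
}

#' Simulate a gap-aligned set of mutated element copies
#'
#' Generates `n_copies` copies of `element` mutated at the configured
#' per-region rates and returns them already aligned against the template:
#' substitutions change a column, deletions appear as gap characters, and
#' insertions add columns (gap in every non-carrier copy). Because the
#' alignment is constructed from the known mutations rather than re-estimated,
#' the true set of variant columns is exact.
#'
#' @param element Template element DNA string.
#' @param orf_span 0-based half-open ORF interval in template coordinates.
#' @param n_copies Number of copies (default 4, the per-population sample
#'   size used in the field study).
#' @param rates A [mutation_rates()] object.
#' @param seed Integer seed.
#' @param group_id Label for the copy set.
#' @return An [aligned_copy_set()] with attribute `truth`, a list holding the
#'   per-copy mutation tables.
#' @export
simulate_copy_set <- function(element, orf_span, n_copies = 4L,
                              rates = mutation_rates(), seed = 1L,
                              group_id = "group1") {
  element <- as_dna(element, arg = "element")
  n <- nchar(element)
  orf_span <- check_interval(orf_span, n, "orf_span")
  xc <- strsplit(element, "", fixed = TRUE)[[1]]
  events <- with_seed(seed, lapply(seq_len(n_copies), function(i)
    draw_mutation_events(n, orf_span, rates)))

  # per-copy per-template-position state: base, substituted base, or gap;
  # plus per-position insertion strings (inserted AFTER template position p)
  copies <- vector("list", n_copies)
  inserts <- matrix("", nrow = n_copies, ncol = n + 1L)  # col p+1 = after pos p-1
  for (i in seq_len(n_copies)) {
    col <- xc
    ev <- events[[i]]
    for (k in seq_len(nrow(ev))) {
      p <- ev$position[k]
      if (ev$type[k] == "sub") {
        ref <- xc[p + 1L]
        alt <- ev$alt[k]
        if (alt == ref) alt <- DNA_BASES[match(ref, DNA_BASES) %% 4L + 1L]
        col[p + 1L] <- alt
      } else if (ev$type[k] == "del") {
        to <- min(p + ev$length[k], n)
        col[(p + 1L):to] <- "-"
      } else {
        inserts[i, p + 1L] <- paste0(inserts[i, p + 1L], ev$alt[k])
      }
    }
    copies[[i]] <- col
  }

  # build alignment columns: insertion block emitted before template
  # position p (p = n: trailing block). Vectorised: template column p
  # (0-based) lands at 1-based alignment index p + csum[p + 1] + 1, where
  # csum[p + 1] counts insertion columns emitted at or before p.
  ins_width <- apply(matrix(nchar(inserts), nrow = n_copies), 2, max)
  csum <- cumsum(ins_width)
  width <- n + csum[n + 1L]
  tcol_idx <- seq_len(n) + csum[seq_len(n)]   # alignment index of template col
  blocks <- which(ins_width > 0L)             # block before template pos b - 1
  seqs <- vapply(seq_len(n_copies), function(i) {
    a <- rep("-", width)
    a[tcol_idx] <- copies[[i]]
    for (b in blocks) {
      s <- inserts[i, b]
      if (nzchar(s))
        a[seq.int((b - 1L) + csum[b] - ins_width[b] + 1L,
                  length.out = nchar(s))] <- strsplit(s, "", fixed = TRUE)[[1]]
    }
    paste(a, collapse = "")
  }, character(1))
  names(seqs) <- paste0(group_id, "_copy", seq_len(n_copies))

  # alignment coordinate of template position p: shifted by every insertion
  # block emitted at or before p
  aln_pos <- function(p) p + csum[p + 1L]
  orf_aln <- c(aln_pos(orf_span[1]), aln_pos(orf_span[2]))

  # template coordinate of each alignment column (inserted columns pooled
  # onto the template position before which they sit)
  tmap <- integer(width)
  tmap[tcol_idx] <- 0:(n - 1L)
  for (b in blocks)
    tmap[seq.int((b - 1L) + csum[b] - ins_width[b] + 1L,
                 length.out = ins_width[b])] <- min(b - 1L, n - 1L)

  cs <- aligned_copy_set(seqs, orf = orf_aln, group_id = group_id)
  attr(cs, "truth") <- list(events = events, template_length = n)
  attr(cs, "template_map") <- tmap
  attr(cs, "template_length") <- n
  cs
}

#' Population scenario for end-to-end simulations
#'
#' Captures the sampling design of a transposon-display / flanking-PCR field
#' survey: a catalog of TTAA insertion loci on a shared reference genome,
#' per-population per-locus insertion probabilities for diploid individuals,
#' and a replicate-group structure. Defaults emulate the field study the
#' package models: 12 populations genotyped at up to 21 loci with 8
#' individuals each for transposon display (frequency surveys instead used 21
#' populations of 3 groups x 15 individuals; pass `groups_per_population = 3`,
#' `individuals_per_group = 15` for that design).
#'
#' @param population_ids Character vector of population labels.
#' @param n_loci Number of insertion loci in the catalog.
#' @param insertion_prob Either a single probability, a per-population vector,
#'   or a `populations x loci` matrix of per-allele insertion probabilities.
#' @param individuals_per_group Individuals per replicate group.
#' @param groups_per_population Replicate groups per population.
#' @param mutation_rates Optional [mutation_rates()] applied to each planted
#'   copy (default `NULL`: clean copies, so flank-based site recovery is
#'   noiseless).
#' @param locus_spacing Bases between consecutive catalog loci on the
#'   reference; also sets the reference length `(n_loci + 1) * locus_spacing`.
#' @param enzyme_upstream Distance (bases) from the planted restriction site
#'   start to each locus target, giving transposon-display tags of length
#'   `enzyme_upstream + 4`.
#' @param seed Integer seed used for every random draw in the scenario.
#' @return Object of class `population_scenario`.
#' @export
population_scenario <- function(population_ids = c("P01", "P02", "P03", "P04",
                                                   "P05", "P06", "P07", "P08",
                                                   "P09", "P10", "P11", "P12"),
                                n_loci = 21L,
                                insertion_prob = 0.3,
                                individuals_per_group = 8L,
                                groups_per_population = 1L,
                                mutation_rates = NULL,
                                locus_spacing = 250L,
                                enzyme_upstream = 100L,
                                seed = 1L) {
  npop <- length(population_ids)
  n_loci <- as.integer(n_loci)
  if (is.matrix(insertion_prob)) {
    stopifnot(nrow(insertion_prob) == npop, ncol(insertion_prob) == n_loci)
    prob <- insertion_prob
  } else if (length(insertion_prob) == npop) {
    prob <- matrix(insertion_prob, nrow = npop, ncol = n_loci)
  } else if (length(insertion_prob) == 1L) {
    prob <- matrix(insertion_prob, nrow = npop, ncol = n_loci)
  } else stop("`insertion_prob` must be scalar, per-population, or a matrix",
              call. = FALSE)
  if (any(prob < 0) || any(prob > 1))
    stop("insertion probabilities must lie in [0, 1]", call. = FALSE)
  dimnames(prob) <- list(population_ids, paste0("locus", seq_len(n_loci)))
  structure(list(
    population_ids = population_ids,
    n_loci = n_loci,
    insertion_prob = prob,
    individuals_per_group = as.integer(individuals_per_group),
    groups_per_population = as.integer(groups_per_population),
    mutation_rates = mutation_rates,
    locus_spacing = as.integer(locus_spacing),
    enzyme_upstream = as.integer(enzyme_upstream),
    seed = as.integer(seed)
  ), class = "population_scenario")
}

#' Simulate diploid host populations with planted element insertions
#'
#' Generates a shared reference host genome (i.i.d. uniform bases with a TTAA
#' target and an upstream HindIII site guaranteed at every catalog locus),
#' then draws two alleles per individual per locus at the scenario's
#' insertion probabilities and builds each individual's genome by inserting
#' the element (with target-site duplication) at every carried locus. The
#' returned truth record is sufficient to recompute every downstream
#' expected output exactly.
#'
#' @param scenario A [population_scenario()].
#' @param template An [element_template()].
#' @return List with elements `genomes` (named character vector, one genome
#'   per individual, named `<pop>.g<group>.i<ind>`), `element` (the planted
#'   element sequence), `reference`, `loci` (0-based TTAA starts on the
#'   reference), and `truth` (list: `alleles` long data frame with 0/1/2
#'   copies per individual x locus, `presence` population x locus 0/1 matrix,
#'   `group_freq` per-population per-group realized carrier frequency at
#'   locus 1, `true_prob` the scenario probability matrix).
#' @export
simulate_populations <- function(scenario, template = element_template()) {
  stopifnot(inherits(scenario, "population_scenario"))
  element <- build_element(template, seed = scenario$seed)
  sp <- scenario$locus_spacing
  n_loci <- scenario$n_loci
  ref_len <- sp * (n_loci + 1L)
  enzyme <- "AAGCTT"

  ref <- with_seed(scenario$seed + 1L, {
    repeat {
      g <- strsplit(random_dna(ref_len), "", fixed = TRUE)[[1]]
      loci <- sp * seq_len(n_loci)  # 0-based TTAA starts
      for (p in loci) {
        g[(p + 1L):(p + 4L)] <- c("T", "T", "A", "A")
        e0 <- p - scenario$enzyme_upstream
        g[(e0 + 1L):(e0 + 6L)] <- strsplit(enzyme, "", fixed = TRUE)[[1]]
      }
      s <- paste(g, collapse = "")
      # flank keys must be locus-unique, and no stray enzyme occurrence may
      # fall inside a locus's 30-base flank window or TSD (it would truncate
      # the transposon-display tag below the flank key length)
      flanks <- substring(s, loci - 30L + 1L, loci)
      if (anyDuplicated(flanks)) next
      occ <- which(slide_mismatch(g, enzyme) == 0L) - 1L  # 0-based starts
      stray <- setdiff(occ, loci - scenario$enzyme_upstream)
      bad <- any(vapply(loci, function(p)
        any(stray + 6L > p - 30L & stray < p + 4L), logical(1)))
      if (!bad) break
    }
    s
  })
  loci <- sp * seq_len(n_loci)

  npop <- length(scenario$population_ids)
  G <- scenario$groups_per_population
  I <- scenario$individuals_per_group
  alleles <- expand.grid(individual = seq_len(I), group = seq_len(G),
                         population = scenario$population_ids,
                         locus = seq_len(n_loci), stringsAsFactors = FALSE)
  genomes <- character(0)
  rows <- vector("list", 0)
  with_seed(scenario$seed + 2L, {
    mut_counter <- 0L
    for (pop in scenario$population_ids) {
      for (g in seq_len(G)) {
        for (ind in seq_len(I)) {
          pr <- scenario$insertion_prob[pop, ]
          a1 <- stats::rbinom(n_loci, 1L, pr)
          a2 <- stats::rbinom(n_loci, 1L, pr)
          ncopies <- a1 + a2
          carried <- which(ncopies > 0L)
          genome <- ref
          for (l in rev(carried)) {  # right-to-left keeps coordinates valid
            copy <- element
            if (!is.null(scenario$mutation_rates)) {
              mut_counter <- mut_counter + 1L
              orf <- c(template$orf_offset,
                       template$orf_offset + 3L * (template$orf_codons + 1L))
              copy <- mutate_copy(element, orf, scenario$mutation_rates,
                                  seed = scenario$seed + 1000L + mut_counter)$seq
            }
            genome <- plant_insertion(genome, loci[l], copy, "TTAA")
          }
          id <- sprintf("%s.g%d.i%d", pop, g, ind)
          genomes[id] <- genome
          rows[[length(rows) + 1L]] <- data.frame(
            individual = id, population = pop, group = g,
            locus = seq_len(n_loci), copies = ncopies)
        }
      }
    }
  })
  allele_df <- do.call(rbind, rows)

  presence <- matrix(unlist(lapply(scenario$population_ids, function(pop) {
    sub <- allele_df[allele_df$population == pop, ]
    vapply(seq_len(n_loci), function(l)
      as.integer(any(sub$copies[sub$locus == l] > 0L)), integer(1))
  })), nrow = length(scenario$population_ids), byrow = TRUE)
  dimnames(presence) <- list(scenario$population_ids,
                             paste0("locus", seq_len(n_loci)))

  gf <- do.call(rbind, lapply(scenario$population_ids, function(pop) {
    do.call(rbind, lapply(seq_len(G), function(g) {
      sub <- allele_df[allele_df$population == pop & allele_df$group == g &
                         allele_df$locus == 1L, ]
      data.frame(population = pop, group = g,
                 frequency = mean(sub$copies > 0L))
    }))
  }))

  list(genomes = genomes, element = element, reference = ref, loci = loci,
       truth = list(alleles = allele_df, presence = presence,
                    group_freq = gf, true_prob = scenario$insertion_prob))
}
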