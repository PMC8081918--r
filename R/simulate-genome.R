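# Canonical damage motifs. The lesion dinucleotide is TC within CTCA for
# (6-4)PP and TT for CPD. `lesion_shift` is the offset of the leftmost base
# of the lesion dinucleotide within the motif (read orientation).
damage_motif <- function(damage_type) {
  switch(damage_type,
         "64PP" = list(motif = "CTCA", lesion_shift = 1L),
         "CPD"  = list(motif = "TT", lesion_shift = 0L),
         abort(paste("unknown damage_type:", damage_type)))
}

#' Simulate a miniature reference genome with planted damage motifs
#'
#' Draws every base i.i.d. from the configured background distribution,
#' then plants, inside each configured hotspot/coldspot interval,
#' `lesions_per_spot` copies of the canonical damage motif (CTCA for
#' (6-4)PP, TT for CPD) on the planted strand, embedded in
#' cytosine-weighted flanking sequence. Deterministic given `config$seed`.
#'
#' @param config A [sim_config()].
#' @return A [Biostrings::DNAStringSet] named by chromosome, with an
#'   attribute `planted_sites`: a tibble (`chrom`, `lesion_pos`, `strand`,
#'   `category`) of the planted lesion positions (leftmost genomic base of
#'   the lesion dinucleotide). Retrieve with [planted_damage_sites()].
#' @export
simulate_genome <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  mot <- damage_motif(config$damage_type)
  with_seed_maybe(config$seed, offset = 1L, {
    seqs <- lapply(config$chrom_lengths, function(len) {
      paste(sample(BASES, len, replace = TRUE, prob = config$base_probs),
            collapse = "")
    })
    genome <- Biostrings::DNAStringSet(unlist(seqs))
    names(genome) <- names(config$chrom_lengths)

    spots <- all_planted_spots(config)
    planted <- tibble::tibble(chrom = character(), lesion_pos = integer(),
                              strand = character(), category = character())
    if (nrow(spots) > 0) {
      pieces <- purrr::pmap(spots, function(chrom, start, end, strand,
                                            category, ...) {
        plant_spot_sequence(config, mot, chrom, start, end, strand, category)
      })
      planted <- dplyr::bind_rows(purrr::map(pieces, "sites"))
      repl <- dplyr::bind_rows(purrr::map(pieces, "replacement"))
      # one replaceAt per chromosome; spots are disjoint by construction
      for (ch in unique(repl$chrom)) {
        r <- repl[repl$chrom == ch, ]
        genome[[ch]] <- Biostrings::replaceAt(
          genome[[ch]],
          IRanges::IRanges(start = r$start + 1L, end = r$end),
          r$seq
        )
      }
    }
    attr(genome, "planted_sites") <-
      dplyr::arrange(planted, .data$chrom, .data$lesion_pos, .data$strand)
    genome
  })
}

# Build the replacement sequence for one planted spot: motifs at evenly
# spaced lesion positions, all remaining bases in the window drawn from the
# cytosine-weighted flank distribution (C weight in lesion-strand
# orientation).
plant_spot_sequence <- function(config, mot, chrom, start, end, strand,
                                category) {
  len <- config$chrom_lengths[[chrom]]
  k <- config$lesions_per_spot
  width <- end - start
  lesion_pos <- start + floor((seq_len(k) - 0.5) / k * width)
  motif_len <- nchar(mot$motif)
  # motif occupies [m, m + motif_len) with lesion_pos = m + lesion_shift
  m <- lesion_pos - mot$lesion_shift
  m <- pmin(pmax(m, 0L), len - motif_len)
  lesion_pos <- m + mot$lesion_shift
  win_start <- max(0L, min(m) - config$flank_width)
  win_end <- min(len, max(m) + motif_len + config$flank_width)

  fc <- config$flank_c_fraction
  flank_probs <- setNames(rep((1 - fc) / 3, 4), BASES)
  flank_probs["C"] <- fc
  window <- sample(BASES, win_end - win_start, replace = TRUE,
                   prob = flank_probs)
  motif_bases <- strsplit(mot$motif, "")[[1]]
  for (mi in m) {
    window[(mi - win_start) + seq_len(motif_len)] <- motif_bases
  }
  seq <- paste(window, collapse = "")
  if (strand == "-") {
    seq <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
  }
  list(
    replacement = tibble::tibble(chrom = chrom, start = win_start,
                                 end = win_end, seq = seq),
    sites = tibble::tibble(
      chrom = chrom,
      lesion_pos = if (strand == "+") as.integer(lesion_pos) else
        as.integer(win_start + win_end - lesion_pos - motif_len +
                     mot$lesion_shift * 2L),
      strand = strand,
      category = category
    )
  )
}

#' Planted damage sites of a synthetic genome
#'
#' @param genome A genome from [simulate_genome()].
#' @return Tibble with columns `chrom`, `lesion_pos` (leftmost genomic base
#'   of the lesion dinucleotide), `strand`, `category`.
#' @export
planted_damage_sites <- function(genome) {
  sites <- attr(genome, "planted_sites")
  sites %||% tibble::tibble(chrom = character(), lesion_pos = integer(),
                            strand = character(), category = character())
}
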