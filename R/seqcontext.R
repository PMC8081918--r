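#' Locate the damage dinucleotide within an excision-product read
#'
#' Scans a window `search_window` nt from the read 3' end (default 9 down
#' to 4, the region where dual-incision geometry places the lesion) for
#' the canonical dipyrimidine: TT or TC for CPD; TC — preferring a CTCA
#' context — for (6-4)PP. Among candidates, the one whose 5' base lies
#' closest to `target_offset` nt from the 3' end wins; ties resolve
#' 3'-ward. Reads with no candidate fall back to exactly `target_offset`
#' nt from the 3' end and are flagged.
#'
#' @param seq Character vector of read sequences (read orientation).
#' @param damage_type `"64PP"` or `"CPD"`.
#' @param search_window `c(min, max)` distance (nt) of the dinucleotide's
#'   5' base from the 3' end.
#' @param target_offset Preferred distance from the 3' end (default 6).
#' @return Tibble `offset` (0-based index of the dinucleotide's 5' base
#'   within the read; `NA` for missing sequence) and `flagged`.
#' @export
locate_damage_in_read <- function(seq, damage_type = c("64PP", "CPD"),
                                  search_window = c(4L, 9L),
                                  target_offset = 6L) {
  damage_type <- match.arg(damage_type)
  dinucs <- if (damage_type == "CPD") c("TT", "TC") else "TC"
  n <- length(seq)
  offset <- rep(NA_integer_, n)
  flagged <- rep(NA, n)
  has_seq <- !is.na(seq) & nzchar(seq)
  L <- nchar(seq)
  ws <- seq.int(search_window[1], search_window[2])
  for (i in which(has_seq)) {
    li <- L[i]
    idx <- li - 1L - ws               # candidate 0-based 5'-base indices
    ok <- idx >= 0L & idx + 1L <= li - 1L
    cand_idx <- idx[ok]; cand_w <- ws[ok]
    di <- substring(seq[i], cand_idx + 1L, cand_idx + 2L)
    hit <- di %in% dinucs
    if (damage_type == "64PP" && any(hit)) {
      ctx <- substring(seq[i], cand_idx, cand_idx + 3L)
      pref <- hit & ctx == "CTCA"
      if (any(pref)) hit <- pref
    }
    if (any(hit)) {
      d <- abs(cand_w - target_offset)
      d[!hit] <- Inf
      best <- which(d == min(d))
      best <- best[which.min(cand_w[best])]  # tie: 3'-ward
      offset[i] <- cand_idx[best]
      flagged[i] <- FALSE
    } else {
      offset[i] <- li - 1L - target_offset
      flagged[i] <- TRUE
    }
  }
  tibble::tibble(offset = offset, flagged = flagged)
}

#' Damage-centred nucleotide frequency matrix
#'
#' Centres every read on the 5' base of its damage dinucleotide (located
#' with [locate_damage_in_read()]) and tallies strand-specific base
#' frequencies over a `2 * flank + 1`-position window (default 15
#' positions, -7..+7). Window positions beyond the read are filled from
#' the genome when one is supplied, otherwise excluded from that
#' position's denominator.
#'
#' @param reads Read tibble with a `seq` column (see
#'   [add_read_sequences()]).
#' @param damage_type `"64PP"` or `"CPD"`.
#' @param genome Optional `DNAStringSet` used to fill short flanks.
#' @param flank Flank width in positions (default 7).
#' @param ... Passed to [locate_damage_in_read()].
#' @return A `freq_matrix`: long tibble `strand`, `position` (-flank..
#'   +flank; 0 and +1 are the damage dinucleotide), `base`, `count`,
#'   `total`, `freq`; attributes `n_reads` and `n_flagged`.
#' @export
nucleotide_frequency <- function(reads, damage_type = c("64PP", "CPD"),
                                 genome = NULL, flank = 7L, ...) {
  validate_reads(reads, require = "seq")
  damage_type <- match.arg(damage_type)
  assert_that(nrow(reads) > 0, "need at least one read")
  loc <- locate_damage_in_read(reads$seq, damage_type, ...)
  usable <- !is.na(loc$offset)
  r <- reads[usable, , drop = FALSE]
  idx <- loc$offset[usable]
  L <- nchar(r$seq)
  positions <- seq.int(-flank, flank)
  tallies <- purrr::map_dfr(seq_along(positions), function(k) {
    rel <- positions[k]
    p <- idx + rel
    inside <- p >= 0L & p <= L - 1L
    base <- rep(NA_character_, nrow(r))
    base[inside] <- substring(r$seq[inside], p[inside] + 1L, p[inside] + 1L)
    if (!is.null(genome) && any(!inside)) {
      need <- which(!inside)
      gpos <- ifelse(r$strand[need] == "+", r$start[need] + p[need],
                     r$end[need] - 1L - p[need])
      base[need] <- fetch_bases(genome, r$chrom[need], gpos,
                                complement = r$strand[need] == "-")
    }
    ok <- !is.na(base) & base %in% BASES
    tibble::tibble(strand = r$strand[ok], position = rel, base = base[ok])
  })
  grid <- tidyr::expand_grid(strand = sort(unique(r$strand)),
                             position = positions, base = BASES)
  out <- tallies |>
    dplyr::count(.data$strand, .data$position, .data$base, name = "count") |>
    dplyr::right_join(grid, by = c("strand", "position", "base")) |>
    dplyr::mutate(count = tidyr::replace_na(.data$count, 0L)) |>
    dplyr::group_by(.data$strand, .data$position) |>
    dplyr::mutate(total = sum(.data$count),
                  freq = dplyr::if_else(.data$total > 0,
                                        .data$count / .data$total,
                                        NA_real_)) |>
    dplyr::ungroup() |>
    dplyr::arrange(.data$strand, .data$position, .data$base)
  attr(out, "n_reads") <- sum(usable)
  attr(out, "n_flagged") <- sum(loc$flagged, na.rm = TRUE)
  attr(out, "damage_type") <- damage_type
  attr(out, "flank") <- flank
  class(out) <- c("freq_matrix", class(out))
  out
}

# Fetch single bases (optionally complemented) from a genome; positions
# outside chromosomes give NA.
fetch_bases <- function(genome, chrom, pos, complement = FALSE) {
  complement <- rep_len(complement, length(pos))
  out <- rep(NA_character_, length(pos))
  sizes <- genome_sizes(genome)
  ok <- chrom %in% names(sizes)
  ok[ok] <- pos[ok] >= 0 & pos[ok] < sizes[chrom[ok]]
  for (ch in unique(chrom[ok])) {
    i <- which(ok & chrom == ch)
    v <- Biostrings::extractAt(genome[[ch]],
                               IRanges::IRanges(start = pos[i] + 1L,
                                                width = 1L))
    out[i] <- as.character(v)
  }
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  out[complement & !is.na(out)] <- comp[out[complement & !is.na(out)]]
  out
}

#' Genome-wide base composition as a reference frequency matrix
#'
#' Constant per-position reference on the same grid as
#' [nucleotide_frequency()]: the genome-wide base frequencies (for the
#' minus strand, of the reverse complement).
#'
#' @param genome A `DNAStringSet`.
#' @param flank Flank width matching the spot matrix.
#' @param strands Strands to emit.
#' @return A `freq_matrix`-shaped tibble.
#' @export
reference_composition <- function(genome, flank = 7L, strands = STRANDS) {
  counts <- colSums(Biostrings::letterFrequency(genome, BASES))
  comp_minus <- counts[c("T", "G", "C", "A")]
  names(comp_minus) <- BASES
  positions <- seq.int(-flank, flank)
  out <- purrr::map_dfr(strands, function(s) {
    cts <- if (s == "+") counts else comp_minus
    tidyr::expand_grid(strand = s, position = positions,
                       base = BASES) |>
      dplyr::mutate(count = as.numeric(cts[.data$base]),
                    total = sum(cts),
                    freq = .data$count / .data$total)
  })
  class(out) <- c("freq_matrix", class(out))
  out
}

#' Cytosine-enrichment comparison between two frequency matrices
#'
#' Per-position difference in cytosine frequency between a spot matrix
#' and a reference (strands pooled), with a two-proportion z-test per
#' flanking position (the damage dinucleotide positions 0/+1 are
#' excluded) and Benjamini-Hochberg correction. The summary statistic is
#' the mean cytosine excess over the flanks.
#'
#' @param fm_spot,fm_ref `freq_matrix` objects on the same position grid.
#' @param exclude Positions excluded from the flank summary (default the
#'   damage dinucleotide, 0 and +1).
#' @return Tibble `position`, `c_spot`, `c_ref`, `delta_c`, `z`,
#'   `p_value`, `q_value` (flank positions only), with attribute
#'   `mean_delta_c`.
#' @export
compare_c_enrichment <- function(fm_spot, fm_ref, exclude = c(0L, 1L)) {
  pool_c <- function(fm) {
    fm |>
      dplyr::group_by(.data$position) |>
      dplyr::summarise(
        c_count = sum(.data$count[.data$base == "C"]),
        total = sum(.data$count), .groups = "drop") |>
      dplyr::mutate(c_freq = .data$c_count / .data$total)
  }
  a <- pool_c(fm_spot)
  b <- pool_c(fm_ref)
  assert_that(identical(a$position, b$position),
              "frequency matrices are on different position grids")
  joined <- dplyr::inner_join(a, b, by = "position",
                              suffix = c("_spot", "_ref")) |>
    dplyr::filter(!.data$position %in% exclude)
  p_pool <- (joined$c_count_spot + joined$c_count_ref) /
    (joined$total_spot + joined$total_ref)
  se <- sqrt(p_pool * (1 - p_pool) *
               (1 / joined$total_spot + 1 / joined$total_ref))
  z <- (joined$c_freq_spot - joined$c_freq_ref) / se
  out <- tibble::tibble(
    position = joined$position,
    c_spot = joined$c_freq_spot, c_ref = joined$c_freq_ref,
    delta_c = joined$c_freq_spot - joined$c_freq_ref,
    z = z, p_value = 2 * pnorm(-abs(z)))
  out$q_value <- p.adjust(out$p_value, method = "BH")
  attr(out, "mean_delta_c") <- mean(out$delta_c)
  out
}
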