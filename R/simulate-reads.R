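# Shared machinery of the synthetic count model. For strand s, bin i,
# sample j:
#   lambda_ij = N_j * beta_i * f_j(TC_i) * e_ij
# with beta ~ log-normal (normalised to sum 1 per strand),
# f_j = exp(b_j * (TC_i - mean(TC))) normalised to beta-weighted mean 1,
# and e_ij the planted enrichment fold (geometric interpolation between the
# spot's early and late folds over the time course; 1 elsewhere).
#
# Draw order under the model stream: beta(+), beta(-), sample slopes b_j.
sim_bin_model <- function(config, genome) {
  bins <- make_bins(config$chrom_lengths, config$bin_width)
  n_bins <- nrow(bins)
  n_samp <- nrow(config$samples)
  ranks <- time_rank(config, config$samples$time_point)
  N <- config$library_sizes[config$samples$sample]
  spots <- all_planted_spots(config)

  with_seed_maybe(config$seed, offset = 2L, {
    beta <- list(
      "+" = rlnorm(n_bins, 0, config$beta_dispersion),
      "-" = rlnorm(n_bins, 0, config$beta_dispersion)
    )
    beta <- lapply(beta, function(b) b / sum(b))
    b_j <- rnorm(n_samp, 0, config$tc_bias_strength)

    out <- lapply(STRANDS, function(s) {
      b_strand <- beta[[s]]
      efold <- matrix(1, n_bins, n_samp)
      planted_rows <- integer(0)
      if (nrow(spots) > 0) {
        sp <- spots[spots$strand == s, , drop = FALSE]
        if (nrow(sp) > 0) {
          hits <- overlap_hits(bins, sp)
          for (h in seq_len(nrow(hits))) {
            i <- hits$a[h]; k <- hits$b[h]
            efold[i, ] <- planted_fold(sp$early_fold[k], sp$late_fold[k],
                                       ranks)
          }
          # planted folds are defined against the clean per-bin baseline:
          # planted bins take the mean propensity so the enrichment fold is
          # not confounded by the bias draw
          planted_rows <- unique(hits$a)
          b_strand[planted_rows] <- 1 / n_bins
          b_strand <- b_strand / sum(b_strand)
        }
      }
      tc <- compute_tc_content(bins, genome, strand = s)
      tc_centered <- tc - mean(tc)
      f <- exp(outer(tc_centered, b_j))
      f <- sweep(f, 2, colSums(f * b_strand), "/")  # beta-weighted mean 1

      lambda <- sweep(b_strand * f * efold, 2, N, "*")
      if (length(planted_rows) > 0) {
        # the TC-bias modulation is likewise excluded at planted bins, so
        # a planted fold means "fold x (N / bins-per-strand) expected
        # reads" regardless of the bias draws
        lambda[planted_rows, ] <-
          (b_strand[planted_rows] %o% N) * efold[planted_rows, , drop = FALSE]
      }
      too_big <- colSums(lambda) > 10 * N
      if (any(too_big)) {
        abort(paste0("expected read total exceeds 10x library size for ",
                     "sample(s) ", paste(config$samples$sample[too_big],
                                         collapse = ", "),
                     ": planted enrichment folds too large"))
      }
      list(tc = tc, beta = b_strand, f = f, efold = efold, lambda = lambda)
    })
    names(out) <- STRANDS
    list(bins = bins, model = out, b_j = b_j, N = N)
  })
}

#' Draw per-bin XR-seq counts directly from the synthetic count model
#'
#' Samples the strand-specific bin-by-sample count matrices from the same
#' Poisson log-linear model that [simulate_xrseq_reads()] uses, skipping
#' read emission. Convenient for exercising the null-model fit at scale.
#'
#' @param config A [sim_config()].
#' @param genome Genome from [simulate_genome()] under the same config.
#' @return Named list (`"+"`, `"-"`) of [bin_count_matrix()] objects, each
#'   carrying the generating truth in attribute `truth` (list with `beta`,
#'   `f`, `efold`, `lambda`, `b_j`).
#' @export
simulate_bin_counts <- function(config, genome) {
  mdl <- sim_bin_model(config, genome)
  counts <- with_seed_maybe(config$seed, offset = 3L, {
    lapply(STRANDS, function(s) {
      lam <- mdl$model[[s]]$lambda
      matrix(rpois(length(lam), lam), nrow = nrow(lam),
             dimnames = list(NULL, config$samples$sample))
    })
  })
  names(counts) <- STRANDS
  out <- lapply(STRANDS, function(s) {
    bcm <- new_bin_count_matrix(
      bins = dplyr::mutate(mdl$bins, tc = mdl$model[[s]]$tc),
      counts = counts[[s]], strand = s, lib_sizes = mdl$N,
      samples = config$samples, damage_type = config$damage_type
    )
    attr(bcm, "truth") <- mdl$model[[s]][c("beta", "f", "efold", "lambda")]
    attr(bcm, "truth")$b_j <- mdl$b_j
    bcm
  })
  names(out) <- STRANDS
  out
}

#' Simulate aligned XR-seq excision-product reads
#'
#' Draws per-bin damage-event counts from the synthetic Poisson model and
#' emits one aligned read per event. The damage site falls at a planted
#' motif when the bin carries one (uniformly among the spot's lesion
#' sites), otherwise uniformly within the bin. Read length is uniform in
#' `config$read_length_range`, the lesion dinucleotide's 5' base sits
#' `lesion_offset` (+/- `offset_jitter`) nt from the read 3' end, MAPQ is
#' 60, and reads are shifted to stay within chromosome bounds.
#'
#' @param config A [sim_config()].
#' @param genome Genome from [simulate_genome()] under the same config.
#' @param extract_seq If `TRUE`, attach the read sequence (read
#'   orientation) in column `seq`; needed for sequence-context analysis.
#' @return Tibble of reads across all samples: `chrom`, `start`, `end`,
#'   `strand`, `mapq`, `sample`, `time_point`, `replicate`
#'   (and `seq` if requested), 0-based half-open.
#' @export
simulate_xrseq_reads <- function(config, genome, extract_seq = FALSE) {
  mdl <- sim_bin_model(config, genome)
  bins <- mdl$bins
  sizes <- config$chrom_lengths
  planted <- planted_damage_sites(genome)

  reads <- with_seed_maybe(config$seed, offset = 3L, {
    per_strand <- lapply(STRANDS, function(s) {
      lam <- mdl$model[[s]]$lambda
      y <- matrix(rpois(length(lam), lam), nrow = nrow(lam))
      # lesion positions of planted sites, by bin
      site_bin <- integer(0); site_pos <- integer(0)
      pl <- planted[planted$strand == s, , drop = FALSE]
      if (nrow(pl) > 0) {
        hit <- overlap_hits(bins, tibble::tibble(
          chrom = pl$chrom, start = pl$lesion_pos,
          end = pl$lesion_pos + 2L))
        site_bin <- hit$a
        site_pos <- pl$lesion_pos[hit$b]
      }
      purrr::map_dfr(seq_len(ncol(y)), function(j) {
        n_per_bin <- y[, j]
        idx <- rep.int(seq_along(n_per_bin), n_per_bin)
        if (length(idx) == 0) return(NULL)
        pos <- bins$start[idx] +
          floor(runif(length(idx)) * (bins$end[idx] - bins$start[idx]))
        # redirect events in planted bins to their lesion sites
        if (length(site_bin) > 0) {
          m <- match(idx, site_bin)
          in_spot <- which(!is.na(m))
          if (length(in_spot) > 0) {
            choice <- vapply(idx[in_spot], function(b) {
              cand <- site_pos[site_bin == b]
              cand[sample.int(length(cand), 1)]
            }, integer(1))
            pos[in_spot] <- choice
          }
        }
        emit_reads_at_lesions(
          chrom = bins$chrom[idx], lesion_pos = as.integer(pos), strand = s,
          config = config, sizes = sizes,
          sample = config$samples$sample[j],
          time_point = config$samples$time_point[j],
          replicate = config$samples$replicate[j]
        )
      })
    })
    dplyr::bind_rows(per_strand)
  })
  reads <- dplyr::arrange(reads, .data$sample, .data$chrom, .data$start)
  if (extract_seq) reads <- add_read_sequences(reads, genome)
  reads
}

# Place XR-seq style reads so that the lesion dinucleotide's 5' base lies
# `lesion_offset` (+/- jitter) nt from the 3' end. `lesion_pos` is the
# leftmost genomic base of the dinucleotide.
emit_reads_at_lesions <- function(chrom, lesion_pos, strand, config, sizes,
                                  sample, time_point, replicate) {
  n <- length(lesion_pos)
  len <- sample_int_range(n, config$read_length_range)
  off <- config$lesion_offset +
    sample_int_range(n, c(-config$offset_jitter, config$offset_jitter))
  if (strand == "+") {
    end <- lesion_pos + off + 1L
    start <- end - len
  } else {
    start <- lesion_pos + 1L - off
    end <- start + len
  }
  chrom_len <- unname(sizes[chrom])
  start <- pmax(0L, pmin(start, chrom_len - len))
  end <- start + len
  tibble::tibble(chrom = chrom, start = as.integer(start),
                 end = as.integer(end), strand = strand, mapq = 60L,
                 sample = sample, time_point = time_point,
                 replicate = replicate)
}

sample_int_range <- function(n, range) {
  if (range[1] == range[2]) return(rep.int(as.integer(range[1]), n))
  as.integer(range[1] + floor(runif(n) * (range[2] - range[1] + 1)))
}

#' Attach read sequences from a genome
#'
#' Extracts each read's sequence (reverse-complemented for minus-strand
#' reads, so `seq` is in read orientation) into a `seq` column.
#'
#' @param reads Read tibble.
#' @param genome A `DNAStringSet`.
#' @return `reads` with a `seq` character column.
#' @export
add_read_sequences <- function(reads, genome) {
  validate_reads(reads)
  if (nrow(reads) == 0) return(dplyr::mutate(reads, seq = character(0)))
  seq <- character(nrow(reads))
  for (ch in unique(reads$chrom)) {
    i <- which(reads$chrom == ch)
    v <- Biostrings::extractAt(
      genome[[ch]],
      IRanges::IRanges(start = reads$start[i] + 1L, end = reads$end[i]))
    v <- as.character(v)
    minus <- reads$strand[i] == "-"
    if (any(minus)) {
      v[minus] <- as.character(Biostrings::reverseComplement(
        Biostrings::DNAStringSet(v[minus])))
    }
    seq[i] <- v
  }
  dplyr::mutate(reads, seq = seq)
}

#' Simulate Damage-seq style reads from a per-position lesion intensity
#'
#' Read counts at each lesion position are Poisson with the given
#' intensity; each read starts immediately 3' of the lesion on the lesion
#' strand, i.e. a plus-strand read starts two bases right of the lesion
#' dinucleotide's leftmost base and a minus-strand read ends at it (the
#' polymerase stops before the damage). Reads that would extend past a
#' chromosome end are dropped and tallied in attribute `skipped`.
#'
#' @param config A [sim_config()] (read lengths, seed).
#' @param genome Genome `DNAStringSet`.
#' @param profile Tibble `chrom`, `pos` (leftmost base of the lesion
#'   dinucleotide), `strand`, `intensity` (non-negative Poisson mean).
#' @param seed Optional seed overriding the config stream.
#' @return Read tibble (`chrom`, `start`, `end`, `strand`, `mapq`).
#' @export
simulate_damage_reads <- function(config, genome, profile, seed = NULL) {
  sizes <- genome_sizes(genome)
  stopifnot(all(c("chrom", "pos", "strand", "intensity") %in% names(profile)))
  assert_that(all(profile$intensity >= 0), "intensities must be non-negative")
  assert_that(all(profile$chrom %in% names(sizes)) &&
                all(profile$pos >= 0) &&
                all(profile$pos < sizes[profile$chrom]),
              "damage profile positions outside chromosome bounds")
  if (is.null(seed)) seed <- derive_seed(config$seed, 4L)
  with_seed_maybe(seed, {
    counts <- rpois(nrow(profile), profile$intensity)
    idx <- rep.int(seq_len(nrow(profile)), counts)
    if (length(idx) == 0) {
      out <- tibble::tibble(chrom = character(), start = integer(),
                            end = integer(), strand = character(),
                            mapq = integer())
      attr(out, "skipped") <- 0L
      return(out)
    }
    len <- sample_int_range(length(idx), config$read_length_range)
    pos <- profile$pos[idx]
    strand <- profile$strand[idx]
    start <- ifelse(strand == "+", pos + 2L, pos - len)
    end <- start + len
    chrom <- profile$chrom[idx]
    ok <- start >= 0 & end <= sizes[chrom]
    out <- tibble::tibble(chrom = chrom[ok], start = as.integer(start[ok]),
                          end = as.integer(end[ok]),
                          strand = strand[ok], mapq = 60L)
    out <- dplyr::arrange(out, .data$chrom, .data$start)
    attr(out, "skipped") <- sum(!ok)
    out
  })
}

#' Simulate uniform genome-wide damage reads
#'
#' Emulates the flat large-scale damage landscape: the total lesion count
#' is Poisson with mean `2 * genome size * mean_intensity` and lesion
#' positions/strands are uniform.
#'
#' @inheritParams simulate_damage_reads
#' @param mean_intensity Mean lesions per base per strand.
#' @return Read tibble as in [simulate_damage_reads()].
#' @export
simulate_uniform_damage_reads <- function(config, genome, mean_intensity,
                                          seed = NULL) {
  sizes <- genome_sizes(genome)
  if (is.null(seed)) seed <- derive_seed(config$seed, 5L)
  margin <- max(config$read_length_range) + 2L
  with_seed_maybe(seed, {
    total <- rpois(1, 2 * sum(as.numeric(sizes)) * mean_intensity)
    chrom <- sample(names(sizes), total, replace = TRUE,
                    prob = sizes / sum(sizes))
    pos <- as.integer(margin +
                        floor(runif(total) * (sizes[chrom] - 2L * margin)))
    strand <- sample(STRANDS, total, replace = TRUE)
    len <- sample_int_range(total, config$read_length_range)
    start <- ifelse(strand == "+", pos + 2L, pos - len)
    end <- start + len
    ok <- start >= 0 & end <= sizes[chrom]
    out <- tibble::tibble(chrom = chrom[ok], start = as.integer(start[ok]),
                          end = as.integer(end[ok]), strand = strand[ok],
                          mapq = 60L)
    out <- dplyr::arrange(out, .data$chrom, .data$start)
    attr(out, "skipped") <- sum(!ok)
    out
  })
}
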