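#' Replicate-wise threshold rule for spot calling
#'
#' A super hotspot bin must hold at least `min_early` reads in *every*
#' designated early replicate and at most `max_late` reads in *every*
#' designated late replicate (defaults 15 and 5, the (6-4)PP rule on the
#' 1-min and 4-h duplicates). A super coldspot is the symmetric rule with
#' relaxed thresholds: at most `max_early` reads in every early replicate
#' and at least `min_late` in every late replicate.
#'
#' @param category `"hotspot"` or `"coldspot"`.
#' @param early_samples,late_samples Character vectors of sample ids. An
#'   empty `late_samples` drops the late constraint (the CPD hotspot case,
#'   where only the 12-min libraries are used).
#' @param min_early,max_late Hotspot thresholds (inclusive).
#' @param max_early,min_late Coldspot thresholds (inclusive).
#' @return A `threshold_rule` object.
#' @export
threshold_rule <- function(category = c("hotspot", "coldspot"),
                           early_samples, late_samples = character(),
                           min_early = 15L, max_late = 5L,
                           max_early = 2L, min_late = 10L) {
  category <- match.arg(category)
  assert_that(length(early_samples) >= 1, "early_samples must be non-empty")
  structure(list(category = category,
                 early_samples = early_samples,
                 late_samples = late_samples,
                 min_early = min_early, max_late = max_late,
                 max_early = max_early, min_late = min_late),
            class = "threshold_rule")
}

#' @rdname threshold_rule
#' @param samples Sample sheet (`sample`, `time_point`) used to resolve
#'   time-point labels into sample ids.
#' @param early_time,late_time Time-point labels designating the early and
#'   late samples. `late_time = NULL` drops the late constraint.
#' @param ... Passed to [threshold_rule()].
#' @export
hotspot_rule <- function(samples, early_time = "1min", late_time = "4h",
                         ...) {
  threshold_rule("hotspot",
                 early_samples = samples$sample[samples$time_point == early_time],
                 late_samples = if (is.null(late_time)) character() else
                   samples$sample[samples$time_point == late_time],
                 ...)
}

#' @rdname threshold_rule
#' @export
coldspot_rule <- function(samples, early_time = "1min", late_time = "4h",
                          ...) {
  threshold_rule("coldspot",
                 early_samples = samples$sample[samples$time_point == early_time],
                 late_samples = if (is.null(late_time)) character() else
                   samples$sample[samples$time_point == late_time],
                 ...)
}

#' @export
print.threshold_rule <- function(x, ...) {
  cat("<threshold_rule>", x$category, "\n")
  if (x$category == "hotspot") {
    cat("  early: >=", x$min_early, "in all of",
        paste(x$early_samples, collapse = ", "), "\n")
    if (length(x$late_samples))
      cat("  late : <=", x$max_late, "in all of",
          paste(x$late_samples, collapse = ", "), "\n")
  } else {
    cat("  early: <=", x$max_early, "in all of",
        paste(x$early_samples, collapse = ", "), "\n")
    if (length(x$late_samples))
      cat("  late : >=", x$min_late, "in all of",
          paste(x$late_samples, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Call repair super hotspots or super coldspots
#'
#' Applies a [threshold_rule()] to every unmasked bin of a downsampled
#' strand-specific count matrix. Adjacent qualifying bins are reported as
#' separate fixed-width spots unless `merge = TRUE`.
#'
#' Calling coldspots on CPD data is refused unless `force = TRUE`:
#' transcription-coupled repair confounds late CPD time points.
#'
#' @param x A [bin_count_matrix()] (samples downsampled to common depth).
#' @param rule A [threshold_rule()].
#' @param merge Merge runs of adjacent qualifying bins into single spots.
#' @param force Override the CPD-coldspot guard.
#' @return Tibble of calls: `chrom`, `start`, `end`, `strand`, `category`,
#'   one count column per sample used by the rule, and `p_value`/`q_value`
#'   placeholders (filled by [test_enrichment()]), sorted by position.
#' @export
call_spots <- function(x, rule, merge = FALSE, force = FALSE) {
  stopifnot(inherits(x, "bin_counts"), inherits(rule, "threshold_rule"))
  if (x$damage_type == "CPD" && rule$category == "coldspot" && !force) {
    abort(paste("refusing to call CPD coldspots: late CPD repair is",
                "confounded by transcription-coupled repair",
                "(use force = TRUE to override)"))
  }
  missing <- setdiff(c(rule$early_samples, rule$late_samples),
                     colnames(x$counts))
  assert_that(length(missing) == 0,
              paste0("rule references absent sample(s): ",
                     paste(missing, collapse = ", ")))
  early <- x$counts[, rule$early_samples, drop = FALSE]
  late <- x$counts[, rule$late_samples, drop = FALSE]
  ok <- if (rule$category == "hotspot") {
    rowSums(early >= rule$min_early) == ncol(early) &
      rowSums(late <= rule$max_late) == ncol(late)
  } else {
    rowSums(early <= rule$max_early) == ncol(early) &
      rowSums(late >= rule$min_late) == ncol(late)
  }
  ok <- ok & !x$bins$masked
  idx <- which(ok)
  used <- c(rule$early_samples, rule$late_samples)
  out <- dplyr::bind_cols(
    x$bins[idx, c("chrom", "start", "end")],
    tibble::tibble(strand = rep(x$strand, length(idx)),
                   category = rep(rule$category, length(idx)),
                   bin_index = idx),
    tibble::as_tibble(x$counts[idx, used, drop = FALSE])
  )
  out$p_value <- NA_real_
  out$q_value <- NA_real_
  out <- dplyr::arrange(out, .data$chrom, .data$start, .data$strand)
  if (merge && nrow(out) > 1) {
    gr <- GenomicRanges::reduce(as_granges(out))
    merged <- tibble::tibble(
      chrom = as.character(GenomicRanges::seqnames(gr)),
      start = GenomicRanges::start(gr) - 1L,
      end = GenomicRanges::end(gr),
      strand = x$strand, category = rule$category)
    return(merged)
  }
  out
}
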