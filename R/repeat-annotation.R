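#' Build a queryable index over simple-sequence-repeat intervals
#'
#' Organizes repeat intervals into per-chromosome [IRanges::IRanges]
#' structures so that overlap queries against millions of mutations are a
#' single vectorized `findOverlaps()` per chromosome instead of a linear
#' scan. Overlapping and duplicate source intervals are all retained.
#'
#' @param intervals data frame with columns `chromosome`, `start`, `end`
#'   (1-based inclusive), as returned by [read_repeat_table()] or
#'   [simulate_repeat_track()].
#' @return a `repeat_index` object.
#' @export
build_repeat_index <- function(intervals) {
  if (nrow(intervals) > 0L) {
    if (any(intervals$end < intervals$start)) {
      stop_data("repeat interval with end < start")
    }
  }
  chroms <- split(seq_len(nrow(intervals)), intervals$chromosome)
  trees <- lapply(chroms, function(idx) {
    IRanges::IRanges(start = intervals$start[idx], end = intervals$end[idx])
  })
  structure(list(trees = trees, total_intervals = nrow(intervals)),
            class = "repeat_index")
}

#' @export
print.repeat_index <- function(x, ...) {
  cat(sprintf("Repeat index: %d interval(s) on %d chromosome(s)\n",
              x$total_intervals, length(x$trees)))
  invisible(x)
}

#' Tag mutations that overlap simple-sequence repeats
#'
#' Sets the `In_repeats` flag of every record: 1 if the mutation's closed
#' interval `[Start_Position, End_Position]` shares at least one base with
#' any repeat interval on the same chromosome, 0 otherwise. Any partial
#' overlap counts. For insertions (MAF convention `end = start + 1`,
#' flanking the insertion point) this means an insertion between two
#' repeat bases is tagged as in-repeat. Mutations on chromosomes absent
#' from the repeat track get 0. All other fields are unchanged and the
#' operation is idempotent.
#'
#' @param cohort a `maf_cohort`.
#' @param index a `repeat_index` from [build_repeat_index()], built with
#'   the same chromosome-name convention (both readers normalize names, so
#'   this holds automatically for files read by this package).
#' @return the cohort with an `In_repeats` column of 0/1 flags.
#' @export
tag_in_repeats <- function(cohort, index) {
  stopifnot(inherits(index, "repeat_index"))
  n <- nrow(cohort)
  flags <- integer(n)
  if (n > 0L) {
    by_chrom <- split(seq_len(n), cohort[["Chromosome"]])
    for (chrom in names(by_chrom)) {
      tree <- index$trees[[chrom]]
      if (is.null(tree)) next
      idx <- by_chrom[[chrom]]
      q <- IRanges::IRanges(start = cohort[["Start_Position"]][idx],
                            end = cohort[["End_Position"]][idx])
      hits <- IRanges::overlapsAny(q, tree)
      flags[idx] <- as.integer(hits)
    }
  }
  cohort[["In_repeats"]] <- flags
  src <- attr(cohort, "source_columns")
  attr(cohort, "source_columns") <- union(src, "In_repeats")
  cohort
}
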