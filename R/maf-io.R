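# Columns a MAF file must carry for the pipeline. Hugo_Symbol is optional
# (only the MMR-gene profile needs it).
.maf_required_cols <- c(
  "Tumor_Sample_Barcode", "Chromosome", "Start_Position", "End_Position",
  "Variant_Type", "Variant_Classification"
)

.variant_types <- c("SNP", "DNP", "TNP", "ONP", "INS", "DEL")

.variant_classifications <- c(
  "Frame_Shift_Del", "Frame_Shift_Ins", "Missense_Mutation",
  "Nonsense_Mutation", "Silent", "Splice_Site", "In_Frame_Del",
  "In_Frame_Ins", "Nonstop_Mutation", "Translation_Start_Site",
  "3'UTR", "5'UTR", "3'Flank", "5'Flank", "Intron", "RNA", "IGR"
)

#' Normalize chromosome names
#'
#' Strips a leading `chr`/`Chr` prefix and maps mitochondrial `M` to `MT`,
#' so MAF files and UCSC annotation tables join on the same naming
#' convention regardless of dialect.
#'
#' @param x character vector of chromosome names.
#' @return character vector of bare names (`"1"`..`"22"`, `"X"`, `"Y"`, `"MT"`,
#'   or the input stripped of its prefix for non-standard contigs).
#' @examples
#' normalize_chromosome(c("chr1", "Chr X", "M", "17"))
#' @export
normalize_chromosome <- function(x) {
  x <- trimws(as.character(x))
  x <- sub("^[Cc][Hh][Rr]", "", x)
  x <- trimws(x)
  x[x %in% c("M", "m")] <- "MT"
  x
}

# Count leading '#' comment lines without slurping the whole file.
.count_comment_lines <- function(path) {
  con <- file(path, open = "r")
  on.exit(close(con))
  n <- 0L
  repeat {
    ln <- readLines(con, n = 1L)
    if (length(ln) == 0L || !startsWith(ln, "#")) break
    n <- n + 1L
  }
  n
}

#' Read a mutation annotation format (MAF) file
#'
#' Parses a tab-separated MAF file into a `maf_cohort` object: one row per
#' somatic mutation, original columns preserved in order, with chromosome
#' names normalized (see [normalize_chromosome()]), coordinates validated
#' as integers, and `Variant_Type` / `Variant_Classification` values outside
#' the standard MAF vocabulary mapped to `"other"` (a single warning reports
#' how many were remapped). Leading `#` comment lines are skipped. If the
#' file already carries an `In_repeats` column (a tagged MAF), it is parsed
#' as the 0/1 repeat-overlap flag.
#'
#' @param path path to a MAF file (plain text, tab-separated).
#' @return a `maf_cohort`: a data frame of the file's columns (original
#'   order) with attribute `source_columns` recording the header.
#' @seealso [write_tagged_maf()], [tag_in_repeats()]
#' @export
read_maf <- function(path) {
  if (!file.exists(path)) stop_data(sprintf("MAF file not found: %s", path))
  skip <- .count_comment_lines(path)
  df <- utils::read.delim(path, skip = skip, header = TRUE, sep = "\t",
                          quote = "", check.names = FALSE,
                          colClasses = "character",
                          stringsAsFactors = FALSE)
  missing <- setdiff(.maf_required_cols, names(df))
  if (length(missing) > 0L) {
    stop_schema(sprintf("MAF file is missing required column(s): %s",
                        paste(missing, collapse = ", ")))
  }
  for (col in c("Start_Position", "End_Position")) {
    v <- trimws(df[[col]])
    bad <- !grepl("^[0-9]+$", v)
    if (any(bad)) {
      line <- skip + 1L + which(bad)[1L]  # +1 for the header row
      stop_parse(sprintf(
        "non-integer %s value '%s' at line %d of %s",
        col, v[which(bad)[1L]], line, path))
    }
    df[[col]] <- as.integer(v)
  }
  df[["Chromosome"]] <- normalize_chromosome(df[["Chromosome"]])
  df[["Tumor_Sample_Barcode"]] <- trimws(df[["Tumor_Sample_Barcode"]])
  if (any(!nzchar(df[["Tumor_Sample_Barcode"]]))) {
    stop_parse(sprintf("empty Tumor_Sample_Barcode in %s", path))
  }

  vt <- trimws(df[["Variant_Type"]])
  unknown_vt <- !(vt %in% .variant_types)
  vt[unknown_vt] <- "other"
  df[["Variant_Type"]] <- vt
  vc <- trimws(df[["Variant_Classification"]])
  unknown_vc <- !(vc %in% .variant_classifications)
  vc[unknown_vc] <- "other"
  df[["Variant_Classification"]] <- vc
  n_unknown <- sum(unknown_vt) + sum(unknown_vc)
  if (n_unknown > 0L) {
    warning(sprintf(
      "read_maf: %d unknown Variant_Type and %d unknown Variant_Classification value(s) mapped to 'other'",
      sum(unknown_vt), sum(unknown_vc)), call. = FALSE)
  }

  if ("In_repeats" %in% names(df)) {
    ir <- trimws(df[["In_repeats"]])
    if (!all(ir %in% c("0", "1"))) {
      stop_parse("In_repeats column must contain only 0/1")
    }
    df[["In_repeats"]] <- as.integer(ir)
  }
  new_maf_cohort(df)
}

#' Construct a MAF cohort from standard columns
#'
#' Builds a `maf_cohort` from an in-memory data frame carrying the standard
#' MAF columns (as produced by [simulate_cohort()] or assembled by hand).
#'
#' @param df data frame with at least the required MAF columns
#'   (`Tumor_Sample_Barcode`, `Chromosome`, `Start_Position`,
#'   `End_Position`, `Variant_Type`, `Variant_Classification`).
#' @return a `maf_cohort` object.
#' @export
maf_cohort <- function(df) {
  missing <- setdiff(.maf_required_cols, names(df))
  if (length(missing) > 0L) {
    stop_schema(sprintf("maf_cohort is missing required column(s): %s",
                        paste(missing, collapse = ", ")))
  }
  df[["Chromosome"]] <- normalize_chromosome(df[["Chromosome"]])
  df[["Start_Position"]] <- as.integer(df[["Start_Position"]])
  df[["End_Position"]] <- as.integer(df[["End_Position"]])
  new_maf_cohort(as.data.frame(df, stringsAsFactors = FALSE))
}

new_maf_cohort <- function(df) {
  rownames(df) <- NULL
  structure(df,
            source_columns = names(df),
            class = c("maf_cohort", "data.frame"))
}

#' @export
print.maf_cohort <- function(x, ...) {
  cat(sprintf("MAF cohort: %d mutation record(s), %d tumor(s)%s\n",
              nrow(x), length(tumor_ids(x)),
              if ("In_repeats" %in% names(x)) ", tagged (In_repeats)" else ""))
  if (nrow(x) > 0L) print(utils::head(as.data.frame(x), 5L))
  invisible(x)
}

#' Distinct tumor barcodes in a cohort
#' @param cohort a `maf_cohort`.
#' @return character vector of distinct `Tumor_Sample_Barcode` values, in
#'   order of first appearance.
#' @export
tumor_ids <- function(cohort) unique(cohort[["Tumor_Sample_Barcode"]])

is_tagged <- function(cohort) {
  "In_repeats" %in% names(cohort) && !anyNA(cohort[["In_repeats"]])
}

#' Write a repeat-tagged MAF file
#'
#' Writes the cohort back as a tab-separated MAF with the original columns
#' in their original order plus a final `In_repeats` column (0/1). Reading
#' the result with [read_maf()] recovers an identical cohort.
#'
#' @param cohort a `maf_cohort` whose records have all been tagged by
#'   [tag_in_repeats()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_tagged_maf <- function(cohort, path) {
  if (!is_tagged(cohort)) {
    stop_state("cohort has untagged records: run tag_in_repeats() before write_tagged_maf()")
  }
  cols <- setdiff(attr(cohort, "source_columns"), "In_repeats")
  out <- as.data.frame(cohort)[, cols, drop = FALSE]
  out[["In_repeats"]] <- as.integer(cohort[["In_repeats"]])
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Write a MAF file
#'
#' Writes a cohort as a tab-separated MAF with its columns in original
#' order (tagged or not). [write_tagged_maf()] is the stricter variant
#' that requires the `In_repeats` flag to be set.
#'
#' @param cohort a `maf_cohort`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_maf <- function(cohort, path) {
  utils::write.table(as.data.frame(cohort), path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Read the UCSC simpleRepeat annotation table
#'
#' Reads a `simpleRepeat.txt` (optionally `.gz`) table in UCSC layout:
#' headerless TSV with `chrom` in column 2, `chromStart` in column 3,
#' `chromEnd` in column 4 and the repeat unit length (`period`) in column
#' 6. UCSC's 0-based half-open coordinates are converted to the 1-based
#' inclusive convention used throughout this package
#' (`start = chromStart + 1`, `end = chromEnd`), and only repeats whose
#' unit length is at most `max_period` base pairs are retained — loci with
#' longer units cannot be assayed reliably with the short (100 bp) reads
#' behind typical exome MAFs.
#'
#' @param path path to the table (plain or gzip-compressed TSV).
#' @param max_period maximum repeat unit length in bp to keep (default 5).
#' @return data frame with columns `chromosome` (normalized), `start`,
#'   `end` (1-based inclusive) and `period`.
#' @export
read_repeat_table <- function(path, max_period = 5) {
  if (!file.exists(path)) stop_data(sprintf("repeat table not found: %s", path))
  con <- if (grepl("\\.gz$", path)) gzfile(path, open = "rt") else file(path, open = "rt")
  lines <- tryCatch(readLines(con), error = function(e) {
    close(con)
    stop_data(sprintf("failed to read repeat table %s: %s", path, conditionMessage(e)))
  })
  close(con)
  lines <- lines[nzchar(lines)]
  empty <- data.frame(chromosome = character(), start = integer(),
                      end = integer(), period = integer(),
                      stringsAsFactors = FALSE)
  if (length(lines) == 0L) return(empty)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf < 6L)) {
    stop_parse(sprintf("malformed repeat-table row (fewer than 6 fields) at line %d of %s",
                       which(nf < 6L)[1L], path))
  }
  chrom <- vapply(parts, `[[`, "", 2L)
  cs <- vapply(parts, `[[`, "", 3L)
  ce <- vapply(parts, `[[`, "", 4L)
  pd <- vapply(parts, `[[`, "", 6L)
  for (v in list(chromStart = cs, chromEnd = ce, period = pd)) {
    bad <- !grepl("^[0-9]+$", v)
    if (any(bad)) {
      stop_parse(sprintf("non-integer field at line %d of %s",
                         which(bad)[1L], path))
    }
  }
  out <- data.frame(
    chromosome = normalize_chromosome(chrom),
    start = as.integer(cs) + 1L,
    end = as.integer(ce),
    period = as.integer(pd),
    stringsAsFactors = FALSE
  )
  out <- out[out$period <= max_period, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write a repeat track in UCSC simpleRepeat layout
#'
#' Inverse of [read_repeat_table()]: emits a headerless TSV whose columns
#' 2/3/4/6 are `chrom` (with `chr` prefix), 0-based `chromStart`,
#' `chromEnd` and `period`, so the file round-trips through the reader.
#'
#' @param track data frame with columns `chromosome`, `start`, `end`,
#'   `period` (1-based inclusive coordinates).
#' @param path output path (a `.gz` suffix writes gzip-compressed text).
#' @return `path`, invisibly.
#' @export
write_repeat_track <- function(track, path) {
  out <- data.frame(
    bin = 0L,
    chrom = paste0("chr", track$chromosome),
    chromStart = track$start - 1L,
    chromEnd = track$end,
    name = sprintf("trf%d", seq_len(nrow(track))),
    period = track$period,
    stringsAsFactors = FALSE
  )
  con <- if (grepl("\\.gz$", path)) gzfile(path, open = "wt") else file(path, open = "wt")
  on.exit(close(con))
  utils::write.table(out, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
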