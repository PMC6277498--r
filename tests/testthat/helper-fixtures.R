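# Fixtures are built in code at test time; nothing binary is stored.

toy_maf_lines <- function(comment = TRUE) {
  header <- paste("Hugo_Symbol", "Chromosome", "Start_Position", "End_Position",
                  "Variant_Classification", "Variant_Type",
                  "Tumor_Sample_Barcode", sep = "\t")
  rows <- c(
    paste("TP53", "chr1", "150", "150", "Missense_Mutation", "SNP", "TCGA-AA-0001", sep = "\t"),
    paste("MLH1", "chr1", "95", "105", "Frame_Shift_Del", "DEL", "TCGA-AA-0001", sep = "\t"),
    paste("KRAS", "chr2", "500", "501", "Frame_Shift_Ins", "INS", "TCGA-AA-0001", sep = "\t")
  )
  c(if (comment) "#version 2.4", header, rows)
}

write_toy_maf <- function(path = tempfile(fileext = ".maf"), comment = TRUE) {
  writeLines(toy_maf_lines(comment), path)
  path
}

# UCSC simpleRepeat rows: bin chrom chromStart chromEnd name period ...
write_toy_repeats <- function(path = tempfile(fileext = ".txt"),
                              rows = list(c("chr1", 99, 199, 2),
                                          c("chr2", 1000, 1100, 6))) {
  lines <- vapply(seq_along(rows), function(i) {
    r <- rows[[i]]
    paste(0, r[[1]], r[[2]], r[[3]], sprintf("trf%d", i), r[[4]], sep = "\t")
  }, "")
  writeLines(lines, path)
  path
}

# Random mutation records on a small genome, as a plain data frame.
random_records <- function(n, n_tumors = 3, chroms = c("1", "2"),
                           max_pos = 1e5) {
  vt <- sample(c("SNP", "DEL", "INS", "DNP"), n, replace = TRUE,
               prob = c(0.6, 0.2, 0.15, 0.05))
  start <- sample.int(max_pos, n, replace = TRUE)
  span <- ifelse(vt == "SNP", 1L,
                 ifelse(vt == "INS", 2L, sample(1:10, n, replace = TRUE)))
  data.frame(
    Hugo_Symbol = sample(c("MLH1", "MSH2", "TP53", "KRAS", "GENE1"), n, TRUE),
    Chromosome = sample(chroms, n, replace = TRUE),
    Start_Position = start,
    End_Position = start + span - 1L,
    Variant_Classification = sample(c("Missense_Mutation", "Silent",
                                      "Frame_Shift_Del", "Frame_Shift_Ins",
                                      "Nonsense_Mutation", "3'UTR"),
                                    n, replace = TRUE),
    Variant_Type = vt,
    Tumor_Sample_Barcode = sample(sprintf("T%02d", seq_len(n_tumors)), n,
                                  replace = TRUE),
    stringsAsFactors = FALSE
  )
}

random_intervals <- function(n, chroms = c("1", "2"), max_pos = 1e5) {
  start <- sample.int(max_pos, n, replace = TRUE)
  width <- sample(1:60, n, replace = TRUE)
  data.frame(chromosome = sample(chroms, n, replace = TRUE),
             start = start, end = start + width - 1L,
             period = sample(1:5, n, replace = TRUE),
             stringsAsFactors = FALSE)
}

# Linear-scan overlap oracle, independent of the IRanges-backed index.
brute_force_flags <- function(records, intervals) {
  vapply(seq_len(nrow(records)), function(i) {
    same <- intervals$chromosome == records$Chromosome[i]
    as.integer(any(same &
                     intervals$start <= records$End_Position[i] &
                     intervals$end >= records$Start_Position[i]))
  }, integer(1))
}

# Separable two-class cloud for classifier tests.
separable_cloud <- function(n_per_class = 100, p = 4, gap = 8, seed = 11) {
  msiclass:::with_seed(seed, {
    x <- rbind(matrix(rnorm(n_per_class * p), ncol = p),
               matrix(rnorm(n_per_class * p, mean = gap), ncol = p))
    dimnames(x) <- list(sprintf("S%03d", seq_len(2 * n_per_class)),
                        paste0("f", seq_len(p)))
    list(x = x, y = rep(c("MSS", "MSI-H"), each = n_per_class))
  })
}
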