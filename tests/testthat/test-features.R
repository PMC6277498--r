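# Independent filter-and-count oracle for a single tumor's features.
oracle_features <- function(df, capture) {
  snp <- df$Variant_Type == "SNP"
  indel <- df$Variant_Type %in% c("INS", "DEL")
  inr <- df$In_repeats == 1
  rat <- function(a, b) if (b == 0) 0 else a / b
  v <- c(SNP = sum(snp), INDEL = sum(indel), TOTAL = nrow(df),
         SNP_R = sum(snp & inr), INDEL_R = sum(indel & inr),
         TOTAL_R = sum(inr)) / capture
  v <- c(v,
         RATIO_SNP = rat(sum(snp & inr), sum(snp)),
         RATIO_INDEL = rat(sum(indel & inr), sum(indel)),
         RATIO_TOTAL = rat(sum(inr), nrow(df)))
  cls <- vapply(feature_spec()$classification,
                function(cl) sum(df$Variant_Classification == cl), 0) / capture
  c(v, cls)
}

tag_randomly <- function(recs, seed) {
  recs$In_repeats <- msiclass:::with_seed(seed, rbinom(nrow(recs), 1, 0.3))
  maf_cohort(recs)
}

test_that("per-Mb arithmetic and panel shape are exact", {
  recs <- data.frame(
    Hugo_Symbol = "G", Chromosome = "1",
    Start_Position = seq_len(44), End_Position = seq_len(44),
    Variant_Classification = "Missense_Mutation", Variant_Type = "SNP",
    Tumor_Sample_Barcode = "T1", In_repeats = 0L, stringsAsFactors = FALSE)
  feats <- extract_features(maf_cohort(recs), capture_mb = 44)
  expect_equal(colnames(feats), feature_names())
  expect_length(feature_names(), 22L)
  expect_equal(feats["T1", "SNP"], 1.0)
  expect_equal(feats["T1", "SNP_R"], 0.0)
  expect_equal(feats["T1", "RATIO_SNP"], 0.0)
  expect_equal(feats["T1", "Missense_Mutation"], 1.0)
  expect_equal(feats["T1", "Frame_Shift_Del"], 0.0)
})

test_that("untagged cohorts and missing capture sizes are errors", {
  cohort <- maf_cohort(random_records(10))
  expect_error(extract_features(cohort, 44), class = "msiclass_state_error")
  tagged <- tag_randomly(random_records(10), 1)
  expect_error(extract_features(tagged, c(T01 = 44)),
               class = "msiclass_config_error")
})

test_that("every feature matches the filter-and-count oracle on random cohorts", {
  for (i in seq_len(100)) {
    recs <- msiclass:::with_seed(1000 + i, random_records(200, n_tumors = 3))
    cohort <- tag_randomly(recs, 2000 + i)
    capture <- 10 * i %% 7 + 20
    feats <- extract_features(cohort, capture)
    for (tid in rownames(feats)) {
      sub <- as.data.frame(cohort)[cohort$Tumor_Sample_Barcode == tid, ]
      expect_equal(unlist(feats[tid, ]), oracle_features(sub, capture),
                   tolerance = 1e-12)
    }
  }
})

test_that("count features scale as 1/capture and ratios are unchanged", {
  cohort <- tag_randomly(random_records(300, n_tumors = 4), 5)
  f1 <- extract_features(cohort, 44)
  f2 <- extract_features(cohort, 88)
  counts <- setdiff(feature_names(), c("RATIO_SNP", "RATIO_INDEL", "RATIO_TOTAL"))
  expect_equal(as.matrix(f1[, counts]) / 2, as.matrix(f2[, counts]))
  ratios <- c("RATIO_SNP", "RATIO_INDEL", "RATIO_TOTAL")
  expect_equal(f1[, ratios], f2[, ratios])
})

test_that("feature extraction is additive over tumors and respects repeat bounds", {
  recs <- msiclass:::with_seed(6, random_records(400, n_tumors = 4))
  cohort <- tag_randomly(recs, 7)
  all_feats <- extract_features(cohort, 44)
  for (tid in tumor_ids(cohort)) {
    solo <- maf_cohort(as.data.frame(cohort)[cohort$Tumor_Sample_Barcode == tid, ])
    expect_equal(unlist(extract_features(solo, 44)[tid, ]),
                 unlist(all_feats[tid, ]))
  }
  # *_R never exceeds its overall counterpart; TOTAL >= SNP + INDEL with
  # equality only when no DNP/TNP/ONP/other records exist
  expect_true(all(all_feats$SNP_R <= all_feats$SNP))
  expect_true(all(all_feats$INDEL_R <= all_feats$INDEL))
  expect_true(all(all_feats$TOTAL_R <= all_feats$TOTAL))
  has_other <- tapply(!(cohort$Variant_Type %in% c("SNP", "INS", "DEL")),
                      factor(cohort$Tumor_Sample_Barcode, tumor_ids(cohort)), any)
  gap <- all_feats$TOTAL - all_feats$SNP - all_feats$INDEL
  expect_equal(gap > 1e-12, as.vector(has_other[rownames(all_feats)]))
})

test_that("feature subsetting preserves rows and rejects unknown names", {
  cohort <- tag_randomly(random_records(100, n_tumors = 3), 8)
  feats <- set_msi_status(extract_features(cohort, 44),
                          c(T01 = "MSS", T02 = "MSI-H", T03 = "MSS"))
  nine <- feature_spec()$type
  sub <- select_feature_subset(feats, nine)
  expect_equal(colnames(sub), nine)
  expect_equal(rownames(sub), rownames(feats))
  expect_equal(msi_status(sub), msi_status(feats))
  expect_equal(select_feature_subset(feats, feature_names()), feats)
  err <- expect_error(select_feature_subset(feats, c("SNP", "BOGUS")),
                      class = "msiclass_key_error")
  expect_match(conditionMessage(err), "BOGUS")
})

test_that("MMR gene profiling reports presence and counts per tumor", {
  recs <- data.frame(
    Hugo_Symbol = c("MLH1", "TP53", "MLH1", "MSH2", "MSH3", "MSH6", "PMS2"),
    Chromosome = "1", Start_Position = 1:7, End_Position = 1:7,
    Variant_Classification = "Missense_Mutation", Variant_Type = "SNP",
    Tumor_Sample_Barcode = c("A", "A", "B", "B", "B", "B", "B"),
    stringsAsFactors = FALSE)
  prof <- mmr_gene_profile(maf_cohort(recs))
  expect_equal(unlist(prof$presence["A", ]),
               c(MLH1 = 1L, MSH2 = 0L, MSH3 = 0L, MSH6 = 0L, PMS2 = 0L))
  expect_true(all(prof$presence["B", ] == 1L))   # all five mutated
  expect_equal(prof$counts["B", "MLH1"], 1L)
  empty <- mmr_gene_profile(maf_cohort(recs[0, ]))
  expect_equal(nrow(empty$counts), 0L)
})

test_that("feature CSV round-trips, merges MSI-L into MSS and checks schema", {
  cohort <- tag_randomly(random_records(120, n_tumors = 3), 9)
  feats <- set_msi_status(extract_features(cohort, 44),
                          c(T01 = "MSS", T02 = "MSI-L", T03 = "MSI-H"))
  expect_equal(unname(msi_status(feats)["T02"]), "MSS")  # merged on attach
  p <- tempfile(fileext = ".csv")
  write_feature_csv(feats, p)
  back <- read_feature_csv(p, spec = feature_spec())
  expect_equal(as.data.frame(back), as.data.frame(feats), ignore_attr = TRUE)
  expect_equal(rownames(back), rownames(feats))
  expect_equal(msi_status(back), msi_status(feats))

  # label normalization happens on read as well
  raw <- utils::read.csv(p, check.names = FALSE)
  raw$MSI_status[1] <- "MSI-L"
  utils::write.csv(raw, p, row.names = FALSE)
  expect_equal(unname(msi_status(read_feature_csv(p))[1]), "MSS")

  raw$SNP <- NULL
  utils::write.csv(raw, p, row.names = FALSE)
  expect_error(read_feature_csv(p, spec = feature_spec()), "SNP",
               class = "msiclass_schema_error")
})
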