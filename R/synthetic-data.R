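# Synthetic cohorts for download-free testing. The generator emulates the
# statistical structure of real exome cohorts: right-skewed per-Mb
# mutational loads (negative-binomial counts), MSI-H tumors elevated in
# SNV, micro-indel and frameshift rates relative to MSS, and a repeat
# track in UCSC simpleRepeat layout so every pipeline stage (read, tag,
# extract, fit, evaluate) can be exercised on files it wrote itself.

#' Per-class mutation rate profile
#'
#' Describes one class's somatic mutational load: per-Mb mean rates of
#' SNVs, micro-indels and multi-nucleotide substitutions (DNP/TNP), the
#' probability that each lands inside a simple-sequence repeat, and the
#' distribution of Variant_Classification categories within each type.
#'
#' @param snp,indel,other mean events per Mb of captured exome.
#' @param p_snp_rep,p_indel_rep,p_other_rep probability an event of that
#'   type falls inside a simple-sequence repeat.
#' @param snp_class,indel_class,other_class named probability vectors over
#'   Variant_Classification categories (each sums to 1). Indel categories
#'   ending in `_Ins` generate `INS` records, the rest `DEL`.
#' @return a `mutation_profile` object.
#' @rdname mutation_profile
#' @export
mutation_profile <- function(snp, indel, other,
                             p_snp_rep, p_indel_rep, p_other_rep,
                             snp_class, indel_class, other_class) {
  for (p in list(snp_class, indel_class, other_class)) {
    if (abs(sum(p) - 1) > 1e-8) stop_config("class probabilities must sum to 1")
    if (any(p < 0)) stop_config("class probabilities must be non-negative")
  }
  if (any(c(snp, indel, other) < 0)) stop_config("rates must be non-negative")
  for (p in c(p_snp_rep, p_indel_rep, p_other_rep)) {
    if (p < 0 || p > 1) stop_config("repeat probabilities must be in [0, 1]")
  }
  structure(list(snp = snp, indel = indel, other = other,
                 p_snp_rep = p_snp_rep, p_indel_rep = p_indel_rep,
                 p_other_rep = p_other_rep,
                 snp_class = snp_class, indel_class = indel_class,
                 other_class = other_class),
            class = "mutation_profile")
}

#' @details `mss_profile()` and `msih_profile()` are the default class
#'   profiles: an MSS tumor averages ~2 SNVs and ~0.2 micro-indels per Mb
#'   with a modest in-repeat fraction, while an MSI-H tumor averages ~12
#'   SNVs and ~3 micro-indels per Mb, with most indels inside repeats and
#'   a larger frameshift share — the slippage signature of mismatch-repair
#'   loss. Every feature's mean rate is higher under the MSI-H profile.
#' @rdname mutation_profile
#' @export
mss_profile <- function() {
  mutation_profile(
    snp = 2.0, indel = 0.2, other = 0.05,
    p_snp_rep = 0.06, p_indel_rep = 0.30, p_other_rep = 0.06,
    snp_class = c(Missense_Mutation = 0.60, Silent = 0.24,
                  Nonsense_Mutation = 0.04, Splice_Site = 0.02,
                  `3'UTR` = 0.035, `5'UTR` = 0.02, `5'Flank` = 0.02,
                  Nonstop_Mutation = 0.0125, Translation_Start_Site = 0.0125),
    indel_class = c(Frame_Shift_Del = 0.40, Frame_Shift_Ins = 0.25,
                    In_Frame_Del = 0.20, In_Frame_Ins = 0.15),
    other_class = c(Missense_Mutation = 0.8, Silent = 0.2)
  )
}

#' @rdname mutation_profile
#' @export
msih_profile <- function() {
  mutation_profile(
    snp = 12, indel = 3.0, other = 0.3,
    p_snp_rep = 0.10, p_indel_rep = 0.65, p_other_rep = 0.10,
    snp_class = c(Missense_Mutation = 0.60, Silent = 0.24,
                  Nonsense_Mutation = 0.04, Splice_Site = 0.02,
                  `3'UTR` = 0.035, `5'UTR` = 0.02, `5'Flank` = 0.02,
                  Nonstop_Mutation = 0.0125, Translation_Start_Site = 0.0125),
    indel_class = c(Frame_Shift_Del = 0.50, Frame_Shift_Ins = 0.30,
                    In_Frame_Del = 0.12, In_Frame_Ins = 0.08),
    other_class = c(Missense_Mutation = 0.8, Silent = 0.2)
  )
}

# Interpolate between the MSS and MSI-H profiles. effect = 1 is the full
# default separation, effect = 0 collapses the classes.
.effective_msih <- function(mss, msih, effect) {
  geo <- function(a, b) ifelse(a > 0, a * (b / a)^effect, b * effect)
  lin <- function(a, b) a + effect * (b - a)
  mix_class <- function(a, b) {
    nms <- union(names(a), names(b))
    av <- stats::setNames(rep(0, length(nms)), nms); av[names(a)] <- a
    bv <- stats::setNames(rep(0, length(nms)), nms); bv[names(b)] <- b
    p <- lin(av, bv)
    p / sum(p)
  }
  mutation_profile(
    snp = geo(mss$snp, msih$snp),
    indel = geo(mss$indel, msih$indel),
    other = geo(mss$other, msih$other),
    p_snp_rep = lin(mss$p_snp_rep, msih$p_snp_rep),
    p_indel_rep = lin(mss$p_indel_rep, msih$p_indel_rep),
    p_other_rep = lin(mss$p_other_rep, msih$p_other_rep),
    snp_class = mix_class(mss$snp_class, msih$snp_class),
    indel_class = mix_class(mss$indel_class, msih$indel_class),
    other_class = mix_class(mss$other_class, msih$other_class)
  )
}

#' Specify a synthetic cohort
#'
#' Defines the study conditions for [simulate_cohort()]: how many MSS and
#' MSI-H tumors per stratum (tumor type), the captured exome length, the
#' two class rate profiles, the negative-binomial dispersion, and the
#' synthetic genome (chromosome lengths, repeat density, repeat-unit
#' length distribution over 1-5 bp).
#'
#' A small fraction of tumors can be drawn with the *opposite* class's
#' rate profile while keeping their nominal label:
#' `frac_attenuated_pos` gives MSI-H-labelled tumors an MSS-like load
#' (mimicking assay-positive tumors whose mismatch repair is intact) and
#' `frac_elevated_neg` gives MSS-labelled tumors an MSI-H-like load.
#' These irreducibly confusable tumors are what keeps synthetic
#' classification performance below 100%.
#'
#' @param n_mss,n_msih tumor counts for a single-stratum cohort (ignored
#'   when `strata` is given).
#' @param capture_mb captured exome length in Mb.
#' @param stratum stratum name for the single-stratum form.
#' @param strata optional data frame with columns `stratum`, `n_mss`,
#'   `n_msih`, `capture_mb` and optionally `frac_attenuated_pos`,
#'   `frac_elevated_neg` (per-stratum overrides).
#' @param mss,msih `mutation_profile`s for the two classes.
#' @param dispersion negative-binomial size parameter for per-tumor event
#'   counts (smaller = more right-skewed; default 3).
#' @param effect effect-size multiplier in (0, 1]: 1 uses the MSI-H
#'   profile as given, smaller values interpolate it toward MSS.
#' @param chrom_lengths named vector of synthetic chromosome lengths (bp).
#' @param repeat_density fraction of the genome covered by simple repeats.
#' @param period_probs probabilities of repeat-unit lengths 1..5.
#' @param frac_attenuated_pos,frac_elevated_neg default mislabel-profile
#'   fractions (see above).
#' @return a `cohort_spec` object.
#' @export
cohort_spec <- function(n_mss = 100, n_msih = 100, capture_mb = 44,
                        stratum = "cohort", strata = NULL,
                        mss = mss_profile(), msih = msih_profile(),
                        dispersion = 3, effect = 1,
                        chrom_lengths = c("1" = 1e7, "2" = 1e7),
                        repeat_density = 0.05,
                        period_probs = c(0.35, 0.25, 0.2, 0.12, 0.08),
                        frac_attenuated_pos = 0, frac_elevated_neg = 0) {
  if (is.null(strata)) {
    strata <- data.frame(stratum = stratum, n_mss = n_mss, n_msih = n_msih,
                         capture_mb = capture_mb,
                         frac_attenuated_pos = frac_attenuated_pos,
                         frac_elevated_neg = frac_elevated_neg,
                         stringsAsFactors = FALSE)
  } else {
    strata <- as.data.frame(strata, stringsAsFactors = FALSE)
    need <- c("stratum", "n_mss", "n_msih", "capture_mb")
    missing <- setdiff(need, names(strata))
    if (length(missing) > 0L) {
      stop_config(sprintf("strata is missing column(s): %s",
                          paste(missing, collapse = ", ")))
    }
    if (is.null(strata$frac_attenuated_pos)) strata$frac_attenuated_pos <- frac_attenuated_pos
    if (is.null(strata$frac_elevated_neg)) strata$frac_elevated_neg <- frac_elevated_neg
  }
  if (sum(strata$n_mss) + sum(strata$n_msih) <= 0) {
    stop_config("cohort must contain at least one tumor")
  }
  if (any(strata$capture_mb <= 0)) stop_config("capture_mb must be positive")
  if (length(chrom_lengths) == 0L || any(chrom_lengths <= 0)) {
    stop_config("chromosome lengths must be positive")
  }
  if (repeat_density < 0 || repeat_density >= 1) {
    stop_config("repeat_density must be in [0, 1)")
  }
  if (length(period_probs) != 5L || any(period_probs < 0)) {
    stop_config("period_probs must be 5 non-negative values (unit lengths 1..5)")
  }
  if (effect < 0 || effect > 1) stop_config("effect must be in [0, 1]")
  structure(list(strata = strata, mss = mss,
                 msih = .effective_msih(mss, msih, effect),
                 dispersion = dispersion, effect = effect,
                 chrom_lengths = chrom_lengths,
                 repeat_density = repeat_density,
                 period_probs = period_probs / sum(period_probs)),
            class = "cohort_spec")
}

#' Four-type exome cohort design
#'
#' The default multi-stratum design: four tumor types (colon, rectal,
#' stomach, endometrial) with 377/131/437/487 tumors captured at
#' 44/44/50/44 Mb, per-type MSI-H prevalences of 15%/3%/22%/30% (about
#' 21% MSI-H overall), a small fraction of low-load MSI-H tumors in the
#' endometrial (10%) and stomach (4%) strata, and ~1% of endometrial MSS
#' tumors with an MSI-H-like load — the discordance structure seen in real
#' pan-tumor cohorts, where nearly all assay/classifier disagreements
#' arise in endometrial and stomach tumors while colorectal tumors
#' separate cleanly.
#'
#' @param ... overrides passed on to [cohort_spec()].
#' @return a `cohort_spec`.
#' @export
cohort_spec_tcga_like <- function(...) {
  strata <- data.frame(
    stratum = c("COAD", "READ", "STAD", "UCEC"),
    n_mss = c(320, 127, 341, 341),
    n_msih = c(57, 4, 96, 146),
    capture_mb = c(44, 44, 50, 44),
    frac_attenuated_pos = c(0, 0, 0.04, 0.10),
    frac_elevated_neg = c(0, 0, 0, 0.012),
    stringsAsFactors = FALSE
  )
  cohort_spec(strata = strata, ...)
}

#' Expected per-Mb features under a rate profile
#'
#' Closed-form expectations of the 22-feature panel for tumors drawn from
#' a `mutation_profile`: count features equal the profile's mean rates
#' (per Mb); ratio features equal the in-repeat probability corrected for
#' the chance that the denominator count is zero under the
#' negative-binomial model (`RATIO_TOTAL` uses the rate-weighted mean
#' in-repeat probability, exact up to the random weighting of types).
#'
#' @param profile a `mutation_profile`.
#' @param capture_mb capture size in Mb (enters the zero-count correction).
#' @param dispersion negative-binomial size parameter.
#' @param spec a `feature_spec`.
#' @return named numeric vector over [feature_names()].
#' @export
expected_features <- function(profile, capture_mb, dispersion = 3,
                              spec = feature_spec()) {
  p0 <- function(mu) if (mu <= 0) 1 else (dispersion / (dispersion + mu))^dispersion
  rates <- c(snp = profile$snp, indel = profile$indel, other = profile$other)
  preps <- c(snp = profile$p_snp_rep, indel = profile$p_indel_rep,
             other = profile$p_other_rep)
  total <- sum(rates)
  ratio <- function(p, mu) if (mu <= 0) 0 else p * (1 - p0(mu))
  out <- c(
    SNP = rates[["snp"]],
    INDEL = rates[["indel"]],
    TOTAL = total,
    SNP_R = rates[["snp"]] * preps[["snp"]],
    INDEL_R = rates[["indel"]] * preps[["indel"]],
    TOTAL_R = sum(rates * preps),
    RATIO_SNP = ratio(preps[["snp"]], rates[["snp"]] * capture_mb),
    RATIO_INDEL = ratio(preps[["indel"]], rates[["indel"]] * capture_mb),
    RATIO_TOTAL = if (total <= 0) 0 else {
      # ratio of sums with random type weights: second-order (delta method)
      # correction around the mean counts, times the non-zero probability
      mu <- rates * capture_mb
      vars <- mu + mu^2 / dispersion
      EA <- sum(mu * preps); ET <- sum(mu)
      (EA / ET + (EA * sum(vars) - ET * sum(preps * vars)) / ET^3) *
        (1 - prod(vapply(mu, p0, 0)))
    }
  )
  cls <- stats::setNames(rep(0, length(spec$classification)), spec$classification)
  for (part in c("snp", "indel", "other")) {
    probs <- profile[[paste0(part, "_class")]]
    hit <- intersect(names(probs), names(cls))
    cls[hit] <- cls[hit] + rates[[part]] * probs[hit]
  }
  c(out, cls)
}

.sim_track <- function(spec) {
  lens <- spec$chrom_lengths
  if (spec$repeat_density == 0) {
    return(data.frame(chromosome = character(), start = integer(),
                      end = integer(), period = integer(),
                      stringsAsFactors = FALSE))
  }
  mean_len <- 45
  out <- lapply(names(lens), function(chrom) {
    n <- max(0L, round(spec$repeat_density * lens[[chrom]] / mean_len))
    if (n == 0L) return(NULL)
    width <- sample(20:70, n, replace = TRUE)
    start <- floor(stats::runif(n, min = 1, max = lens[[chrom]] - width))
    data.frame(chromosome = chrom,
               start = as.integer(start),
               end = as.integer(start + width - 1L),
               period = sample(1:5, n, replace = TRUE, prob = spec$period_probs),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  out <- out[order(out$chromosome, out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Simulate a simple-repeat track
#'
#' Draws repeat intervals over the spec's synthetic genome (unit lengths
#' 1-5 bp, density and length distribution from the spec). Writable in
#' UCSC simpleRepeat layout via [write_repeat_track()], after which
#' [read_repeat_table()] round-trips it.
#'
#' @param spec a `cohort_spec`.
#' @param seed integer seed (same seed, same track).
#' @return data frame of intervals (`chromosome`, `start`, `end`,
#'   `period`), 1-based inclusive.
#' @export
simulate_repeat_track <- function(spec, seed = 1) {
  stopifnot(inherits(spec, "cohort_spec"))
  with_seed(seed, .sim_track(spec))
}

# Complement of the merged repeat intervals within each chromosome,
# restricted to segments wide enough to hold any event span.
.complement_segments <- function(track, chrom_lengths, min_width = 12L) {
  out <- lapply(names(chrom_lengths), function(chrom) {
    len <- chrom_lengths[[chrom]]
    iv <- track[track$chromosome == chrom, , drop = FALSE]
    if (nrow(iv) == 0L) {
      return(data.frame(chromosome = chrom, start = 1L,
                        end = as.integer(len), stringsAsFactors = FALSE))
    }
    merged <- IRanges::reduce(IRanges::IRanges(iv$start, iv$end))
    gaps <- IRanges::gaps(merged, start = 1L, end = as.integer(len))
    data.frame(chromosome = chrom,
               start = IRanges::start(gaps), end = IRanges::end(gaps),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  out$width <- out$end - out$start + 1L
  out <- out[out$width >= min_width, , drop = FALSE]
  if (nrow(out) == 0L) {
    stop_config("synthetic genome has no repeat-free segment wide enough for event placement")
  }
  rownames(out) <- NULL
  out
}

# Place n events of the given spans. in_repeat events start inside a
# repeat interval (any-overlap tagging then flags them); out-of-repeat
# events are fully contained in a repeat-free segment, so tagging flags
# neither flank.
.place_events <- function(n, span, in_repeat, track, comp) {
  chrom <- character(n); start <- integer(n)
  if (any(in_repeat)) {
    k <- sum(in_repeat)
    w <- track$end - track$start + 1L
    idx <- sample.int(nrow(track), k, replace = TRUE, prob = w)
    chrom[in_repeat] <- track$chromosome[idx]
    start[in_repeat] <- track$start[idx] +
      floor(stats::runif(k) * w[idx])
  }
  if (any(!in_repeat)) {
    k <- sum(!in_repeat)
    sp <- span[!in_repeat]
    idx <- sample.int(nrow(comp), k, replace = TRUE, prob = comp$width)
    chrom[!in_repeat] <- comp$chromosome[idx]
    start[!in_repeat] <- comp$start[idx] +
      floor(stats::runif(k) * (comp$width[idx] - sp + 1L))
  }
  list(chromosome = chrom, start = start, end = start + span - 1L)
}

#' Simulate a labelled MAF cohort
#'
#' Draws, for every tumor, negative-binomial event counts per mutation
#' type under its class's rate profile, assigns repeat membership and
#' Variant_Classification per the profile's probabilities, and places
#' each event on the synthetic genome so that the recorded repeat
#' membership is exactly what [tag_in_repeats()] recovers (in-repeat
#' events start inside a repeat interval; out-of-repeat events are fully
#' contained in repeat-free sequence). Insertions use the MAF convention
#' `End_Position = Start_Position + 1`.
#'
#' @param spec a `cohort_spec`.
#' @param seed integer seed; all outputs are reproducible from it.
#' @param dir optional directory: when given, writes `cohort.maf`
#'   (untagged MAF), `simpleRepeat.txt` (UCSC layout), `labels.csv`
#'   (tumor id, stratum, MSI status, profile used, capture Mb) and
#'   `truth.csv` (per-record repeat membership).
#' @return list with `cohort` (untagged `maf_cohort`), `track` (repeat
#'   intervals), `truth` (integer vector: true `In_repeats` per record),
#'   `labels` (data frame: `tumor_id`, `stratum`, `status`, `profile`,
#'   `capture_mb`), `expected` (matrix of closed-form expected features
#'   per tumor, from the profile each tumor was actually drawn with),
#'   `capture_mb` (named vector), and `seed`.
#' @export
simulate_cohort <- function(spec, seed = 1, dir = NULL) {
  stopifnot(inherits(spec, "cohort_spec"))
  res <- with_seed(seed, {
    track <- .sim_track(spec)

    tumors <- do.call(rbind, lapply(seq_len(nrow(spec$strata)), function(i) {
      st <- spec$strata[i, ]
      n <- st$n_mss + st$n_msih
      if (n == 0L) return(NULL)
      status <- c(rep("MSS", st$n_mss), rep("MSI-H", st$n_msih))
      profile <- status
      if (st$n_msih > 0L && st$frac_attenuated_pos > 0) {
        flip <- stats::runif(st$n_msih) < st$frac_attenuated_pos
        profile[st$n_mss + which(flip)] <- "MSS"
      }
      if (st$n_mss > 0L && st$frac_elevated_neg > 0) {
        flip <- stats::runif(st$n_mss) < st$frac_elevated_neg
        profile[which(flip)] <- "MSI-H"
      }
      data.frame(tumor_id = sprintf("SYN-%s-%04d", st$stratum, seq_len(n)),
                 stratum = st$stratum, status = status, profile = profile,
                 capture_mb = st$capture_mb, stringsAsFactors = FALSE)
    }))

    have_track <- nrow(track) > 0L
    comp <- .complement_segments(track, spec$chrom_lengths)
    gene_pool <- sprintf("GENE%03d", seq_len(200))

    recs <- list()
    truth <- list()
    for (prof_name in c("MSS", "MSI-H")) {
      prof <- if (prof_name == "MSS") spec$mss else spec$msih
      rows <- which(tumors$profile == prof_name)
      if (length(rows) == 0L) next
      cap <- tumors$capture_mb[rows]
      ids <- tumors$tumor_id[rows]
      for (part in c("snp", "indel", "other")) {
        rate <- prof[[part]]
        if (rate <= 0) next
        counts <- stats::rnbinom(length(rows), mu = rate * cap,
                                 size = spec$dispersion)
        total <- sum(counts)
        if (total == 0L) next
        tumor <- rep(ids, counts)
        p_rep <- if (have_track) prof[[paste0("p_", part, "_rep")]] else 0
        in_rep <- stats::runif(total) < p_rep
        probs <- prof[[paste0(part, "_class")]]
        cls <- sample(names(probs), total, replace = TRUE, prob = probs)
        if (part == "snp") {
          vt <- rep("SNP", total)
          span <- rep(1L, total)
        } else if (part == "indel") {
          vt <- ifelse(grepl("_Ins$", cls), "INS", "DEL")
          span <- ifelse(vt == "INS", 2L, sample(1:8, total, replace = TRUE))
        } else {
          vt <- sample(c("DNP", "TNP"), total, replace = TRUE, prob = c(0.8, 0.2))
          span <- ifelse(vt == "DNP", 2L, 3L)
        }
        pos <- .place_events(total, span, in_rep, track, comp)
        recs[[length(recs) + 1L]] <- data.frame(
          Hugo_Symbol = sample(gene_pool, total, replace = TRUE),
          Chromosome = pos$chromosome,
          Start_Position = pos$start,
          End_Position = pos$end,
          Variant_Classification = cls,
          Variant_Type = vt,
          Tumor_Sample_Barcode = tumor,
          stringsAsFactors = FALSE
        )
        truth[[length(truth) + 1L]] <- as.integer(in_rep)
      }
    }
    if (length(recs) == 0L) {
      maf <- data.frame(Hugo_Symbol = character(), Chromosome = character(),
                        Start_Position = integer(), End_Position = integer(),
                        Variant_Classification = character(),
                        Variant_Type = character(),
                        Tumor_Sample_Barcode = character(),
                        stringsAsFactors = FALSE)
      truth_v <- integer()
    } else {
      maf <- do.call(rbind, recs)
      truth_v <- unlist(truth)
      # shuffle record order so file order carries no class signal
      ord <- sample.int(nrow(maf))
      maf <- maf[ord, , drop = FALSE]
      truth_v <- truth_v[ord]
    }

    fnames <- feature_names()
    expected <- t(vapply(seq_len(nrow(tumors)), function(i) {
      prof <- if (tumors$profile[i] == "MSS") spec$mss else spec$msih
      expected_features(prof, tumors$capture_mb[i], spec$dispersion)
    }, stats::setNames(numeric(length(fnames)), fnames)))
    rownames(expected) <- tumors$tumor_id

    list(cohort = maf_cohort(maf), track = track, truth = truth_v,
         labels = tumors[, c("tumor_id", "stratum", "status", "profile",
                             "capture_mb")],
         expected = expected,
         capture_mb = stats::setNames(tumors$capture_mb, tumors$tumor_id))
  })
  res$seed <- seed
  if (nrow(res$cohort) == 0L) {
    warning("simulated cohort has no mutation records (all rates zero?)",
            call. = FALSE)
  }
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    write_maf(res$cohort, file.path(dir, "cohort.maf"))
    write_repeat_track(res$track, file.path(dir, "simpleRepeat.txt"))
    utils::write.csv(res$labels, file.path(dir, "labels.csv"), row.names = FALSE)
    utils::write.csv(data.frame(record = seq_along(res$truth),
                                In_repeats = res$truth),
                     file.path(dir, "truth.csv"), row.names = FALSE)
  }
  res
}

#' Construct label vectors with a requested confusion structure
#'
#' Builds reference and predicted label vectors realizing exactly the
#' requested counts: `n_pos` MSI-H and `n_neg` MSS reference tumors, of
#' which `fn` positives are predicted MSS and `fp` negatives are
#' predicted MSI-H.
#'
#' @param n_pos,n_neg reference class sizes.
#' @param fn,fp number of false negatives / false positives.
#' @return list with named character vectors `reference` and `predicted`.
#' @export
make_confusion_fixture <- function(n_pos, n_neg, fn = 0, fp = 0) {
  if (fn > n_pos || fp > n_neg || fn < 0 || fp < 0) {
    stop_config("need 0 <= fn <= n_pos and 0 <= fp <= n_neg")
  }
  ids <- sprintf("T%04d", seq_len(n_pos + n_neg))
  reference <- stats::setNames(c(rep("MSI-H", n_pos), rep("MSS", n_neg)), ids)
  predicted <- reference
  if (fn > 0) predicted[seq_len(fn)] <- "MSS"
  if (fp > 0) predicted[n_pos + seq_len(fp)] <- "MSI-H"
  list(reference = reference, predicted = predicted)
}
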