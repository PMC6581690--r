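#' Signal calling, normalization, quantitation and community statistics
#'
#' The analysis layer turns a raw probe-by-sample intensity table into:
#' positive calls (net intensity and signal-to-noise ratio against
#' per-subarray negative controls), PM/MM ratio calls, intensities
#' normalized across arrays via common oligonucleotide reference standards
#' (CORS), per-probe log-log quantitation fits over a dilution series, and
#' community-level statistics (richness, Shannon-Weaver diversity,
#' evenness, between-group relative differences with Mann-Whitney U
#' tests).
#'
#' @name signal
NULL

fga_error <- function(category, msg) {
  stop(structure(class = c(paste0("fga_", category, "_error"),
                           "error", "condition"),
                 list(message = msg, call = NULL)))
}

#' Call positive spots by signal-to-noise ratio
#'
#' Background is estimated per subarray within each array (sample x
#' replicate) from its negative-control spots: `snr = (raw - bg_mean) /
#' bg_sd`, `net = max(raw - bg_mean, 0)`. A spot is positive when its SNR
#' strictly exceeds the threshold. When the negative controls have zero
#' spread the SNR is undefined; such spots are flagged and called positive
#' when raw intensity exceeds the background mean.
#'
#' @param signals An `fga_signals` data frame.
#' @param snr_threshold Positive-call threshold (default 2, strict `>`).
#' @return An `fga_calls` data frame: input columns plus `net`, `snr`,
#'   `positive`, `sd_zero`.
#' @export
compute_calls <- function(signals, snr_threshold = 2) {
  df <- as.data.frame(signals)
  key <- interaction(df$sample, df$replicate, df$subarray, drop = TRUE)
  neg <- df$probe_class == "negative_control"
  if (!all(tapply(neg, key, sum) >= 2L)) {
    fga_error("contract",
              "every subarray needs >= 2 negative-control spots to estimate background")
  }
  bg_mean <- tapply(df$intensity[neg], key[neg], mean)
  bg_sd <- tapply(df$intensity[neg], key[neg], sd)
  m <- as.numeric(bg_mean[as.character(key)])
  s <- as.numeric(bg_sd[as.character(key)])
  df$net <- pmax(df$intensity - m, 0)
  df$sd_zero <- s == 0
  df$snr <- ifelse(df$sd_zero, NA_real_, (df$intensity - m) / s)
  df$positive <- ifelse(df$sd_zero, df$intensity > m,
                        df$snr > snr_threshold)
  if (any(df$sd_zero)) {
    warning("zero background spread in some subarrays: SNR undefined, calls fall back to raw > background mean",
            call. = FALSE)
  }
  class(df) <- c("fga_calls", "data.frame")
  df
}

#' PM/MM ratio calls
#'
#' For each perfect-match/mismatch pair the ratio of net intensities is
#' computed with both nets floored at a small positive epsilon (1
#' intensity unit) to avoid division by zero. A pair is called positive
#' when the PM spot is itself SNR-positive and the ratio strictly exceeds
#' the threshold: a large PM/MM ratio on a spot indistinguishable from
#' background is noise, not hybridization.
#'
#' @param calls An `fga_calls` table containing `pm_control` and
#'   `mm_control` rows with a shared pair structure (MM probe id = PM
#'   probe id + `"_mm"`, as produced by [generate_mm_probes()]).
#' @param ratio_threshold Positive-call ratio threshold (default 1.3,
#'   strict `>`).
#' @param eps Net-intensity floor for the ratio (default 1).
#' @return A data frame with one row per pair, sample and replicate:
#'   `pair_id`, `net_pm`, `net_mm`, `ratio`, `ratio_positive`.
#' @export
pm_mm_calls <- function(calls, ratio_threshold = 1.3, eps = 1) {
  df <- as.data.frame(calls)
  pm <- df[df$probe_class == "pm_control", , drop = FALSE]
  mm <- df[df$probe_class == "mm_control", , drop = FALSE]
  if (nrow(pm) == 0L || nrow(mm) == 0L) {
    fga_error("contract", "no PM/MM pairs present in the call table")
  }
  mm$pair_id <- sub("_mm$", "", mm$probe_id)
  key <- function(d, id) paste(id, d$sample, d$replicate, sep = "\r")
  idx <- match(key(pm, pm$probe_id), key(mm, mm$pair_id))
  if (anyNA(idx)) {
    fga_error("contract",
              sprintf("missing MM mate for PM probe(s): %s",
                      paste(unique(pm$probe_id[is.na(idx)]), collapse = ", ")))
  }
  out <- data.frame(pair_id = pm$probe_id,
                    sample = pm$sample, replicate = pm$replicate,
                    net_pm = pm$net, net_mm = mm$net[idx],
                    stringsAsFactors = FALSE)
  out$ratio <- pmax(out$net_pm, eps) / pmax(out$net_mm, eps)
  out$ratio_positive <- pm$positive & out$ratio > ratio_threshold
  out
}

#' Normalize intensities across arrays with CORS spikes
#'
#' Every array (sample x replicate) is scaled by
#' `mean(CORS across all arrays) / mean(CORS on this array)`, equalizing
#' CORS means across arrays while preserving within-array intensity
#' ratios exactly. Idempotent.
#'
#' @param signals An `fga_signals` data frame containing `cors_control`
#'   rows on every array.
#' @return The normalized `fga_signals`.
#' @export
normalize_cors <- function(signals) {
  df <- as.data.frame(signals)
  arr <- interaction(df$sample, df$replicate, drop = TRUE)
  cors <- df$probe_class == "cors_control"
  if (!all(tapply(cors, arr, any))) {
    fga_error("contract", "every array needs >= 1 CORS spot for normalization")
  }
  arr_mean <- tapply(df$intensity[cors], arr[cors], mean)
  global <- mean(df$intensity[cors])
  scale <- global / arr_mean[as.character(arr)]
  df$intensity <- as.numeric(df$intensity * scale)
  class(df) <- c("fga_signals", "data.frame")
  df
}

is_designed <- function(probe_class) {
  probe_class %in% c("sequence_specific", "group_specific", "pm_control",
                     "mm_control")
}

# mean net intensity and replicate-majority detection per probe x sample
probe_sample_summary <- function(calls, detection_min_reps = 2L) {
  df <- as.data.frame(calls)
  df <- df[is_designed(df$probe_class), , drop = FALSE]
  agg <- aggregate(cbind(net = df$net, positive = df$positive),
                   by = list(probe_id = df$probe_id, sample = df$sample),
                   FUN = function(x) c(v = mean(x), s = sum(x)))
  out <- data.frame(probe_id = agg$probe_id, sample = agg$sample,
                    mean_net = agg$net[, "v"],
                    n_positive = agg$positive[, "s"],
                    stringsAsFactors = FALSE)
  out$detected <- out$n_positive >= detection_min_reps
  out
}

#' Log-log quantitation fit over a dilution series
#'
#' Per probe, least-squares fit of `log10(mean net intensity across
#' replicates)` on `log10(mass)`, restricted to samples where the probe is
#' detected (positive in at least `detection_min_reps` replicates); probes
#' detected in fewer than 3 samples are excluded and counted. Net
#' intensities are floored at 1 unit before the log. A total-signal fit
#' sums net intensity over all positive spots per array.
#'
#' @param signals An `fga_signals` over the dilution series.
#' @param masses Named numeric vector: DNA mass (ng) per sample id.
#' @param snr_threshold Positive-call threshold (default 2).
#' @param detection_min_reps Replicate majority for detection (default 2).
#' @param saturation Optional intensity ceiling; probes with any point
#'   within 1% of it are flagged `saturated`.
#' @return An `fga_quantfit` list: `per_probe` (probe_id, slope,
#'   intercept, pearson_r, n_points, saturated), `total` (slope,
#'   intercept, pearson_r, n_points), `n_excluded`.
#' @export
fit_quantitation <- function(signals, masses, snr_threshold = 2,
                             detection_min_reps = 2L, saturation = NULL) {
  if (length(unique(masses)) < 3L) {
    fga_error("contract", "quantitation needs >= 3 distinct masses")
  }
  if (any(masses <= 0)) fga_error("contract", "masses must be > 0")
  calls <- compute_calls(signals, snr_threshold)
  ps <- probe_sample_summary(calls, detection_min_reps)
  ps$mass <- masses[ps$sample]
  if (anyNA(ps$mass)) fga_error("input", "sample without a mass in `masses`")
  fits <- lapply(split(ps, ps$probe_id), function(d) {
    pts <- d[d$detected, , drop = FALSE]
    sat <- if (is.null(saturation)) FALSE else any(pts$mean_net >= 0.99 * saturation)
    if (nrow(pts) < 3L) {
      return(data.frame(probe_id = d$probe_id[1], slope = NA_real_,
                        intercept = NA_real_, pearson_r = NA_real_,
                        n_points = nrow(pts), saturated = sat))
    }
    x <- log10(pts$mass)
    y <- log10(pmax(pts$mean_net, 1))
    fit <- lm(y ~ x)
    data.frame(probe_id = d$probe_id[1], slope = unname(coef(fit)[2]),
               intercept = unname(coef(fit)[1]), pearson_r = cor(x, y),
               n_points = nrow(pts), saturated = sat)
  })
  per_probe <- do.call(rbind, fits)
  rownames(per_probe) <- NULL
  n_excluded <- sum(per_probe$n_points < 3L)
  # total signal over detected spots, per sample (mean of replicate sums)
  df <- as.data.frame(calls)
  pos <- df[df$positive & is_designed(df$probe_class), , drop = FALSE]
  tot_rep <- aggregate(net ~ sample + replicate, data = pos, FUN = sum)
  tot <- aggregate(net ~ sample, data = tot_rep, FUN = mean)
  tot$mass <- masses[tot$sample]
  total <- list(slope = NA_real_, intercept = NA_real_,
                pearson_r = NA_real_, n_points = nrow(tot))
  if (nrow(tot) >= 3L) {
    x <- log10(tot$mass)
    y <- log10(pmax(tot$net, 1))
    fit <- lm(y ~ x)
    total <- list(slope = unname(coef(fit)[2]),
                  intercept = unname(coef(fit)[1]),
                  pearson_r = cor(x, y), n_points = nrow(tot))
  }
  structure(list(per_probe = per_probe, total = total,
                 n_excluded = n_excluded),
            class = "fga_quantfit")
}

#' Relative difference between two group means
#'
#' `(m1 - m2) / max(m1, m2)`: the difference of the mean abundances of two
#' groups divided by the higher mean. Lies in `[-1, 1]` for nonnegative
#' means (NA when both are 0) and flips sign under group exchange.
#'
#' @param m1,m2 Group mean abundances (>= 0).
#' @return The relative difference.
#' @export
relative_difference <- function(m1, m2) {
  hi <- pmax(m1, m2)
  ifelse(hi == 0, NA_real_, (m1 - m2) / hi)
}

#' Community statistics from a call table
#'
#' Per sample (over designed probes, treating each probe as a detected
#' gene): richness = number of detected genes (positive in at least
#' `detection_min_reps` replicates), Shannon-Weaver diversity `H' =
#' -sum(p_i log p_i)` over relative mean net intensities of detected
#' genes, evenness `H'/log(richness)`. Per gene and ordered group pair:
#' the relative difference of mean abundances (samples where the gene is
#' undetected contribute 0) and a two-sided Mann-Whitney U p-value
#' (significant at two-tailed p < 0.1, i.e. one-tailed p < 0.05; no
#' multiple-testing correction by default, with an optional
#' Benjamini-Hochberg column).
#'
#' @param calls An `fga_calls` table, ideally computed from a
#'   CORS-normalized matrix.
#' @param group_labels Named character vector: group per sample id.
#' @param detection_min_reps Replicate majority for detection (default 2).
#' @param p_adjust Add a Benjamini-Hochberg adjusted p column (default
#'   `FALSE`).
#' @return A list: `per_sample` (sample, group, richness, shannon,
#'   evenness), `per_gene` (gene, group1, group2, mean1, mean2,
#'   relative_difference, p_value, significant).
#' @export
community_stats <- function(calls, group_labels, detection_min_reps = 2L,
                            p_adjust = FALSE) {
  ps <- probe_sample_summary(calls, detection_min_reps)
  ps$abundance <- ifelse(ps$detected, ps$mean_net, 0)
  samples <- unique(ps$sample)
  if (!all(samples %in% names(group_labels))) {
    fga_error("input", "every sample needs a group label")
  }
  per_sample <- do.call(rbind, lapply(samples, function(s) {
    d <- ps[ps$sample == s & ps$detected, , drop = FALSE]
    rich <- nrow(d)
    if (rich == 0L) {
      h <- NA_real_
      ev <- NA_real_
    } else {
      p <- d$abundance / sum(d$abundance)
      p <- p[p > 0]
      h <- -sum(p * log(p))
      ev <- if (rich > 1L) h / log(rich) else NA_real_
    }
    data.frame(sample = s, group = unname(group_labels[s]),
               richness = rich, shannon = h, evenness = ev,
               stringsAsFactors = FALSE)
  }))
  groups <- unique(unname(group_labels[samples]))
  per_gene <- NULL
  if (length(groups) >= 2L) {
    pairs <- utils::combn(groups, 2)
    abmat <- tapply(ps$abundance, list(ps$probe_id, ps$sample), identity)
    rows <- list()
    for (pi in seq_len(ncol(pairs))) {
      g1 <- pairs[1, pi]; g2 <- pairs[2, pi]
      s1 <- samples[group_labels[samples] == g1]
      s2 <- samples[group_labels[samples] == g2]
      for (gene in rownames(abmat)) {
        x <- unlist(abmat[gene, s1]); y <- unlist(abmat[gene, s2])
        m1 <- mean(x); m2 <- mean(y)
        p <- if (length(x) >= 3L && length(y) >= 3L) {
          suppressWarnings(wilcox.test(x, y, alternative = "two.sided")$p.value)
        } else NA_real_
        rows[[length(rows) + 1L]] <- data.frame(
          gene = gene, group1 = g1, group2 = g2, mean1 = m1, mean2 = m2,
          relative_difference = relative_difference(m1, m2),
          p_value = p, significant = !is.na(p) & p < 0.1,
          stringsAsFactors = FALSE)
      }
    }
    per_gene <- do.call(rbind, rows)
    if (p_adjust && !is.null(per_gene)) {
      per_gene$p_bh <- stats::p.adjust(per_gene$p_value, method = "BH")
    }
  }
  list(per_sample = per_sample, per_gene = per_gene)
}
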