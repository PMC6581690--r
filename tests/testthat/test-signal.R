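# hand-built signal tables with known background: negatives at 90/110
# give mean 100 and sd = sqrt(200)
toy_signals <- function(probe_intensity, sample = "S1", replicate = 1L) {
  data.frame(probe_id = c("neg1", "neg2", "cors1", names(probe_intensity)),
             probe_class = c("negative_control", "negative_control",
                             "cors_control",
                             rep("sequence_specific", length(probe_intensity))),
             subarray = 1L, sample = sample, replicate = replicate,
             intensity = c(90, 110, 5000, unname(probe_intensity)),
             stringsAsFactors = FALSE)
}

test_that("SNR calling subtracts subarray background and uses a strict threshold", {
  s <- sd(c(90, 110))
  sig <- toy_signals(c(at_bg = 100, at_2sd = 100 + 2 * s,
                       above = 100 + 3 * s, below = 50))
  calls <- compute_calls(sig)
  expect_equal(calls$snr[calls$probe_id == "at_bg"], 0)
  expect_false(calls$positive[calls$probe_id == "at_bg"])
  # SNR exactly 2 is not positive (strict >)
  expect_equal(calls$snr[calls$probe_id == "at_2sd"], 2)
  expect_false(calls$positive[calls$probe_id == "at_2sd"])
  expect_true(calls$positive[calls$probe_id == "above"])
  # net intensity floors at zero
  expect_equal(calls$net[calls$probe_id == "below"], 0)
})

test_that("calling requires negative controls and flags zero background spread", {
  sig <- toy_signals(c(p = 500))
  sig <- sig[sig$probe_class != "negative_control", ]
  expect_error(compute_calls(sig), class = "fga_contract_error")

  flat <- toy_signals(c(p = 500))
  flat$intensity[flat$probe_class == "negative_control"] <- 100
  expect_warning(calls <- compute_calls(flat), "zero background")
  expect_true(calls$sd_zero[calls$probe_id == "p"])
  expect_true(calls$positive[calls$probe_id == "p"])
})

test_that("raising a raw intensity never turns a positive call negative", {
  set.seed(61)
  sig <- toy_signals(setNames(runif(10, 50, 300), paste0("p", 1:10)))
  before <- compute_calls(sig)
  bumped <- sig
  idx <- which(bumped$probe_class == "sequence_specific")
  bumped$intensity[idx] <- bumped$intensity[idx] + runif(length(idx), 0, 200)
  after <- compute_calls(bumped)
  was_pos <- before$positive[match(bumped$probe_id[idx], before$probe_id)]
  now_pos <- after$positive[match(bumped$probe_id[idx], after$probe_id)]
  expect_true(all(now_pos >= was_pos))
})

test_that("PM/MM ratios floor nets and require a positive PM spot", {
  s <- sd(c(90, 110))
  sig <- data.frame(probe_id = c("neg1", "neg2", "a", "a_mm", "b", "b_mm"),
                    probe_class = c("negative_control", "negative_control",
                                    "pm_control", "mm_control",
                                    "pm_control", "mm_control"),
                    subarray = 1L, sample = "S1", replicate = 1L,
                    intensity = c(90, 110, 600, 600, 2100, 100 + (2000 / 15)),
                    stringsAsFactors = FALSE)
  calls <- compute_calls(sig)
  ratios <- pm_mm_calls(calls)
  a <- ratios[ratios$pair_id == "a", ]
  expect_equal(a$ratio, 1)
  expect_false(a$ratio_positive)
  b <- ratios[ratios$pair_id == "b", ]
  expect_equal(b$ratio, 15)
  expect_true(b$ratio_positive)

  orphan <- calls[calls$probe_id != "a_mm", ]
  expect_error(pm_mm_calls(orphan), class = "fga_contract_error")
})

test_that("CORS normalization recovers a global scale and is idempotent", {
  arr <- fixture_array()
  pools <- list(target = arr$pools$targets, bg = arr$pools$nontargets)
  mix <- community_mix(data.frame(pool_id = c("target", "bg"),
                                  mass_ng = c(10, 990)))
  sig <- simulate_hybridization(arr$layout, mix, pools, hyb_model(seed = 8),
                                n_replicates = 1)
  # replicate 2 is the same array scanned at 3x the gain
  twin <- sig
  twin$replicate <- 2L
  twin$intensity <- twin$intensity * 3
  scaled <- rbind(sig, twin)
  class(scaled) <- c("fga_signals", "data.frame")
  norm <- normalize_cors(scaled)
  r2 <- norm$replicate == 2
  # per-probe agreement across the two arrays is restored
  v1 <- norm$intensity[!r2]
  v2 <- norm$intensity[r2]
  expect_equal(unname(v1 / v2), rep(1, length(v1)), tolerance = 1e-12)
  # within-array ratios are preserved exactly
  raw1 <- scaled$intensity[scaled$replicate == 2]
  expect_equal(norm$intensity[r2][1] / norm$intensity[r2][10],
               raw1[1] / raw1[10], tolerance = 1e-12)
  # idempotent
  norm2 <- normalize_cors(norm)
  expect_equal(norm2$intensity, norm$intensity, tolerance = 1e-12)

  no_cors <- sig[sig$probe_class != "cors_control", ]
  expect_error(normalize_cors(no_cors), class = "fga_contract_error")
})

test_that("noise-free dilution series recover slope 1 and r = 1 per probe", {
  arr <- fixture_array()
  ser <- simulate_dilution_series(arr$layout, arr$pools$targets,
                                  arr$pools$nontargets,
                                  masses_ng = c(1, 5, 10, 50, 100),
                                  model = hyb_model(noise_cv = 0,
                                                    background_sd = 0,
                                                    background_mean = 0,
                                                    seed = 4),
                                  n_replicates = 2)
  # zero-spread background: calls fall back to raw > background mean
  suppressWarnings(
    fit <- fit_quantitation(ser$signals,
                            setNames(ser$samples$mass_ng, ser$samples$sample),
                            detection_min_reps = 2L))
  ok <- fit$per_probe[fit$per_probe$n_points >= 3, ]
  expect_gt(nrow(ok), 0)
  expect_equal(ok$slope, rep(1, nrow(ok)), tolerance = 1e-6)
  expect_equal(ok$pearson_r, rep(1, nrow(ok)), tolerance = 1e-9)
  expect_equal(fit$total$pearson_r, 1, tolerance = 1e-3)
})

test_that("saturated dilution points flatten the fitted slope and are flagged", {
  arr <- fixture_array()
  model <- hyb_model(noise_cv = 0, background_sd = 0, background_mean = 0,
                     gain = 2000, seed = 4)
  ser <- simulate_dilution_series(arr$layout, arr$pools$targets,
                                  arr$pools$nontargets,
                                  masses_ng = c(1, 10, 100, 1000),
                                  total_ng = 2000, model = model,
                                  n_replicates = 2)
  suppressWarnings(
    fit <- fit_quantitation(ser$signals,
                            setNames(ser$samples$mass_ng, ser$samples$sample),
                            saturation = model$saturation))
  sat <- fit$per_probe[fit$per_probe$saturated & fit$per_probe$n_points >= 3, ]
  expect_gt(nrow(sat), 0)
  expect_true(all(sat$slope < 1))
})

test_that("shuffled mass labels destroy the per-probe correlation", {
  arr <- fixture_array()
  ser <- simulate_dilution_series(arr$layout, arr$pools$targets,
                                  arr$pools$nontargets,
                                  masses_ng = c(0.5, 1, 5, 10, 50, 100),
                                  model = hyb_model(seed = 4))
  masses <- setNames(ser$samples$mass_ng, ser$samples$sample)
  fit <- fit_quantitation(ser$signals, masses)
  set.seed(62)
  rs <- replicate(20, {
    shuf <- setNames(sample(ser$samples$mass_ng), ser$samples$sample)
    f <- fit_quantitation(ser$signals, shuf)
    mean(abs(f$per_probe$pearson_r), na.rm = TRUE)
  })
  expect_gt(mean(fit$per_probe$pearson_r, na.rm = TRUE), 0.9)
  expect_lt(mean(rs), 0.6)

  expect_error(fit_quantitation(ser$signals,
                                setNames(rep(1, 6), ser$samples$sample)),
               class = "fga_contract_error")
})

test_that("relative difference matches its closed form and is antisymmetric", {
  expect_equal(relative_difference(3, 4), -0.25)
  expect_equal(relative_difference(4, 3), 0.25)
  expect_equal(relative_difference(5, 5), 0)
  expect_true(is.na(relative_difference(0, 0)))
  set.seed(63)
  for (i in 1:50) {
    m <- runif(2, 0, 100)
    rd <- relative_difference(m[1], m[2])
    expect_gte(rd, -1)
    expect_lte(rd, 1)
    expect_equal(rd, -relative_difference(m[2], m[1]))
  }
})

test_that("uniform detected abundances give H' = ln(n) and evenness 1", {
  sig <- do.call(rbind, lapply(1:3, function(r) {
    toy_signals(setNames(rep(1100, 6), paste0("g", 1:6)), replicate = r)
  }))
  calls <- compute_calls(sig)
  st <- community_stats(calls, c(S1 = "L0"))
  expect_equal(st$per_sample$richness, 6)
  expect_equal(st$per_sample$shannon, log(6))
  expect_equal(st$per_sample$evenness, 1)
})

test_that("undetected samples report missing diversity", {
  sig <- do.call(rbind, lapply(1:3, function(r) {
    toy_signals(setNames(rep(100, 4), paste0("g", 1:4)), replicate = r)
  }))
  calls <- compute_calls(sig)
  st <- community_stats(calls, c(S1 = "L0"))
  expect_equal(st$per_sample$richness, 0)
  expect_true(is.na(st$per_sample$shannon))
  expect_true(is.na(st$per_sample$evenness))
})

test_that("group contrasts report relative differences and U-test significance", {
  set.seed(64)
  # 2 groups x 4 samples; gene g1 strongly higher in L0, g2 equal
  sig <- do.call(rbind, lapply(1:8, function(k) {
    grp_hi <- k <= 4
    do.call(rbind, lapply(1:3, function(r) {
      toy_signals(c(g1 = if (grp_hi) 2000 + 10 * k + r else 300 + 10 * k + r,
                    g2 = 1000 + 5 * (k %% 2) + r),
                  sample = paste0("S", k), replicate = r)
    }))
  }))
  calls <- compute_calls(sig)
  labels <- setNames(rep(c("L0", "L1"), each = 4), paste0("S", 1:8))
  st <- community_stats(calls, labels)
  g1 <- st$per_gene[st$per_gene$gene == "g1", ]
  expect_equal(g1$relative_difference,
               relative_difference(g1$mean1, g1$mean2))
  expect_gt(g1$relative_difference, 0.5)
  expect_true(g1$significant)
  g2 <- st$per_gene[st$per_gene$gene == "g2", ]
  expect_false(g2$significant)
})

test_that("the U test matches exhaustive enumeration for small groups", {
  set.seed(65)
  for (i in 1:20) {
    n1 <- sample(3:8, 1)
    n2 <- sample(3:8, 1)
    x <- runif(n1)
    y <- runif(n2) + runif(1, -0.5, 0.5)
    p_pkg <- suppressWarnings(wilcox.test(x, y)$p.value)
    expect_equal(p_pkg, oracle_u_test(x, y), tolerance = 1e-12)
  }
})
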