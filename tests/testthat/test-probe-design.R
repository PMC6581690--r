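no_filters <- list(gc_range = c(0, 100), max_homopolymer = 50L,
                   max_selfcomp = 51L)

test_that("candidate enumeration yields every window when unfiltered", {
  set.seed(41)
  target <- data.frame(seq_id = "t1", sequence = rand_dna(60))
  cand <- do.call(enumerate_candidates, c(list(target), no_filters))
  expect_equal(nrow(cand), 11)
  expect_equal(cand$start, 0:10)
  expect_equal(nchar(cand$sequence), rep(50, 11))
  expect_equal(cand$sequence[1], substr(target$sequence, 1, 50))
})

test_that("candidate filters drop homopolymers and extreme GC", {
  target <- data.frame(seq_id = "t1", sequence = strrep("A", 50))
  cand <- enumerate_candidates(target, gc_range = c(0, 100),
                               max_homopolymer = 10L)
  expect_equal(nrow(cand), 0)
  # same target passes only when the homopolymer cap is lifted
  cand2 <- do.call(enumerate_candidates, c(list(target), no_filters))
  expect_equal(nrow(cand2), 1)
  # default GC range rejects the all-A window even without the run cap
  cand3 <- enumerate_candidates(target, max_homopolymer = 50L)
  expect_equal(nrow(cand3), 0)
})

test_that("short targets produce an empty candidate set with a warning", {
  target <- data.frame(seq_id = "t1", sequence = rand_dna(40))
  expect_warning(cand <- enumerate_candidates(target), "shorter than probe length")
  expect_equal(nrow(cand), 0)
})

test_that("selection returns passing probes with reproducible reports", {
  pools <- fixture_pools()
  all_pool <- rbind(pools$targets, pools$nontargets)
  probes <- select_sequence_specific(pools$targets[1, , drop = FALSE],
                                     all_pool, k = 2, step = 2L)
  expect_gt(nrow(probes), 0)
  expect_true(all(probes$passed))
  expect_true(all(probes$probe_class == "sequence_specific"))
  # re-screening an emitted probe from scratch reproduces a passing report
  pool <- all_pool[all_pool$seq_id != probes$source_id[1] &
                     (is.na(all_pool$gene_family) |
                        all_pool$gene_family !=
                          pools$targets$gene_family[1]), ]
  rep <- screen_sequence_specific(probes$sequence[1], pool)
  expect_true(rep$passed)
  expect_equal(rep$vs_nontarget$max_identity_pct,
               probes$nt_max_identity_pct[1])
})

test_that("a target duplicated in the nontarget pool yields no probes", {
  pools <- fixture_pools()
  t1 <- pools$targets[1, , drop = FALSE]
  dup <- pools$nontargets
  dup <- rbind(dup, data.frame(seq_id = "dup", gene_family = NA,
                               taxon_label = "", sequence = t1$sequence))
  probes <- select_sequence_specific(t1, dup, k = 2, step = 2L)
  expect_equal(nrow(probes), 0)
})

test_that("equal-margin candidates break ties by the leftmost start", {
  set.seed(42)
  # a periodic target: windows whose starts agree mod 4 are identical, so
  # the winning window sequence recurs every 4 nt and the leftmost copy
  # must be the one selected
  target <- data.frame(seq_id = "t1", sequence = strrep("ACGT", 30))
  probes <- do.call(select_sequence_specific,
                    c(list(target, c(nt = rand_dna(200)), k = 1),
                      no_filters))
  expect_equal(nrow(probes), 1)
  expect_lte(probes$start[1], 3)
})

test_that("selection is invariant to nontarget pool ordering", {
  pools <- fixture_pools()
  all_pool <- rbind(pools$targets, pools$nontargets)
  shuffled <- all_pool[rev(seq_len(nrow(all_pool))), ]
  p1 <- select_sequence_specific(pools$targets[2, , drop = FALSE], all_pool,
                                 k = 2, step = 2L)
  p2 <- select_sequence_specific(pools$targets[2, , drop = FALSE], shuffled,
                                 k = 2, step = 2L)
  expect_equal(p1$probe_id, p2$probe_id)
  expect_equal(p1$nt_max_identity_pct, p2$nt_max_identity_pct)
})

test_that("group selection spans all members or returns nothing for divergent groups", {
  pools <- fixture_pools()
  all_pool <- rbind(pools$targets, pools$nontargets)
  g <- select_group_specific(pools$groups$fam02, pools$targets, all_pool,
                             k = 2, step = 2L)
  expect_gt(nrow(g), 0)
  expect_true(all(g$probe_class == "group_specific"))
  expect_true(all(g$source_id == "fam02"))
  expect_true(all(g$grp_min_identity_pct > 94))

  # members at ~80% mutual identity cannot satisfy the >94% criterion
  set.seed(43)
  anc <- rand_dna(150)
  div <- data.frame(seq_id = c("d1", "d2"), gene_family = "div",
                    taxon_label = "",
                    sequence = c(mutate_n(anc, 15), mutate_n(anc, 15)))
  grp <- structure(list(family_id = "div", member_ids = c("d1", "d2"),
                        description = ""), class = "fga_group")
  g2 <- select_group_specific(grp, div, pools$nontargets, k = 2, step = 2L)
  expect_equal(nrow(g2), 0)
})

test_that("legacy probes partition into valid and invalid with recycling", {
  pools <- fixture_pools()
  targets <- pools$targets
  # valid: an exact window of target 1; no-match: a random 50-mer;
  # nonspecific: an exact window of target 2 planted into a nontarget
  set.seed(44)
  valid_seq <- substr(targets$sequence[1], 31, 80)
  nomatch_seq <- rand_dna(50)
  nonspec_seq <- substr(targets$sequence[4], 31, 80)
  nt <- pools$nontargets
  nt$sequence[1] <- paste0(substr(nt$sequence[1], 1, 100), nonspec_seq)
  legacy <- data.frame(probe_id = c("L1", "L2", "L3"),
                       sequence = c(valid_seq, nomatch_seq, nonspec_seq),
                       stringsAsFactors = FALSE)
  legacy$declared_target_ids <- list(character(0), "fam03_m1", character(0))
  res <- validate_legacy_probes(legacy, targets, nt)
  expect_setequal(res$valid, "L1")
  expect_setequal(res$invalid, c("L2", "L3"))
  expect_setequal(union(res$valid, res$invalid), legacy$probe_id)
  expect_true("fam03_m1" %in% res$recycled_target_ids)
  expect_true("fam02_m1" %in% res$recycled_target_ids)
  expect_false("fam01_m1" %in% res$recycled_target_ids)
})

test_that("mismatch probes differ at exactly one position per segment", {
  set.seed(45)
  for (i in 1:50) {
    pm <- rand_dna(50)
    pair <- generate_mm_probe(pm, seed = i)
    diff <- which(strsplit(pair$pm, "")[[1]] != strsplit(pair$mm, "")[[1]])
    expect_length(diff, 5)
    expect_equal(findInterval(diff - 1, c(0, 10, 20, 30, 40)), 1:5)
    expect_equal(sort(pair$mismatch_positions), pair$mismatch_positions)
  }
  expect_error(generate_mm_probe(rand_dna(49), 1), "divisible by 5")
})

test_that("mismatch generation is deterministic under a fixed seed", {
  pm <- rand_dna(50)
  expect_identical(generate_mm_probe(pm, 7)$mm, generate_mm_probe(pm, 7)$mm)
  expect_false(identical(generate_mm_probe(pm, 7)$mm,
                         generate_mm_probe(pm, 8)$mm))
})

test_that("mismatch positions are uniform within each segment", {
  set.seed(46)
  pm <- rand_dna(50)
  n <- 3000
  pos <- t(vapply(seq_len(n), function(i) {
    generate_mm_probe(pm, seed = i)$mismatch_positions
  }, integer(5)))
  # each of the 10 positions in a segment should appear with freq 1/10
  for (s in 1:5) {
    freq <- tabulate(pos[, s] - (s - 1) * 10 + 1, nbins = 10) / n
    se <- sqrt(0.1 * 0.9 / n)
    expect_true(all(abs(freq - 0.1) < 4 * se))
  }
})

test_that("array layout spreads controls evenly and keeps PM/MM pairs together", {
  set.seed(47)
  probes <- data.frame(probe_id = paste0("p", 1:100),
                       probe_class = "sequence_specific",
                       source_id = "t", start = 0,
                       sequence = vapply(1:100, function(i) rand_dna(50),
                                         character(1)))
  lay <- build_array_layout(probes, c(negative_control = 8, cors_control = 8),
                            n_subarrays = 4, seed = 5)
  tab <- table(lay$probes$probe_class, lay$probes$subarray)
  expect_true(all(tab["negative_control", ] == 2))
  expect_true(all(tab["cors_control", ] == 2))
  expect_true(all(tab["sequence_specific", ] == 25))

  pm <- generate_mm_probes(probes[1:10, ], seed = 2)
  lay2 <- build_array_layout(pm, c(negative_control = 4, cors_control = 4),
                             n_subarrays = 2, seed = 5)
  sub <- split(lay2$probes$subarray, lay2$probes$pair_id)
  pairs <- sub[lengths(sub) == 2]
  expect_true(all(vapply(pairs, function(x) x[1] == x[2], logical(1))))

  expect_error(build_array_layout(probes, c(negative_control = 0,
                                            cors_control = 4),
                                  n_subarrays = 4),
               "negative_control")
})

test_that("layouts and probe tables round-trip through TSV", {
  arr <- fixture_array()
  p1 <- tempfile(fileext = ".tsv")
  write_layout(arr$layout, p1)
  back <- read_layout(p1)
  expect_equal(back$probes$probe_id, arr$layout$probes$probe_id)
  expect_equal(back$probes$subarray, arr$layout$probes$subarray)
  expect_equal(back$n_subarrays, arr$layout$n_subarrays)
})
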