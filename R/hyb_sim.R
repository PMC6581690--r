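#' Simulated community hybridizations
#'
#' The simulator emulates the evaluation experiments a functional gene
#' array undergoes: a community DNA mixture (target genomes spiked into a
#' divergent background) is hybridized to a laid-out array, producing a
#' probe-by-sample intensity table. The structural assumptions mirror what
#' those experiments rely on:
#'
#' * **log-linear dose response** — expected specific signal is
#'   proportional to target mass below scanner saturation;
#' * **GC-dependent efficiency** — high-GC probes bind more strongly than
#'   low-GC probes (A:T pairs are weaker than G:C), scaled as
#'   `(gc / 0.5) ^ gc_exponent`;
#' * **divergence-dependent cross-hybridization** — a probe picks up
#'   signal from an imperfect target with yield `crosshyb_decay ^ (100 -
#'   identity)`, zero below an identity floor;
#' * **two-component noise** — multiplicative lognormal spot noise plus
#'   additive Gaussian background, clipped at zero and saturating at the
#'   16-bit scanner ceiling.
#'
#' Negative controls receive background only; common oligonucleotide
#' reference standards (CORS) receive a fixed spike independent of the
#' mixture, which is what makes cross-array normalization possible.
#'
#' @name hyb_sim
NULL

#' Hybridization model parameters
#'
#' @param gain Intensity units per ng of perfectly matched target
#'   (default 100).
#' @param gc_exponent Exponent of the GC efficiency factor
#'   `(gc / 0.5) ^ gc_exponent` (default 4; a 37% vs 63% GC probe pair
#'   then differs roughly eightfold in sensitivity).
#' @param crosshyb_identity_floor Identity (percent) below which
#'   cross-hybridization yield is 0 (default 85).
#' @param crosshyb_decay Fractional yield per percentage point of identity
#'   below 100 (default `0.1^(1/10)`, so a 90%-identity duplex yields
#'   about 10% of the perfect-match signal).
#' @param background_mean,background_sd Additive background intensity
#'   (defaults 100 and 20).
#' @param noise_cv Coefficient of variation of the multiplicative
#'   lognormal spot noise (default 0.1; must be < 1).
#' @param saturation Intensity ceiling (default 65535, 16-bit scanner).
#' @param cors_intensity Expected CORS spike intensity (default 10000).
#' @param seed Base RNG seed.
#' @return An `fga_hyb_model` list.
#' @export
hyb_model <- function(gain = 100, gc_exponent = 4,
                      crosshyb_identity_floor = 85,
                      crosshyb_decay = 0.1^(1 / 10),
                      background_mean = 100, background_sd = 20,
                      noise_cv = 0.1, saturation = 65535,
                      cors_intensity = 10000, seed = 1L) {
  stopifnot(gain >= 0, crosshyb_identity_floor >= 0,
            crosshyb_decay >= 0, crosshyb_decay <= 1,
            background_mean >= 0, background_sd >= 0,
            noise_cv >= 0, noise_cv < 1, saturation > background_mean,
            cors_intensity >= 0)
  structure(list(gain = gain, gc_exponent = gc_exponent,
                 crosshyb_identity_floor = crosshyb_identity_floor,
                 crosshyb_decay = crosshyb_decay,
                 background_mean = background_mean,
                 background_sd = background_sd,
                 noise_cv = noise_cv, saturation = saturation,
                 cors_intensity = cors_intensity, seed = seed),
            class = "fga_hyb_model")
}

#' Community DNA mixture
#'
#' @param components Data frame with columns `pool_id` and `mass_ng`
#'   (>= 0): named sequence pools and the DNA mass each contributes. A
#'   component's mass is a genomic dose: every member sequence of the
#'   pool is present at the component's full mass, the way every gene of
#'   a genome scales with that genome's mass in a mixture.
#' @return An `fga_mix` list with `components` and `total_ng`.
#' @export
community_mix <- function(components) {
  stopifnot(is.data.frame(components),
            all(c("pool_id", "mass_ng") %in% names(components)),
            all(is.finite(components$mass_ng)), all(components$mass_ng >= 0))
  total <- sum(components$mass_ng)
  if (total <= 0) stop("total mixture mass must be > 0", call. = FALSE)
  structure(list(components = components, total_ng = total),
            class = "fga_mix")
}

crosshyb_yield <- function(identity_pct, model) {
  ifelse(identity_pct < model$crosshyb_identity_floor, 0,
         model$crosshyb_decay^(100 - identity_pct))
}

gc_factor <- function(sequence, model) {
  (gc_fraction(sequence) / 0.5)^model$gc_exponent
}

# Expected specific signal per probe (no noise, no background), given the
# identity of each probe to each pool member.
expected_signal <- function(layout, mix, pools, model,
                            identity_cache = NULL) {
  probes <- layout$probes
  if (is.null(identity_cache)) {
    identity_cache <- probe_pool_identities(layout, pools)
  }
  gcf <- vapply(probes$sequence, gc_factor, numeric(1), model = model,
                USE.NAMES = FALSE)
  expected <- numeric(nrow(probes))
  for (ci in seq_len(nrow(mix$components))) {
    pid <- mix$components$pool_id[ci]
    mass <- mix$components$mass_ng[ci]
    if (mass == 0) next
    if (!pid %in% names(identity_cache)) {
      stop(sprintf("mixture references unknown pool '%s'", pid), call. = FALSE)
    }
    idm <- identity_cache[[pid]] # probes x members identity matrix
    yield <- crosshyb_yield(idm, model)
    # mass is a genomic dose: every member gene of the component scales
    # with the component's full mass
    expected <- expected + model$gain * mass * rowSums(yield) * gcf
  }
  # control classes override the sequence-driven expectation
  expected[probes$probe_class == "negative_control"] <- 0
  expected[probes$probe_class == "cors_control"] <- model$cors_intensity
  expected
}

#' Precompute probe-to-pool identities
#'
#' Best ungapped identity of every probe in a layout to every member of
#' every pool; reused across the samples and replicates of a simulated
#' series.
#'
#' @param layout An `fga_layout`.
#' @param pools Named list of sequence pools (`fga_targets` or named
#'   character vectors).
#' @return Named list of probe-by-member identity matrices (percent).
#' @export
probe_pool_identities <- function(layout, pools) {
  probes <- layout$probes
  lapply(pools, function(pool) {
    pool <- as_pool(pool)
    m <- vapply(pool, function(subject) {
      vapply(probes$sequence, function(p) {
        .best_identity_cpp(p, subject)$identity_pct
      }, numeric(1), USE.NAMES = FALSE)
    }, numeric(nrow(probes)))
    matrix(m, nrow = nrow(probes), dimnames = list(probes$probe_id,
                                                   names(pool)))
  })
}

#' Simulate hybridization of a community mixture to an array
#'
#' Observed intensity per spot is
#' `min(saturation, expected * LN(1, noise_cv) + N(background_mean,
#' background_sd))`, clipped at zero, where `expected` follows the dose,
#' GC and cross-hybridization model described in [hyb_sim]. Deterministic
#' for a fixed model seed, sample id and replicate count.
#'
#' @param layout An `fga_layout`.
#' @param mix An `fga_mix`.
#' @param pools Named list of sequence pools referenced by the mixture.
#' @param model An `fga_hyb_model`.
#' @param n_replicates Number of replicate arrays (default 3).
#' @param sample_id Sample label (default `"S1"`).
#' @param identity_cache Optional result of [probe_pool_identities()].
#' @return An `fga_signals` data frame: `probe_id`, `probe_class`,
#'   `subarray`, `sample`, `replicate`, `intensity`.
#' @export
simulate_hybridization <- function(layout, mix, pools, model = hyb_model(),
                                   n_replicates = 3L, sample_id = "S1",
                                   identity_cache = NULL) {
  probes <- layout$probes
  expected <- expected_signal(layout, mix, pools, model, identity_cache)
  n <- nrow(probes)
  sdlog <- sqrt(log(1 + model$noise_cv^2))
  out <- lapply(seq_len(n_replicates), function(rep_i) {
    noise <- with_seed(stage_seed(model$seed,
                                  paste0("hyb:", sample_id, ":", rep_i)), {
      spot <- if (model$noise_cv > 0) {
        rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
      } else rep(1, n)
      bg <- rnorm(n, model$background_mean, model$background_sd)
      list(spot = spot, bg = bg)
    })
    intensity <- pmin(model$saturation,
                      pmax(0, expected * noise$spot + noise$bg))
    data.frame(probe_id = probes$probe_id,
               probe_class = probes$probe_class,
               subarray = probes$subarray,
               sample = sample_id,
               replicate = rep_i,
               intensity = intensity,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  attr(res, "provenance") <- list(model = model, sample = sample_id)
  class(res) <- c("fga_signals", "data.frame")
  res
}

#' Simulate a spike-in dilution series
#'
#' Emulates the sensitivity/quantitation protocol: increasing masses of a
#' target pool are mixed with a background pool so that the total DNA per
#' hybridization is constant, and each mixture is hybridized in replicate.
#'
#' @param layout An `fga_layout`.
#' @param target_pool,background_pool Sequence pools.
#' @param masses_ng Target masses (one sample per value).
#' @param total_ng Constant total DNA per hybridization (default 1000).
#' @param model An `fga_hyb_model`.
#' @param n_replicates Replicates per mass (default 3).
#' @return A list: `signals` (row-bound `fga_signals` across samples) and
#'   `samples` (sample sheet with `sample`, `mass_ng`).
#' @export
simulate_dilution_series <- function(layout, target_pool, background_pool,
                                     masses_ng = c(0.05, 0.1, 0.5, 1, 5, 10,
                                                   50, 100),
                                     total_ng = 1000,
                                     model = hyb_model(),
                                     n_replicates = 3L) {
  stopifnot(all(masses_ng > 0), all(masses_ng <= total_ng))
  pools <- list(target = target_pool, background = background_pool)
  cache <- probe_pool_identities(layout, pools)
  samples <- data.frame(sample = sprintf("M%g", masses_ng),
                        mass_ng = masses_ng, stringsAsFactors = FALSE)
  sig <- lapply(seq_len(nrow(samples)), function(i) {
    mix <- community_mix(data.frame(
      pool_id = c("target", "background"),
      mass_ng = c(samples$mass_ng[i], total_ng - samples$mass_ng[i])))
    simulate_hybridization(layout, mix, pools, model, n_replicates,
                           sample_id = samples$sample[i],
                           identity_cache = cache)
  })
  signals <- do.call(rbind, sig)
  class(signals) <- c("fga_signals", "data.frame")
  list(signals = signals, samples = samples)
}

mutate_sequence <- function(seq, n_subs) {
  if (n_subs == 0L) return(seq)
  chars <- strsplit(seq, "")[[1]]
  pos <- sample.int(length(chars), n_subs)
  for (p in pos) {
    chars[p] <- sample(setdiff(c("A", "C", "G", "T"), chars[p]), 1L)
  }
  paste(chars, collapse = "")
}

# Exact-composition random sequence: hits the GC target by construction
# rather than in expectation.
random_gc_dna <- function(length, gc) {
  n_gc <- round(length * gc)
  bases <- c(sample(c("G", "C"), n_gc, replace = TRUE),
             sample(c("A", "T"), length - n_gc, replace = TRUE))
  paste(sample(bases), collapse = "")
}

ungapped_identity <- function(a, b) {
  100 * mean(strsplit(a, "")[[1]] == strsplit(b, "")[[1]])
}

#' Generate synthetic target families and a nontarget pool
#'
#' Each gene family is grown by mutating a random ancestor: every member
#' carries substitutions at half the requested divergence, so pairwise
#' member identity lands near the requested value (realized identities are
#' asserted to be within 2 points). The nontarget pool is derived from the
#' same ancestors at the requested divergence, emulating distant homologs.
#' Family GC content cycles through `gc_targets` (realized pool GC within
#' 0.03 of the request).
#'
#' @param n_families Number of gene families.
#' @param members_per_family Members per family.
#' @param within_family_identity Requested pairwise member identity,
#'   percent (< 100 allowed down to 80).
#' @param nontarget_divergence Percent of positions mutated to derive each
#'   nontarget from a family ancestor (default 40).
#' @param gc_targets GC fractions cycled across families (default 0.5).
#' @param seq_length Sequence length in nt (default 300).
#' @param n_nontargets Size of the nontarget pool (default
#'   `2 * n_families`).
#' @param seed RNG seed; same seed, same pools.
#' @return A list: `targets` (`fga_targets` with `gene_family` set),
#'   `groups` (list of `fga_group`), `nontargets` (`fga_targets`).
#' @export
make_synthetic_pools <- function(n_families = 4L, members_per_family = 3L,
                                 within_family_identity = 97,
                                 nontarget_divergence = 40,
                                 gc_targets = 0.5,
                                 seq_length = 300L,
                                 n_nontargets = 2L * n_families,
                                 seed = 1L) {
  if (within_family_identity > 100 || within_family_identity < 80) {
    stop("within_family_identity must be in [80, 100]", call. = FALSE)
  }
  if (nontarget_divergence < 0 || nontarget_divergence > 100) {
    stop("nontarget_divergence must be in [0, 100]", call. = FALSE)
  }
  with_seed(stage_seed(seed, "synthetic_pools"), {
    per_member_subs <- round(seq_length * (100 - within_family_identity) / 200)
    fam_gc <- rep_len(gc_targets, n_families)
    ancestors <- vapply(fam_gc, random_gc_dna, character(1),
                        length = seq_length)
    members <- list()
    groups <- list()
    for (f in seq_len(n_families)) {
      fid <- sprintf("fam%02d", f)
      ids <- sprintf("%s_m%d", fid, seq_len(members_per_family))
      seqs <- vapply(ids, function(i) {
        mutate_sequence(ancestors[f], per_member_subs)
      }, character(1))
      # realized pairwise identity must sit near the request
      if (members_per_family >= 2L) {
        pairs <- utils::combn(members_per_family, 2)
        ids_pct <- apply(pairs, 2, function(p) {
          ungapped_identity(seqs[p[1]], seqs[p[2]])
        })
        if (any(abs(ids_pct - within_family_identity) > 2)) {
          stop("realized within-family identity drifted > 2 points from request",
               call. = FALSE)
        }
      }
      members[[fid]] <- data.frame(seq_id = ids, gene_family = fid,
                                   taxon_label = "", sequence = unname(seqs),
                                   stringsAsFactors = FALSE)
      groups[[fid]] <- structure(list(family_id = fid, member_ids = ids,
                                      description = "synthetic family"),
                                 class = "fga_group")
    }
    targets <- do.call(rbind, members)
    rownames(targets) <- NULL
    class(targets) <- c("fga_targets", "data.frame")
    gc_real <- vapply(split(vapply(targets$sequence, gc_fraction, numeric(1),
                                   USE.NAMES = FALSE),
                            rep(fam_gc, each = members_per_family)),
                      mean, numeric(1))
    if (any(abs(gc_real - as.numeric(names(gc_real))) > 0.03)) {
      stop("realized pool GC drifted > 0.03 from request", call. = FALSE)
    }
    nt_subs <- round(seq_length * nontarget_divergence / 100)
    nt_seqs <- vapply(seq_len(n_nontargets), function(i) {
      mutate_sequence(ancestors[((i - 1L) %% n_families) + 1L], nt_subs)
    }, character(1))
    nontargets <- data.frame(seq_id = sprintf("nt%03d", seq_len(n_nontargets)),
                             gene_family = NA_character_, taxon_label = "",
                             sequence = nt_seqs, stringsAsFactors = FALSE)
    class(nontargets) <- c("fga_targets", "data.frame")
    list(targets = targets, groups = groups, nontargets = nontargets)
  })
}

#' @rdname probe_io
#' @export
write_signals <- function(signals, path) {
  write.table(as.data.frame(signals), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' @rdname probe_io
#' @export
read_signals <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  class(df) <- c("fga_signals", "data.frame")
  df
}
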