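#' Probe design and array assembly
#'
#' Probes are 50-mers. For each target, every window of the target is a
#' candidate, filtered by simple synthesis-hygiene rules (GC range,
#' homopolymer cap, self-complementarity cap), screened by the specificity
#' module, and ranked by how far its worst-case statistics sit from the
#' criterion thresholds. Legacy probes from a previous array version are
#' revalidated against the current sequence universe, mismatch (MM)
#' controls are derived from perfect-match (PM) probes, and designed probes
#' plus controls are arranged into subarrays.
#'
#' @name probe_design
NULL

# Evaluate an expression under a fixed RNG seed without disturbing the
# caller's RNG state.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

# Derive a stage-specific substream seed (< 2^31) so adding stages never
# perturbs earlier stages' draws.
stage_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_len(nchar(stage)))
  as.integer((as.double(seed) * 48271 + h) %% 2147483647)
}

max_homopolymer_run <- function(seq) {
  r <- rle(strsplit(seq, "")[[1]])
  max(r$lengths)
}

empty_probes <- function() {
  data.frame(probe_id = character(), probe_class = character(),
             source_id = character(), start = integer(),
             sequence = character(), stringsAsFactors = FALSE)
}

#' Enumerate candidate probe windows from a target
#'
#' All windows of the stated length and step along the target, filtered by
#' GC content, maximum homopolymer run, and a self-complementarity cap (no
#' perfect reverse-complement self-match of `max_selfcomp` bases or more,
#' which would fold the probe into a hairpin or dimer on the array).
#'
#' @param target One row of an `fga_targets` data frame (or a list with
#'   `seq_id` and `sequence`).
#' @param length Probe length in bases (default 50).
#' @param gc_range Allowed GC percent interval, inclusive (default 30–70).
#' @param max_homopolymer Longest allowed single-base run (default 6).
#' @param max_selfcomp Self reverse-complement match cap, bases (default
#'   12, exclusive).
#' @param step Window step in bases (default 1).
#' @return A probe data frame (`probe_id`, `probe_class = "candidate"`,
#'   `source_id`, `start` 0-based, `sequence`); empty with a warning when
#'   the target is shorter than the probe length.
#' @export
enumerate_candidates <- function(target, length = 50L,
                                 gc_range = c(30, 70),
                                 max_homopolymer = 6L,
                                 max_selfcomp = 12L,
                                 step = 1L) {
  seq <- normalize_dna(target$sequence[[1]], target$seq_id[[1]])
  id <- target$seq_id[[1]]
  L <- nchar(seq)
  if (L < length) {
    warning(sprintf("target '%s' (%d nt) shorter than probe length %d: no candidates",
                    id, L, length), call. = FALSE)
    return(empty_probes())
  }
  starts <- seq.int(0L, L - length, by = step)
  windows <- substring(seq, starts + 1L, starts + length)
  gc <- vapply(windows, gc_fraction, numeric(1), USE.NAMES = FALSE) * 100
  keep <- gc >= gc_range[1] & gc <= gc_range[2]
  keep <- keep & vapply(windows, max_homopolymer_run, numeric(1),
                        USE.NAMES = FALSE) <= max_homopolymer
  selfcomp <- vapply(windows, function(w) {
    .longest_stretch_cpp(w, reverse_complement(w), FALSE)
  }, integer(1), USE.NAMES = FALSE)
  keep <- keep & selfcomp < max_selfcomp
  if (!any(keep)) return(empty_probes())
  data.frame(probe_id = paste0(id, "_p", starts[keep]),
             probe_class = "candidate",
             source_id = id,
             start = starts[keep],
             sequence = unname(windows[keep]),
             stringsAsFactors = FALSE)
}

# Nontarget pool for a target/family: drop the target itself and any
# sequence sharing its gene family.
nontarget_pool <- function(pool, exclude_ids = character(0),
                           exclude_family = NA_character_) {
  p <- pool
  if (inherits(p, "data.frame")) {
    keep <- !(p$seq_id %in% exclude_ids)
    if (!is.na(exclude_family) && "gene_family" %in% names(p)) {
      keep <- keep & (is.na(p$gene_family) | p$gene_family != exclude_family)
    }
    as_pool(p[keep, , drop = FALSE])
  } else {
    v <- as_pool(p)
    v[!(names(v) %in% exclude_ids)]
  }
}

# Specificity margin: minimum over criteria of the normalized distance from
# the threshold; larger = farther from all thresholds.
specificity_margin <- function(rep, th) {
  vn <- rep$vs_nontarget
  m <- c((th$max_identity_pct - vn$max_identity_pct) / th$max_identity_pct,
         (th$max_stretch_bp - vn$max_stretch_bp) / th$max_stretch_bp,
         (vn$min_dg_kcal - th$min_dg_kcal) / abs(th$min_dg_kcal))
  if (!is.null(rep$vs_group)) {
    vg <- rep$vs_group
    m <- c(m,
           (vg$min_identity_pct - th$group_min_identity_pct) / th$group_min_identity_pct,
           (vg$min_stretch_bp - th$group_min_stretch_bp) / th$group_min_stretch_bp,
           (th$group_max_dg_kcal - vg$max_dg_kcal) / abs(th$group_max_dg_kcal))
  }
  min(m)
}

attach_reports <- function(probes, reports) {
  if (nrow(probes) > 0L) {
    stats <- do.call(rbind, lapply(reports, report_row))
  } else {
    # keep the full column schema so empty results row-bind cleanly
    stats <- data.frame(nt_max_identity_pct = numeric(0),
                        nt_max_stretch_bp = numeric(0),
                        nt_min_dg_kcal = numeric(0),
                        nt_worst_identity_id = character(0),
                        nt_worst_stretch_id = character(0),
                        nt_worst_dg_id = character(0),
                        grp_min_identity_pct = numeric(0),
                        grp_min_stretch_bp = numeric(0),
                        grp_max_dg_kcal = numeric(0),
                        passed = logical(0),
                        failed_criteria = character(0),
                        stringsAsFactors = FALSE)
  }
  probes <- cbind(probes, stats[, setdiff(names(stats), "probe_id"),
                                drop = FALSE])
  attr(probes, "reports") <- reports
  class(probes) <- c("fga_probes", "data.frame")
  probes
}

select_screened <- function(cand, reports, th, k, class_label) {
  passed <- vapply(reports, `[[`, logical(1), "passed")
  if (!any(passed)) return(attach_reports(empty_probes(), list()))
  cand <- cand[passed, , drop = FALSE]
  reports <- reports[passed]
  margin <- vapply(reports, specificity_margin, numeric(1), th = th)
  ord <- order(-margin, cand$start)
  take <- ord[seq_len(min(k, length(ord)))]
  out <- cand[take, , drop = FALSE]
  out$probe_class <- class_label
  rownames(out) <- NULL
  attach_reports(out, reports[take])
}

#' Select sequence-specific probes for a target
#'
#' Enumerates candidate windows, screens each against the nontarget pool
#' (sequences sharing the target's gene family are excluded from the pool
#' automatically), and returns up to `k` passing probes ranked by
#' specificity margin — the minimum over criteria of the normalized
#' distance from the threshold — with ties broken by the leftmost start.
#'
#' @param target One row of an `fga_targets` data frame.
#' @param nontargets Candidate nontarget pool (`fga_targets` or named
#'   character vector); the target itself and same-family sequences are
#'   removed before screening.
#' @param thresholds An `fga_thresholds` object.
#' @param k Maximum probes returned per target (default 2).
#' @param ... Passed to [enumerate_candidates()].
#' @return An `fga_probes` data frame (`probe_class = "sequence_specific"`)
#'   with report statistics columns; full reports in `attr(, "reports")`.
#' @export
select_sequence_specific <- function(target, nontargets,
                                     thresholds = specificity_thresholds(),
                                     k = 2L, ...) {
  cand <- enumerate_candidates(target, length = thresholds$probe_length, ...)
  if (nrow(cand) == 0L) return(attach_reports(empty_probes(), list()))
  fam <- if ("gene_family" %in% names(target)) target$gene_family[[1]] else NA
  pool <- nontarget_pool(nontargets, exclude_ids = target$seq_id[[1]],
                         exclude_family = fam)
  reports <- lapply(seq_len(nrow(cand)), function(i) {
    screen_sequence_specific(cand$sequence[i], pool, thresholds,
                             probe_id = cand$probe_id[i])
  })
  select_screened(cand, reports, thresholds, k, "sequence_specific")
}

#' Select group-specific probes for a gene-family group
#'
#' Candidates are enumerated from a designated reference member (the
#' longest member by default, which maximizes the candidate space) and
#' screened with [screen_group_specific()] against all group members and
#' the nontarget pool (same-family sequences excluded). Ranking as in
#' [select_sequence_specific()], with the group-side margins included.
#'
#' @param group An `fga_group` (>= 2 members).
#' @param targets The `fga_targets` the group's member ids resolve to.
#' @param nontargets Candidate nontarget pool.
#' @param thresholds An `fga_thresholds` object.
#' @param k Maximum probes returned (default 2).
#' @param reference_id Member to enumerate candidates from; default the
#'   longest member.
#' @param ... Passed to [enumerate_candidates()].
#' @return An `fga_probes` data frame (`probe_class = "group_specific"`,
#'   `source_id` = the family id, `start` on the reference member).
#' @export
select_group_specific <- function(group, targets, nontargets,
                                  thresholds = specificity_thresholds(),
                                  k = 2L, reference_id = NULL, ...) {
  if (length(group$member_ids) < 2L) {
    stop("group-specific design requires >= 2 members", call. = FALSE)
  }
  members <- targets[match(group$member_ids, targets$seq_id), , drop = FALSE]
  if (anyNA(members$seq_id)) {
    stop("group member ids missing from target set", call. = FALSE)
  }
  if (is.null(reference_id)) {
    reference_id <- members$seq_id[which.max(nchar(members$sequence))]
  }
  ref <- members[members$seq_id == reference_id, , drop = FALSE]
  cand <- enumerate_candidates(ref, length = thresholds$probe_length, ...)
  if (nrow(cand) == 0L) return(attach_reports(empty_probes(), list()))
  pool <- nontarget_pool(nontargets, exclude_ids = members$seq_id,
                         exclude_family = group$family_id)
  member_pool <- as_pool(members)
  reports <- lapply(seq_len(nrow(cand)), function(i) {
    screen_group_specific(cand$sequence[i], member_pool, pool, thresholds,
                          probe_id = cand$probe_id[i])
  })
  out <- select_screened(cand, reports, thresholds, k, "group_specific")
  if (nrow(out) > 0L) {
    out$probe_id <- sub(paste0("^", reference_id), group$family_id, out$probe_id)
    out$source_id <- group$family_id
  }
  out
}

#' Revalidate legacy probes against a new sequence universe
#'
#' A legacy probe remains valid only if it still passes the sequence-
#' specificity screen against the new nontarget pool *and* is contained
#' verbatim in at least one new target (a continuous stretch equal to the
#' probe length). Targets covered by valid probes need no new design;
#' targets covered only by invalid probes are returned for re-design.
#' A probe's coverage is its exact-containment targets plus any declared
#' target ids present in the new target set.
#'
#' @param legacy Legacy probe data frame from [read_legacy_probes()].
#' @param targets New `fga_targets`.
#' @param nontargets Nontarget pool.
#' @param thresholds An `fga_thresholds` object.
#' @return A list with `valid` and `invalid` (character vectors of probe
#'   ids, a disjoint partition of the input), `covered_target_ids` (covered
#'   by valid probes) and `recycled_target_ids` (covered only by invalid
#'   probes).
#' @export
validate_legacy_probes <- function(legacy, targets, nontargets,
                                   thresholds = specificity_thresholds()) {
  pool <- as_pool(nontargets)
  n <- nrow(legacy)
  valid <- logical(n)
  coverage <- vector("list", n)
  for (i in seq_len(n)) {
    seq <- legacy$sequence[i]
    exact <- targets$seq_id[vapply(targets$sequence, function(t) {
      .longest_stretch_cpp(seq, t, TRUE) == nchar(seq)
    }, logical(1), USE.NAMES = FALSE)]
    rep <- screen_sequence_specific(seq, pool, thresholds,
                                    probe_id = legacy$probe_id[i])
    valid[i] <- rep$passed && length(exact) > 0L
    declared <- intersect(legacy$declared_target_ids[[i]], targets$seq_id)
    coverage[[i]] <- union(exact, declared)
  }
  covered_valid <- unique(unlist(coverage[valid]))
  covered_invalid <- unique(unlist(coverage[!valid]))
  list(valid = legacy$probe_id[valid],
       invalid = legacy$probe_id[!valid],
       covered_target_ids = covered_valid,
       recycled_target_ids = setdiff(covered_invalid, covered_valid))
}

#' Generate a mismatch (MM) control probe from a perfect-match probe
#'
#' The PM probe is divided into 5 equal segments and one mismatch is
#' introduced at a uniformly chosen position within each segment, the
#' replacement base drawn uniformly from the 3 alternatives — 5 mismatches
#' in total (10% of a 50-mer). Signal on the MM probe estimates
#' nonspecific cross-hybridization background for its PM partner.
#'
#' @param pm PM probe sequence (length divisible by 5) or a probe data
#'   frame row with a `sequence` column.
#' @param seed RNG seed; the same PM and seed always yield the same MM.
#' @return An `fga_mm_pair` list: `pm`, `mm` (sequences),
#'   `mismatch_positions` (0-based, one per segment, ascending), `seed`.
#' @export
generate_mm_probe <- function(pm, seed) {
  pm_seq <- if (is.character(pm)) pm else pm$sequence[[1]]
  pm_seq <- normalize_dna(pm_seq)
  L <- nchar(pm_seq)
  if (L %% 5L != 0L) {
    stop("PM probe length must be divisible by 5", call. = FALSE)
  }
  seg <- L %/% 5L
  bases <- c("A", "C", "G", "T")
  with_seed(seed, {
    pos <- vapply(0:4, function(s) s * seg + sample.int(seg, 1L), integer(1))
    mm <- strsplit(pm_seq, "")[[1]]
    for (p in pos) {
      mm[p] <- sample(setdiff(bases, mm[p]), 1L)
    }
    structure(list(pm = pm_seq, mm = paste(mm, collapse = ""),
                   mismatch_positions = pos - 1L, seed = seed),
              class = "fga_mm_pair")
  })
}

#' Generate MM partners for a set of PM probes
#'
#' @param probes An `fga_probes` data frame; each row becomes a PM control
#'   with an MM partner (`probe_id` suffixed `_mm`), using per-probe
#'   substream seeds derived from `seed`.
#' @param seed Base RNG seed.
#' @return A probe data frame with classes `pm_control` / `mm_control` and
#'   a `pair_id` column linking partners.
#' @export
generate_mm_probes <- function(probes, seed) {
  rows <- lapply(seq_len(nrow(probes)), function(i) {
    pair <- generate_mm_probe(probes$sequence[i],
                              stage_seed(seed, probes$probe_id[i]))
    data.frame(probe_id = c(probes$probe_id[i],
                            paste0(probes$probe_id[i], "_mm")),
               probe_class = c("pm_control", "mm_control"),
               source_id = probes$source_id[i],
               start = probes$start[i],
               sequence = c(pair$pm, pair$mm),
               pair_id = probes$probe_id[i],
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

control_classes <- c("positive_16S", "negative_control", "genome_control",
                     "cors_control")

random_dna <- function(n, length = 50L) {
  vapply(seq_len(n), function(i) {
    paste(sample(c("A", "C", "G", "T"), length, replace = TRUE),
          collapse = "")
  }, character(1))
}

#' Assemble an array layout with control classes
#'
#' Designed probes (and PM/MM pairs, kept together) are dealt round-robin
#' across subarrays; control probes of each class are distributed evenly so
#' that every subarray carries at least one negative control (for
#' background estimation) and one common oligonucleotide reference
#' standard (CORS, for cross-array normalization). Control sequences are
#' drawn randomly under `seed` unless supplied.
#'
#' @param designed Probe data frame (designed probes and/or PM/MM pairs; a
#'   `pair_id` column keeps partners in one subarray).
#' @param controls Named counts per control class; must include
#'   `negative_control >= n_subarrays` and `cors_control >= n_subarrays`.
#' @param n_subarrays Number of subarrays.
#' @param seed RNG seed for control sequence generation.
#' @return An `fga_layout` list: `probes` (data frame with a `subarray`
#'   column, 1-based), `n_subarrays`.
#' @export
build_array_layout <- function(designed,
                               controls = c(negative_control = 4L,
                                            cors_control = 4L),
                               n_subarrays = 4L, seed = 1L) {
  bad <- setdiff(names(controls), control_classes)
  if (length(bad) > 0L) {
    stop(sprintf("unknown control class(es): %s", paste(bad, collapse = ", ")),
         call. = FALSE)
  }
  for (cls in c("negative_control", "cors_control")) {
    if (is.na(controls[cls]) || controls[cls] < n_subarrays) {
      stop(sprintf("need at least one %s per subarray (%d requested, %d subarrays)",
                   cls, if (is.na(controls[cls])) 0L else controls[cls],
                   n_subarrays), call. = FALSE)
    }
  }
  designed <- as.data.frame(designed)
  if (nrow(designed) > 0L && !"pair_id" %in% names(designed)) {
    designed$pair_id <- designed$probe_id
  }
  ctrl <- with_seed(stage_seed(seed, "layout_controls"), {
    do.call(rbind, lapply(names(controls), function(cls) {
      n <- controls[[cls]]
      if (n == 0L) return(NULL)
      data.frame(probe_id = sprintf("%s_%03d", cls, seq_len(n)),
                 probe_class = cls, source_id = NA_character_,
                 start = NA_integer_, sequence = random_dna(n),
                 pair_id = sprintf("%s_%03d", cls, seq_len(n)),
                 stringsAsFactors = FALSE)
    }))
  })
  keep_cols <- c("probe_id", "probe_class", "source_id", "start",
                 "sequence", "pair_id")
  all_probes <- rbind(
    if (nrow(designed) > 0L) designed[, keep_cols, drop = FALSE] else NULL,
    ctrl)
  if (anyDuplicated(all_probes$probe_id)) {
    stop("probe ids must be unique in a layout", call. = FALSE)
  }
  # round-robin per class over pair units, so controls spread evenly and
  # PM/MM partners share a subarray
  all_probes$subarray <- NA_integer_
  for (cls in unique(all_probes$probe_class)) {
    idx <- which(all_probes$probe_class %in% cls)
    units <- unique(all_probes$pair_id[idx])
    assign_unit <- setNames(((seq_along(units) - 1L) %% n_subarrays) + 1L,
                            units)
    all_probes$subarray[idx] <- assign_unit[all_probes$pair_id[idx]]
  }
  # MM partners follow their PM's subarray
  pm_sub <- all_probes$subarray[all_probes$probe_class == "pm_control"]
  names(pm_sub) <- all_probes$pair_id[all_probes$probe_class == "pm_control"]
  mm_idx <- all_probes$probe_class == "mm_control"
  all_probes$subarray[mm_idx] <- pm_sub[all_probes$pair_id[mm_idx]]
  rownames(all_probes) <- NULL
  structure(list(probes = all_probes, n_subarrays = n_subarrays),
            class = "fga_layout")
}

#' Write / read probe tables and layouts as TSV
#'
#' @param probes,layout Objects to serialize.
#' @param path File path.
#' @return The path (writers, invisibly) or the reconstructed object
#'   (readers).
#' @name probe_io
NULL

#' @rdname probe_io
#' @export
write_probes <- function(probes, path) {
  write.table(as.data.frame(probes), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' @rdname probe_io
#' @export
read_probes <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  class(df) <- c("fga_probes", "data.frame")
  df
}

#' @rdname probe_io
#' @export
write_layout <- function(layout, path) {
  write.table(layout$probes, path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' @rdname probe_io
#' @export
read_layout <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  structure(list(probes = df, n_subarrays = max(df$subarray)),
            class = "fga_layout")
}
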