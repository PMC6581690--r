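#' Probe specificity screening
#'
#' A candidate probe is accepted only if it is unlikely to cross-hybridize
#' with any nontarget sequence. Three statistics are computed between a
#' probe and every sequence in a pool, over both subject strands:
#'
#' * **identity** — percent identity of the best ungapped register of the
#'   probe along the subject (matches / probe length);
#' * **stretch** — length of the longest exact common substring;
#' * **free energy** — nearest-neighbor duplex \eqn{\Delta G} evaluated at
#'   the best-identity register ([alignment_delta_g()]).
#'
#' A sequence-specific probe passes when, against its closest nontarget,
#' identity < 90%, stretch < 20 bp and \eqn{\Delta G > -35} kcal/mol (all
#' strict, configurable). A group-specific probe must in addition bind
#' every member of its target group tightly: identity > 94%, stretch >
#' 35 bp and \eqn{\Delta G < -60} kcal/mol against the weakest member.
#'
#' @name specificity
NULL

#' Specificity screening thresholds
#'
#' @param max_identity_pct Nontarget side: maximum tolerated identity,
#'   percent (pass requires identity strictly below). Default 90, the
#'   conservative end of the established 90–92% range.
#' @param max_stretch_bp Nontarget side: maximum tolerated continuous
#'   stretch, bases (strictly below). Default 20.
#' @param min_dg_kcal Nontarget side: free-energy floor, kcal/mol (pass
#'   requires the most negative nontarget \eqn{\Delta G} strictly above).
#'   Default −35.
#' @param group_min_identity_pct Target-group side: minimum identity to the
#'   weakest group member, percent (strictly above). Default 94.
#' @param group_min_stretch_bp Target-group side: minimum stretch to the
#'   weakest member, bases (strictly above). Default 35.
#' @param group_max_dg_kcal Target-group side: free-energy ceiling for the
#'   weakest member, kcal/mol (strictly below). Default −60.
#' @param probe_length Probe length the stretch thresholds are checked
#'   against. Default 50.
#' @return An `fga_thresholds` list.
#' @export
specificity_thresholds <- function(max_identity_pct = 90,
                                   max_stretch_bp = 20,
                                   min_dg_kcal = -35,
                                   group_min_identity_pct = 94,
                                   group_min_stretch_bp = 35,
                                   group_max_dg_kcal = -60,
                                   probe_length = 50) {
  stopifnot(max_identity_pct > 0, max_identity_pct <= 100,
            group_min_identity_pct > 0, group_min_identity_pct <= 100,
            max_stretch_bp <= probe_length,
            group_min_stretch_bp <= probe_length)
  if (max_identity_pct >= group_min_identity_pct) {
    stop("nontarget identity threshold must be below the group identity threshold",
         call. = FALSE)
  }
  structure(list(max_identity_pct = max_identity_pct,
                 max_stretch_bp = max_stretch_bp,
                 min_dg_kcal = min_dg_kcal,
                 group_min_identity_pct = group_min_identity_pct,
                 group_min_stretch_bp = group_min_stretch_bp,
                 group_max_dg_kcal = group_max_dg_kcal,
                 probe_length = probe_length),
            class = "fga_thresholds")
}

# Coerce a pool argument (fga_targets, named character vector, or data frame
# with seq_id/sequence) to a named character vector of sequences.
as_pool <- function(x) {
  if (inherits(x, "fga_targets") ||
      (is.data.frame(x) && all(c("seq_id", "sequence") %in% names(x)))) {
    return(setNames(x$sequence, x$seq_id))
  }
  if (is.character(x)) {
    if (is.null(names(x)) && length(x) > 0L) {
      names(x) <- paste0("seq", seq_along(x))
    }
    return(x)
  }
  stop("cannot interpret sequence pool", call. = FALSE)
}

#' Best ungapped identity of a probe to a subject
#'
#' Scans every ungapped register of the probe along both strands of the
#' subject (registers may overhang the subject ends; overhanging positions
#' count as mismatches, so identity is always matches / probe length).
#' Ties are broken in favor of the forward strand, then the smaller offset.
#'
#' @param probe,subject DNA strings.
#' @return A list with `identity_pct`, `subject_offset` (0-based start of
#'   the best register, in coordinates of the reported strand; negative
#'   when the probe overhangs the 5' end), and `strand` (`"+"` or `"-"`).
#' @export
best_identity <- function(probe, subject) {
  .best_identity_cpp(normalize_dna(probe), normalize_dna(subject))
}

#' Longest continuous sequence stretch between probe and subject
#'
#' Length of the longest exact (ungapped, mismatch-free) common substring
#' between the probe and either strand of the subject. Long stretches are
#' a primary driver of cross-hybridization.
#'
#' @param probe,subject DNA strings.
#' @param both_strands Also scan the subject's reverse complement
#'   (default `TRUE`).
#' @return Stretch length in bases (0 if no base is shared).
#' @export
longest_stretch <- function(probe, subject, both_strands = TRUE) {
  .longest_stretch_cpp(normalize_dna(probe), normalize_dna(subject),
                       both_strands)
}

# All three statistics of one probe against one subject; dG at the
# best-identity register.
probe_vs_subject <- function(probe, subject, params) {
  bi <- .best_identity_cpp(probe, subject)
  win <- .aligned_window_cpp(probe, subject, bi$subject_offset, bi$strand)
  list(identity_pct = bi$identity_pct,
       stretch_bp = .longest_stretch_cpp(probe, subject, TRUE),
       dg_kcal = alignment_delta_g(probe, win, params))
}

pool_statistics <- function(probe, pool, params) {
  ids <- names(pool)
  stats <- lapply(pool, probe_vs_subject, probe = probe, params = params)
  data.frame(subject_id = ids,
             identity_pct = vapply(stats, `[[`, numeric(1), "identity_pct"),
             stretch_bp = vapply(stats, `[[`, numeric(1), "stretch_bp"),
             dg_kcal = vapply(stats, `[[`, numeric(1), "dg_kcal"),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Screen a probe for sequence specificity against a nontarget pool
#'
#' The probe passes when its worst-case statistics against the pool satisfy
#' all three nontarget criteria with strict inequalities: maximum identity
#' below the identity threshold, maximum stretch below the stretch
#' threshold, and minimum (most negative) \eqn{\Delta G} above the
#' free-energy threshold. All three statistics are computed even after a
#' criterion fails, so the report is always complete. The pool must not
#' contain the probe's own target(s).
#'
#' @param probe Probe sequence (typically a 50-mer).
#' @param nontargets Nontarget pool: an `fga_targets` data frame or a named
#'   character vector of sequences.
#' @param thresholds An `fga_thresholds` object.
#' @param probe_id Id recorded in the report.
#' @param params Nearest-neighbor table.
#' @return An `fga_specificity_report` with elements `probe_id`,
#'   `vs_nontarget` (worst-case statistics and the subject ids attaining
#'   them), `passed`, `failed_criteria`.
#' @export
screen_sequence_specific <- function(probe, nontargets,
                                     thresholds = specificity_thresholds(),
                                     probe_id = "probe",
                                     params = default_nn_params()) {
  probe <- normalize_dna(probe, probe_id)
  pool <- as_pool(nontargets)
  if (length(pool) == 0L) {
    warning("empty nontarget pool: specificity passes vacuously", call. = FALSE)
    rep <- list(probe_id = probe_id,
                vs_nontarget = list(max_identity_pct = 0, max_stretch_bp = 0,
                                    min_dg_kcal = 0,
                                    worst_identity_id = NA_character_,
                                    worst_stretch_id = NA_character_,
                                    worst_dg_id = NA_character_),
                vs_group = NULL, passed = TRUE, failed_criteria = character(0))
    class(rep) <- "fga_specificity_report"
    return(rep)
  }
  st <- pool_statistics(probe, pool, params)
  vs <- list(max_identity_pct = max(st$identity_pct),
             max_stretch_bp = max(st$stretch_bp),
             min_dg_kcal = min(st$dg_kcal),
             worst_identity_id = st$subject_id[which.max(st$identity_pct)],
             worst_stretch_id = st$subject_id[which.max(st$stretch_bp)],
             worst_dg_id = st$subject_id[which.min(st$dg_kcal)])
  failed <- character(0)
  if (!(vs$max_identity_pct < thresholds$max_identity_pct)) failed <- c(failed, "identity")
  if (!(vs$max_stretch_bp < thresholds$max_stretch_bp)) failed <- c(failed, "stretch")
  if (!(vs$min_dg_kcal > thresholds$min_dg_kcal)) failed <- c(failed, "free_energy")
  rep <- list(probe_id = probe_id, vs_nontarget = vs, vs_group = NULL,
              passed = length(failed) == 0L, failed_criteria = failed)
  class(rep) <- "fga_specificity_report"
  rep
}

#' Screen a group-specific probe
#'
#' A group-specific probe must both remain specific against the nontarget
#' pool (the three nontarget criteria of [screen_sequence_specific()]) and
#' hybridize tightly with every member of its target group: minimum
#' identity across members above the group identity threshold, minimum
#' stretch above the group stretch threshold, and maximum (least negative)
#' \eqn{\Delta G} below the group free-energy ceiling — all strict.
#'
#' @param probe Probe sequence.
#' @param group_members Pool of the group's member sequences (>= 2).
#' @param nontargets Nontarget pool.
#' @param thresholds An `fga_thresholds` object.
#' @param probe_id Id recorded in the report.
#' @param params Nearest-neighbor table.
#' @return An `fga_specificity_report` with `vs_group` filled in.
#' @export
screen_group_specific <- function(probe, group_members, nontargets,
                                  thresholds = specificity_thresholds(),
                                  probe_id = "probe",
                                  params = default_nn_params()) {
  members <- as_pool(group_members)
  if (length(members) < 2L) {
    stop("group-specific screening requires a group with >= 2 members",
         call. = FALSE)
  }
  rep <- screen_sequence_specific(probe, nontargets, thresholds, probe_id,
                                  params)
  probe <- normalize_dna(probe, probe_id)
  st <- pool_statistics(probe, members, params)
  vg <- list(min_identity_pct = min(st$identity_pct),
             min_stretch_bp = min(st$stretch_bp),
             max_dg_kcal = max(st$dg_kcal),
             worst_identity_id = st$subject_id[which.min(st$identity_pct)],
             worst_stretch_id = st$subject_id[which.min(st$stretch_bp)],
             worst_dg_id = st$subject_id[which.max(st$dg_kcal)])
  failed <- rep$failed_criteria
  if (!(vg$min_identity_pct > thresholds$group_min_identity_pct)) {
    failed <- c(failed, "group_identity")
  }
  if (!(vg$min_stretch_bp > thresholds$group_min_stretch_bp)) {
    failed <- c(failed, "group_stretch")
  }
  if (!(vg$max_dg_kcal < thresholds$group_max_dg_kcal)) {
    failed <- c(failed, "group_free_energy")
  }
  rep$vs_group <- vg
  rep$failed_criteria <- failed
  rep$passed <- length(failed) == 0L
  rep
}

# Flatten a report into a one-row data frame for the TSV writer.
report_row <- function(rep) {
  vn <- rep$vs_nontarget
  vg <- rep$vs_group
  data.frame(probe_id = rep$probe_id,
             nt_max_identity_pct = vn$max_identity_pct,
             nt_max_stretch_bp = vn$max_stretch_bp,
             nt_min_dg_kcal = vn$min_dg_kcal,
             nt_worst_identity_id = vn$worst_identity_id,
             nt_worst_stretch_id = vn$worst_stretch_id,
             nt_worst_dg_id = vn$worst_dg_id,
             grp_min_identity_pct = if (is.null(vg)) NA_real_ else vg$min_identity_pct,
             grp_min_stretch_bp = if (is.null(vg)) NA_real_ else vg$min_stretch_bp,
             grp_max_dg_kcal = if (is.null(vg)) NA_real_ else vg$max_dg_kcal,
             passed = rep$passed,
             failed_criteria = paste(rep$failed_criteria, collapse = ","),
             stringsAsFactors = FALSE)
}

#' Write specificity reports to TSV
#'
#' One row per probe: the six worst-case statistics, the subject ids that
#' attain them, the pass flag and any failed criteria.
#'
#' @param reports A list of `fga_specificity_report` objects.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_specificity_reports <- function(reports, path) {
  df <- do.call(rbind, lapply(reports, report_row))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
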