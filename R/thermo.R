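#' Nearest-neighbor duplex free energy
#'
#' The stability of a probe-target DNA duplex is scored with the standard
#' nearest-neighbor model: the free energy of a perfectly matched duplex is
#' the sum of dinucleotide stacking terms plus duplex initiation penalties
#' for the two terminal base pairs. More negative values mean a more stable
#' duplex. The packaged parameter set is the unified oligonucleotide
#' \eqn{\Delta G^\circ_{37}} table (kcal/mol); alternative tables can be
#' loaded from TSV with [load_nn_params()]. No salt or temperature
#' correction is applied: screening thresholds are compared on the
#' \eqn{\Delta G^\circ_{37}} scale directly.
#'
#' @name thermo
NULL

#' Load a nearest-neighbor parameter table
#'
#' @param path TSV with columns `key` and `dg37`: the 16 dinucleotide stacks
#'   (5'->3' top strand of a matched duplex) and the `init_AT` / `init_GC`
#'   terminal initiation terms, in kcal/mol. Defaults to the packaged
#'   unified table.
#' @param name Label recorded in provenance.
#' @return An `fga_nn_params` object with fields `stack_dg` (named numeric,
#'   16 entries), `init_dg` (named numeric: `AT`, `GC`) and `name`.
#' @export
load_nn_params <- function(path = NULL, name = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "nn_unified_dg37.tsv", package = "fgarray")
    if (is.null(name)) name <- "unified_dg37"
  }
  if (is.null(name)) name <- basename(path)
  df <- read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  vals <- setNames(df$dg37, df$key)
  stacks <- as.vector(outer(c("A", "C", "G", "T"), c("A", "C", "G", "T"),
                            paste0))
  missing <- setdiff(c(stacks, "init_AT", "init_GC"), names(vals))
  if (length(missing) > 0L) {
    stop(sprintf("nearest-neighbor table missing entries: %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  stack_dg <- vals[stacks]
  init_dg <- c(AT = unname(vals["init_AT"]), GC = unname(vals["init_GC"]))
  if (!all(is.finite(c(stack_dg, init_dg)))) {
    stop("nearest-neighbor parameters must be finite", call. = FALSE)
  }
  if (any(stack_dg >= 0) || any(init_dg <= 0)) {
    stop("stacking terms must be negative and initiation terms positive",
         call. = FALSE)
  }
  # matched-duplex symmetry: dG(XY) == dG(revcomp(XY))
  rc <- vapply(stacks, reverse_complement, character(1))
  if (any(abs(stack_dg - stack_dg[rc]) > 1e-9)) {
    stop("nearest-neighbor table violates complementary-stack symmetry",
         call. = FALSE)
  }
  structure(list(stack_dg = stack_dg, init_dg = init_dg, name = name),
            class = "fga_nn_params")
}

# cached default parameter set
.fga_env <- new.env(parent = emptyenv())

default_nn_params <- function() {
  if (is.null(.fga_env$nn)) .fga_env$nn <- load_nn_params()
  .fga_env$nn
}

init_term <- function(base, params) {
  ifelse(base %in% c("A", "T"), params$init_dg[["AT"]], params$init_dg[["GC"]])
}

# stack sum over a contiguous matched run (no initiation terms)
stack_sum <- function(seq, params) {
  n <- nchar(seq)
  if (n < 2L) return(0)
  st <- substring(seq, 1:(n - 1L), 2:n)
  sum(params$stack_dg[st])
}

#' Free energy of a perfectly matched duplex
#'
#' \eqn{\Delta G = } initiation terms for both terminal base pairs plus the
#' sum over the \eqn{L-1} dinucleotide stacks.
#'
#' @param sequence Top strand of the duplex (5'->3'), length >= 2.
#' @param params An `fga_nn_params` table (default: packaged unified table).
#' @return Free energy in kcal/mol.
#' @examples
#' duplex_delta_g("AT") # 2 * 1.03 - 0.88 = 1.18
#' @export
duplex_delta_g <- function(sequence, params = default_nn_params()) {
  s <- normalize_dna(sequence)
  n <- nchar(s)
  if (n < 2L) stop("duplex free energy requires length >= 2", call. = FALSE)
  init_term(substr(s, 1L, 1L), params) + init_term(substr(s, n, n), params) +
    stack_sum(s, params)
}

#' Free energy of an ungapped probe/window alignment
#'
#' Scores the heteroduplex formed when a probe sits on a subject window in
#' a fixed ungapped register (the best-identity register found by the
#' specificity screen). Only stacks whose two flanking base pairs are both
#' Watson-Crick matches contribute; a mismatch contributes nothing and
#' breaks the stacking run. Initiation terms are added once — for the 5'
#' end of the first matched run of length >= 2 and the 3' end of the last —
#' so a fully matched window reduces to [duplex_delta_g()]. If no matched
#' run of length >= 2 exists, no stable duplex forms and the result is 0.
#'
#' @param probe Probe sequence.
#' @param window Subject window of the same length, in probe orientation
#'   (positions a match when characters are equal). `-` marks positions
#'   with no aligned subject base (register overhang); they count as
#'   mismatches.
#' @param params An `fga_nn_params` table.
#' @return Free energy in kcal/mol (0 when no duplex forms).
#' @export
alignment_delta_g <- function(probe, window, params = default_nn_params()) {
  if (nchar(probe) != nchar(window)) {
    stop("probe and window must have equal length", call. = FALSE)
  }
  p <- strsplit(normalize_dna(probe), "")[[1]]
  w <- strsplit(toupper(window), "")[[1]]
  match <- p == w & w %in% c("A", "C", "G", "T")
  r <- rle(match)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & r$lengths >= 2L
  if (!any(keep)) return(0)
  runs <- mapply(function(s, e) paste(p[s:e], collapse = ""),
                 starts[keep], ends[keep])
  dg <- sum(vapply(runs, stack_sum, numeric(1), params = params))
  first <- substr(runs[1L], 1L, 1L)
  last_run <- runs[length(runs)]
  last <- substr(last_run, nchar(last_run), nchar(last_run))
  dg + init_term(first, params) + init_term(last, params)
}
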