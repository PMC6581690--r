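#' Target sequences, gene-family groups and legacy probes
#'
#' Functional gene array design starts from a set of target coding sequences
#' (or gene fragments) assigned to gene families. `read_fasta()` ingests
#' targets from FASTA, `read_group_manifest()` attaches the family/group
#' structure, and `read_legacy_probes()` ingests a probe set carried over
#' from a previous array generation for revalidation.
#'
#' Sequences are normalized on ingest: uppercased, RNA `U` converted to `T`.
#' Ambiguity codes (N, R, Y, ...) are rejected rather than expanded because
#' probe selection and duplex free-energy computation require concrete bases;
#' pre-filtering ambiguous records is the caller's job.
#'
#' @name sequences
NULL

# Strict {A,C,G,T} validation; reports the record and 1-based offending
# position. Returns the normalized sequence.
normalize_dna <- function(seq, id = "<sequence>") {
  s <- chartr("u", "t", seq)
  s <- toupper(chartr("U", "T", s))
  bad <- regexpr("[^ACGT]", s)
  if (bad > 0L) {
    ch <- substr(s, bad, bad)
    if (ch %in% c("N", "R", "Y", "S", "W", "K", "M", "B", "D", "H", "V")) {
      stop(sprintf("ambiguous base '%s' in record '%s' at position %d",
                   ch, id, bad), call. = FALSE)
    }
    stop(sprintf("invalid character '%s' in record '%s' at position %d (alphabet is A/C/G/T)",
                 ch, id, bad), call. = FALSE)
  }
  s
}

new_targets <- function(seq_id, gene_family, taxon_label, sequence) {
  df <- data.frame(seq_id = as.character(seq_id),
                   gene_family = as.character(gene_family),
                   taxon_label = as.character(taxon_label),
                   sequence = as.character(sequence),
                   stringsAsFactors = FALSE)
  dup <- duplicated(df$seq_id)
  if (any(dup)) {
    stop(sprintf("duplicate seq_id in target set: %s",
                 paste(unique(df$seq_id[dup]), collapse = ", ")), call. = FALSE)
  }
  class(df) <- c("fga_targets", "data.frame")
  df
}

#' Read target sequences from FASTA
#'
#' Headers are parsed as `>seq_id description`, where the first
#' whitespace-delimited token is the record id. `key=value` pairs in the
#' description are recognized; a `family=` key sets the record's gene
#' family (it may instead be supplied through [read_group_manifest()], which
#' wins on conflict). Wrapped and unwrapped sequence lines are both accepted.
#'
#' @param path Path to a FASTA file of DNA sequences.
#' @return An `fga_targets` data frame with columns `seq_id`, `gene_family`
#'   (`NA` when no `family=` key is present), `taxon_label` (from a
#'   `taxon=` key, empty otherwise) and `sequence`, in file order.
#' @examples
#' fa <- tempfile(fileext = ".fasta")
#' writeLines(c(">g1 family=dsrA", "ACGTACGTACGT"), fa)
#' read_fasta(fa)
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) {
    stop(sprintf("empty FASTA file: %s", path), call. = FALSE)
  }
  headers <- names(set)
  ids <- vapply(strsplit(headers, "\\s+"), `[`, character(1), 1L)
  kv <- function(header, key) {
    m <- regmatches(header, regexec(paste0("\\b", key, "=(\\S+)"), header))[[1]]
    if (length(m) == 2L) m[2] else NA_character_
  }
  fam <- vapply(headers, kv, character(1), key = "family", USE.NAMES = FALSE)
  tax <- vapply(headers, kv, character(1), key = "taxon", USE.NAMES = FALSE)
  tax[is.na(tax)] <- ""
  seqs <- as.character(set)
  seqs <- mapply(normalize_dna, seqs, ids, USE.NAMES = FALSE)
  new_targets(ids, fam, tax, seqs)
}

#' Write target sequences to FASTA
#'
#' Inverse of [read_fasta()]: ids and sequences round-trip exactly; a
#' non-missing gene family is written back as a `family=` key.
#'
#' @param targets An `fga_targets` data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(targets, path) {
  hdr <- targets$seq_id
  has_fam <- !is.na(targets$gene_family)
  hdr[has_fam] <- paste0(hdr[has_fam], " family=", targets$gene_family[has_fam])
  set <- Biostrings::DNAStringSet(targets$sequence)
  names(set) <- hdr
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Read a gene-family group manifest
#'
#' The manifest is a two-column TSV (`family_id`, `seq_id`; header row
#' required, `#` comments allowed) assigning target sequences to gene
#' families. Member order within a family is first-seen order. A family
#' assignment in the manifest overrides a `family=` key parsed from the
#' FASTA description (with a warning on conflict).
#'
#' @param path Path to the manifest TSV.
#' @param targets The `fga_targets` the manifest refers to.
#' @return A named list of `fga_group` objects (fields `family_id`,
#'   `member_ids`, `description`), keyed by family id. An empty file yields
#'   an empty list.
#' @export
read_group_manifest <- function(path, targets) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  df <- tryCatch(
    read.delim(path, comment.char = "#", stringsAsFactors = FALSE,
               colClasses = "character"),
    error = function(e) data.frame(family_id = character(), seq_id = character())
  )
  if (nrow(df) == 0L) return(structure(list(), names = character()))
  if (!all(c("family_id", "seq_id") %in% names(df))) {
    stop("group manifest must have columns 'family_id' and 'seq_id'", call. = FALSE)
  }
  unknown <- setdiff(df$seq_id, targets$seq_id)
  if (length(unknown) > 0L) {
    stop(sprintf("group manifest references unknown seq_id(s): %s",
                 paste(unknown, collapse = ", ")), call. = FALSE)
  }
  dup <- duplicated(df[, c("family_id", "seq_id")])
  if (any(dup)) {
    warning(sprintf("%d duplicate (family_id, seq_id) manifest row(s) dropped",
                    sum(dup)), call. = FALSE)
    df <- df[!dup, , drop = FALSE]
  }
  fam_from_fasta <- targets$gene_family[match(df$seq_id, targets$seq_id)]
  conflict <- !is.na(fam_from_fasta) & fam_from_fasta != df$family_id
  if (any(conflict)) {
    warning(sprintf("manifest overrides FASTA family= for: %s",
                    paste(df$seq_id[conflict], collapse = ", ")), call. = FALSE)
  }
  groups <- lapply(split(df$seq_id, df$family_id)[unique(df$family_id)],
                   function(ids) ids)
  out <- lapply(names(groups), function(fid) {
    structure(list(family_id = fid, member_ids = groups[[fid]],
                   description = ""),
              class = "fga_group")
  })
  names(out) <- names(groups)
  out
}

#' Apply a group manifest to target metadata
#'
#' Fills the `gene_family` column of a target set from a manifest read with
#' [read_group_manifest()]; manifest assignments win over FASTA-derived ones.
#'
#' @param targets An `fga_targets` data frame.
#' @param groups A list of `fga_group` objects.
#' @return The updated `fga_targets`.
#' @export
assign_families <- function(targets, groups) {
  for (g in groups) {
    targets$gene_family[match(g$member_ids, targets$seq_id)] <- g$family_id
  }
  targets
}

#' Read legacy probes
#'
#' Legacy probes are 50-mers carried over from a previous array version,
#' read either from FASTA (declared target ids from a `targets=` key,
#' comma-separated) or from a TSV with columns `probe_id`, `sequence` and
#' optional `declared_target_ids` (comma-separated).
#'
#' @param path Path to a FASTA or TSV file.
#' @return A data frame with columns `probe_id`, `sequence`,
#'   `declared_target_ids` (list column of character vectors).
#' @export
read_legacy_probes <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  first <- readLines(path, n = 1L)
  if (length(first) > 0L && startsWith(first, ">")) {
    set <- Biostrings::readBStringSet(path)
    headers <- names(set)
    ids <- vapply(strsplit(headers, "\\s+"), `[`, character(1), 1L)
    tgt <- vapply(headers, function(h) {
      m <- regmatches(h, regexec("\\btargets=(\\S+)", h))[[1]]
      if (length(m) == 2L) m[2] else ""
    }, character(1), USE.NAMES = FALSE)
    seqs <- mapply(normalize_dna, as.character(set), ids, USE.NAMES = FALSE)
  } else {
    df <- read.delim(path, comment.char = "#", stringsAsFactors = FALSE,
                     colClasses = "character")
    ids <- df$probe_id
    seqs <- mapply(normalize_dna, df$sequence, ids, USE.NAMES = FALSE)
    tgt <- if ("declared_target_ids" %in% names(df)) df$declared_target_ids else ""
  }
  out <- data.frame(probe_id = ids, sequence = seqs, stringsAsFactors = FALSE)
  out$declared_target_ids <- lapply(tgt, function(x) {
    if (is.na(x) || !nzchar(x)) character(0) else strsplit(x, ",")[[1]]
  })
  out
}

#' Reverse complement of a DNA string
#'
#' Strict-alphabet reverse complement; an involution that preserves length
#' and GC count.
#'
#' @param sequence DNA string over `{A,C,G,T}` (lowercase accepted).
#' @return The reverse complement, uppercase.
#' @examples
#' reverse_complement("GATTACA") # "TGTAATC"
#' @export
reverse_complement <- function(sequence) {
  s <- normalize_dna(sequence)
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}

#' GC fraction of a DNA string
#'
#' @param sequence DNA string over `{A,C,G,T}`.
#' @return Fraction of G and C bases, in `[0, 1]`.
#' @export
gc_fraction <- function(sequence) {
  s <- normalize_dna(sequence)
  mean(strsplit(s, "")[[1]] %in% c("G", "C"))
}
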