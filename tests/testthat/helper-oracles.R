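# Brute-force reference implementations, kept independent of the package's
# kernels: direct enumeration in plain R, validated only by inspection.

rand_dna <- function(len) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}

oracle_revcomp <- function(s) {
  map <- c(A = "T", C = "G", G = "C", T = "A")
  paste(rev(map[strsplit(s, "")[[1]]]), collapse = "")
}

# best ungapped register over both strands, overhang allowed, matches / L
oracle_best_identity <- function(probe, subject) {
  p <- utf8ToInt(probe)
  L <- length(p)
  best <- -1L
  best_strand <- "+"
  best_off <- 0L
  for (strand in c("+", "-")) {
    s <- utf8ToInt(if (strand == "+") subject else oracle_revcomp(subject))
    M <- length(s)
    for (off in (-(L - 1L)):(M - 1L)) {
      i <- max(1L, 1L - off):min(L, M - off)
      m <- sum(p[i] == s[off + i])
      if (m > best) {
        best <- m
        best_strand <- strand
        best_off <- off
      }
    }
  }
  list(identity_pct = 100 * best / L, strand = best_strand,
       subject_offset = best_off)
}

lcs_len_oracle <- function(a, b) {
  A <- utf8ToInt(a)
  B <- utf8ToInt(b)
  prev <- integer(length(B))
  best <- 0L
  for (i in seq_along(A)) {
    cur <- integer(length(B))
    eq <- which(B == A[i])
    cur[eq] <- c(0L, prev)[eq] + 1L
    best <- max(best, cur)
    prev <- cur
  }
  best
}

oracle_longest_stretch <- function(probe, subject) {
  max(lcs_len_oracle(probe, subject),
      lcs_len_oracle(probe, oracle_revcomp(subject)))
}

# nearest-neighbor table read directly from the packaged TSV
nn_table <- local({
  tab <- NULL
  function() {
    if (is.null(tab)) {
      df <- read.delim(system.file("extdata", "nn_unified_dg37.tsv",
                                   package = "fgarray"),
                       comment.char = "#")
      tab <<- as.list(setNames(df$dg37, df$key))
    }
    tab
  }
})

oracle_duplex_dg <- function(seq) {
  tab <- nn_table()
  b <- strsplit(seq, "")[[1]]
  init <- function(x) if (x %in% c("A", "T")) tab$init_AT else tab$init_GC
  dg <- init(b[1]) + init(b[length(b)])
  for (k in seq_len(length(b) - 1L)) {
    dg <- dg + tab[[paste0(b[k], b[k + 1L])]]
  }
  dg
}

# explicit matched-run enumeration for the heteroduplex free energy
oracle_alignment_dg <- function(probe, window) {
  tab <- nn_table()
  p <- strsplit(probe, "")[[1]]
  w <- strsplit(window, "")[[1]]
  runs <- list()
  cur <- integer(0)
  for (i in seq_along(p)) {
    if (w[i] %in% c("A", "C", "G", "T") && p[i] == w[i]) {
      cur <- c(cur, i)
    } else {
      if (length(cur) > 0L) runs[[length(runs) + 1L]] <- cur
      cur <- integer(0)
    }
  }
  if (length(cur) > 0L) runs[[length(runs) + 1L]] <- cur
  runs <- Filter(function(r) length(r) >= 2L, runs)
  if (length(runs) == 0L) return(0)
  dg <- 0
  for (r in runs) {
    for (k in seq_len(length(r) - 1L)) {
      dg <- dg + tab[[paste0(p[r[k]], p[r[k + 1L]])]]
    }
  }
  init <- function(x) if (x %in% c("A", "T")) tab$init_AT else tab$init_GC
  first <- p[runs[[1L]][1L]]
  last <- p[rev(runs[[length(runs)]])[1L]]
  dg + init(first) + init(last)
}

# exact two-sided Mann-Whitney p by enumerating every group assignment
oracle_u_test <- function(x, y) {
  n1 <- length(x)
  pooled <- c(x, y)
  r <- rank(pooled)
  u_of <- function(idx) sum(r[idx]) - n1 * (n1 + 1) / 2
  u_obs <- u_of(seq_len(n1))
  combos <- utils::combn(length(pooled), n1)
  dist <- apply(combos, 2, function(idx) {
    sum(rank(pooled)[idx]) - n1 * (n1 + 1) / 2
  })
  min(1, 2 * min(mean(dist <= u_obs), mean(dist >= u_obs)))
}

# substitute exactly n positions of a sequence with different bases
mutate_n <- function(seq, n, positions = NULL) {
  b <- strsplit(seq, "")[[1]]
  if (is.null(positions)) positions <- sample(length(b), n)
  for (p in positions) {
    b[p] <- sample(setdiff(c("A", "C", "G", "T"), b[p]), 1)
  }
  paste(b, collapse = "")
}
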