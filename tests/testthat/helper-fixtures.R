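# Shared synthetic fixtures, built once per test run.

fixture_pools <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- make_synthetic_pools(n_families = 3, members_per_family = 3,
                                     within_family_identity = 97,
                                     nontarget_divergence = 40,
                                     gc_targets = c(0.4, 0.5, 0.6),
                                     seq_length = 150L, seed = 2024L)
    }
    cache
  }
})

# a small laid-out array with designed probes and PM/MM pairs
fixture_array <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      pools <- fixture_pools()
      all_pool <- rbind(pools$targets, pools$nontargets)
      probes <- do.call(rbind, lapply(seq_len(nrow(pools$targets)), function(i) {
        as.data.frame(select_sequence_specific(
          pools$targets[i, , drop = FALSE], all_pool, k = 2, step = 2L))
      }))
      cols <- c("probe_id", "probe_class", "source_id", "start", "sequence")
      seq_probes <- probes[!duplicated(probes$source_id), cols]
      pm_parents <- probes[duplicated(probes$source_id), cols]
      pm <- generate_mm_probes(pm_parents, seed = 11L)
      designed <- rbind(cbind(seq_probes, pair_id = seq_probes$probe_id),
                        pm[, c(cols, "pair_id")])
      layout <- build_array_layout(designed,
                                   c(negative_control = 24L, cors_control = 8L),
                                   n_subarrays = 4L, seed = 3L)
      cache <<- list(pools = pools, layout = layout)
    }
    cache
  }
})

write_tmp_fasta <- function(records) {
  path <- tempfile(fileext = ".fasta")
  writeLines(unlist(lapply(names(records), function(id) {
    c(paste0(">", id), records[[id]])
  })), path)
  path
}
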