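# Independent brute-force oracle and random fixture plans shared by tests.

# Per-element membership scan, written deliberately as plain loops so it
# shares no code path with compute_partition().
brute_partition <- function(collection) {
  n <- collection$n
  cs <- collection$case_sensitive
  all_members <- character(0)
  for (s in collection$sets) all_members <- c(all_members, s)
  keys <- if (cs) all_members else tolower(all_members)
  union_members <- all_members[!duplicated(keys)]
  regions <- vector("list", 2^n - 1)
  names(regions) <- as.character(seq_len(2^n - 1))
  for (i in seq_along(regions)) regions[[i]] <- character(0)
  for (lab in union_members) {
    mask <- 0
    for (i in seq_len(n)) {
      set_keys <- if (cs) collection$sets[[i]] else tolower(collection$sets[[i]])
      lk <- if (cs) lab else tolower(lab)
      if (lk %in% set_keys) mask <- mask + 2^(i - 1)
    }
    regions[[as.character(mask)]] <- c(regions[[as.character(mask)]], lab)
  }
  lapply(regions, sort)
}

random_plan <- function(n, seed, lambda = 2, max_total = Inf) {
  set.seed(seed)
  m <- 2L^n - 1L
  counts <- stats::rpois(m, lambda)
  if (sum(counts) == 0L) counts[sample.int(m, 1L)] <- 1L
  while (sum(counts) > max_total) counts <- pmax(counts - 1L, 0L)
  if (sum(counts) == 0L) counts[1L] <- 1L
  partition_plan(n, counts, seed = seed)
}

disjoint_pair <- function() {
  compute_partition(set_collection(list(A = "a", B = "b")))
}

identical_six <- function(members = sprintf("G%02d", 1:8)) {
  sets <- stats::setNames(rep(list(members), 6), paste0("D", 1:6))
  compute_partition(set_collection(sets))
}
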