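# Synthetic set collections with a fully known ground-truth partition, so the
# whole pipeline is testable without any external data. Labels are sequential
# "P<seed>_000001"-style strings: comparison is string-exact, so mimicking
# real gene symbols would add nothing.

#' Plan a synthetic partition
#'
#' A plan fixes, per region signature, how many fresh labels the generator
#' should place there. Generation is deterministic given the seed, and
#' distinct seeds yield label-disjoint collections (the seed is part of every
#' label).
#'
#' @param n set count, 2--6.
#' @param counts non-negative integer vector of length `2^n - 1`, indexed by
#'   region mask (element 1 = mask 1); at least one count must be positive.
#'   A named vector (names = mask values) in any order is also accepted.
#' @param label_prefix prefix for generated labels.
#' @param seed integer seed.
#' @param set_names optional set names (default `Set1 .. SetN`).
#' @return an object of class `partition_plan`.
#' @export
partition_plan <- function(n, counts, label_prefix = "P", seed = 1L,
                           set_names = NULL) {
  n <- check_n(n)
  m <- 2L^n - 1L
  if (!is.null(names(counts))) {
    full <- integer(m)
    full[as.integer(names(counts))] <- as.integer(counts)
    counts <- full
  }
  counts <- as.integer(counts)
  if (length(counts) != m || any(is.na(counts)) || any(counts < 0L)) {
    stop(sprintf("`counts` must be %d non-negative integers (one per mask)", m))
  }
  if (sum(counts) == 0L) stop("a plan needs at least one positive count")
  if (is.null(set_names)) set_names <- paste0("Set", seq_len(n))
  stopifnot(length(set_names) == n, !anyDuplicated(set_names))
  structure(list(n = n, counts = counts, label_prefix = label_prefix,
                 seed = as.integer(seed), set_names = set_names),
            class = "partition_plan")
}

#' Generate a collection (and its exact expected partition) from a plan
#'
#' Synthesizes `counts[sig]` fresh labels per signature and places each label
#' into exactly the sets named by its signature's bits. The returned ground
#' truth is what [compute_partition()] must recover.
#'
#' @param plan a [partition_plan()].
#' @return list with `collection` (a [set_collection()]), `partition` (the
#'   ground-truth `venn_partition`), and `plan`.
#' @export
generate_collection <- function(plan) {
  stopifnot(inherits(plan, "partition_plan"))
  n <- plan$n
  m <- 2L^n - 1L
  total <- sum(plan$counts)
  labels <- sprintf("%s%d_%06d", plan$label_prefix, plan$seed, seq_len(total))
  sig_of <- rep.int(seq_len(m), plan$counts)
  sets <- stats::setNames(vector("list", n), plan$set_names)
  for (i in seq_len(n)) {
    sets[[i]] <- labels[bitwAnd(sig_of, 2L^(i - 1L)) > 0L]
  }
  # shuffle member order within sets so downstream code cannot rely on it
  set.seed(plan$seed)
  sets <- lapply(sets, function(s) s[sample.int(length(s))])
  collection <- set_collection(sets)
  regions <- lapply(seq_len(m), function(s) sort(labels[sig_of == s]))
  names(regions) <- as.character(seq_len(m))
  truth <- structure(list(collection = collection, n = n, regions = regions),
                     class = "venn_partition")
  list(collection = collection, partition = truth, plan = plan)
}

dose_presets <- list(
  control         = list(red = c(15, 15, 21, 22, 27), stim_pct = 36),
  cmp             = list(red = c(7, 11, 24, 27, 31),  stim_pct = 38),
  control_go      = list(red = c(24, 19, 19, 19, 19), stim_pct = 37),
  cmp_go          = list(red = c(4, 14, 14, 14, 54),  stim_pct = 36),
  control_pathway = list(red = c(11, 30, 20, 20, 19), stim_pct = 37),
  cmp_pathway     = list(red = c(0, 15, 25, 35, 25),  stim_pct = 36)
)

#' Six-set dose-response plan with prescribed dose-unique proportions
#'
#' Builds a reference-plus-five-doses plan whose RED (dose-unique) region
#' counts follow the requested per-dose shares, and whose GREY mass (members
#' shared between doses but absent from the reference) is sized so that the
#' stimulated-unique fraction of [dose_unique_profile()] comes out at
#' `stimulated_unique_pct`. Remaining mass (BLUE/BLACK/GREEN) is spread
#' uniformly and does not enter either percentage.
#'
#' Presets encode the published dose-response applications: `"control"` and
#' `"cmp"` are the phosphoprotein profiles of the untreated and
#' chronic-minimal-peroxide cellular contexts (dose-unique shares
#' 15/15/21/22/27% vs 7/11/24/27/31% across 10 nM .. 100 uM, stimulated-unique
#' 36% vs 38%); `"*_go"` and `"*_pathway"` mirror the GO-term and signaling
#' pathway applications (e.g. 54% of CMP dose-unique GO terms at the top dose,
#' none at 10 nM for CMP pathways). Shares without a published value are
#' fixed, realistic choices — see the methods vignette.
#'
#' @param context one of `names(dose_presets)`; ignored when `red_shares`
#'   is given.
#' @param scale total dose-unique member count at shares summing to 100
#'   (minimum 100, so integer percents are exact).
#' @param seed integer seed for the generator.
#' @param red_shares optional custom per-dose shares (5 values summing to
#'   100).
#' @param stimulated_unique_pct optional custom stimulated-unique percentage.
#' @return a [partition_plan()] for n = 6 with set names
#'   `NS, 10nM, 100nM, 1uM, 10uM, 100uM` (reference first).
#' @export
dose_response_plan <- function(context = c("control", "cmp", "control_go",
                                           "cmp_go", "control_pathway",
                                           "cmp_pathway"),
                               scale = 100L, seed = 1L,
                               red_shares = NULL,
                               stimulated_unique_pct = NULL) {
  if (is.null(red_shares)) {
    context <- match.arg(context)
    preset <- dose_presets[[context]]
    red_shares <- preset$red
    if (is.null(stimulated_unique_pct)) stimulated_unique_pct <- preset$stim_pct
  } else {
    context <- "custom"
    if (is.null(stimulated_unique_pct)) stimulated_unique_pct <- 36
  }
  stopifnot(length(red_shares) == 5L, all(red_shares >= 0),
            abs(sum(red_shares) - 100) < 1e-9,
            stimulated_unique_pct > 0, stimulated_unique_pct <= 100,
            scale >= 100)
  n <- 6L
  idx <- seq_len(2L^n - 1L)
  counts <- integer(length(idx))
  # reference = set 1; doses = sets 2..6
  red_masks <- 2L^(1:5)
  counts[red_masks] <- as.integer(round(red_shares / 100 * scale))
  total_red <- sum(counts[red_masks])
  cls <- classify_region(idx, 1L, n)
  spread <- function(total, masks) {
    base <- total %/% length(masks)
    extra <- total %% length(masks)
    counts[masks] <<- base + c(rep(1L, extra), rep(0L, length(masks) - extra))
  }
  grey_total <- as.integer(round(total_red * (100 / stimulated_unique_pct - 1)))
  spread(grey_total, idx[cls == "GREY"])
  spread(as.integer(round(0.8 * scale)), idx[cls == "BLACK"])
  counts[1L] <- as.integer(round(0.4 * scale))          # BLUE: reference only
  counts[2L^n - 1L] <- as.integer(round(0.1 * scale))   # GREEN: common to all
  partition_plan(n, counts, label_prefix = toupper(substr(context, 1, 2)),
                 seed = seed,
                 set_names = c("NS", "10nM", "100nM", "1uM", "10uM", "100uM"))
}
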