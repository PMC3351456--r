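# Dose-response set summaries: category histogram, dose-unique proportional
# distribution, and dose-by-dose cross-context overlap.

round_half_up <- function(x) floor(x + 0.5)

#' Region-size histogram with five-colour classification
#'
#' The renderable data behind the per-region distribution bar charts: one row
#' per region (all `2^n - 1` of them, ascending index) with its size and its
#' category code relative to the reference set.
#'
#' @param partition a `venn_partition`.
#' @param reference_index reference set (index or name); default set 1.
#' @return data.frame with columns `region_index`, `signature` (set names
#'   joined by the intersection sign), `size`, `category`.
#' @export
category_histogram <- function(partition, reference_index = 1L) {
  ref <- resolve_reference(partition$collection, reference_index)
  n <- partition$n
  idx <- seq_len(2L^n - 1L)
  nm <- names(partition$collection$sets)
  data.frame(
    region_index = idx,
    signature = vapply(idx, signature_label, character(1), set_names = nm),
    size = unname(region_sizes(partition)),
    category = classify_region(idx, ref, n),
    stringsAsFactors = FALSE
  )
}

#' Dose-unique profile of a partition
#'
#' Summarizes the RED regions: for each non-reference ("dose") set, the count
#' of members unique to that set and absent from the reference, the share of
#' each dose within the total dose-unique pool (integer percent, rounded half
#' up), and the stimulated-unique fraction — the percentage of stimulated
#' members that are dose-unique.
#'
#' The denominator of the stimulated-unique fraction is controlled by
#' `denominator`:
#' \describe{
#'   \item{`"stimulated_only"`}{members present in at least one dose set but
#'     absent from the reference set (the default: reference-common members
#'     are excluded).}
#'   \item{`"all_stimulated"`}{members present in at least one dose set,
#'     whether or not they also occur in the reference set.}
#' }
#'
#' @param partition a `venn_partition` with `n >= 3` (reference plus at least
#'   two doses).
#' @param reference_index reference set (index or name); default set 1.
#' @param denominator see above.
#' @return an object of class `dose_profile`; see Details.
#' @export
dose_unique_profile <- function(partition, reference_index = 1L,
                                denominator = c("stimulated_only",
                                                "all_stimulated")) {
  denominator <- match.arg(denominator)
  n <- partition$n
  if (n < 3L) stop("dose profiling needs a reference plus at least two doses (n >= 3)")
  ref <- resolve_reference(partition$collection, reference_index)
  nm <- names(partition$collection$sets)
  doses <- setdiff(seq_len(n), ref)
  sizes <- region_sizes(partition)
  if (all(vapply(partition$collection$sets[doses], length, integer(1)) == 0L)) {
    stop("every dose set is empty; nothing to profile")
  }
  unique_counts <- stats::setNames(unname(sizes[2L^(doses - 1L)]), nm[doses])
  total_unique <- sum(unique_counts)
  idx <- seq_len(2L^n - 1L)
  ref_bit <- 2L^(ref - 1L)
  in_ref <- bitwAnd(idx, ref_bit) > 0L
  denom <- if (denominator == "stimulated_only") {
    sum(sizes[idx[!in_ref]])
  } else {
    sum(sizes[idx[idx != ref_bit]]) # every region touching >= 1 dose set
  }
  frac_raw <- if (total_unique > 0) 100 * unique_counts / total_unique
              else stats::setNames(rep(NA_real_, length(doses)), nm[doses])
  stim_raw <- if (denom > 0) 100 * total_unique / denom else NA_real_
  structure(list(
    reference_name = nm[ref],
    dose_names = nm[doses],
    unique_counts = unique_counts,
    unique_fractions = round_half_up(frac_raw),
    unique_fractions_raw = frac_raw,
    total_unique = total_unique,
    denominator = denominator,
    denominator_size = denom,
    stimulated_unique_fraction = round_half_up(stim_raw),
    stimulated_unique_fraction_raw = stim_raw
  ), class = "dose_profile")
}

#' @export
print.dose_profile <- function(x, ...) {
  cat(sprintf("<dose_profile> reference: %s\n", x$reference_name))
  for (d in x$dose_names) {
    cat(sprintf("  %-12s unique %4d  (%s%% of dose-unique pool)\n",
                d, x$unique_counts[[d]],
                format(x$unique_fractions[[d]])))
  }
  cat(sprintf("  dose-unique members: %d of %d stimulated (%s%%, denominator: %s)\n",
              x$total_unique, x$denominator_size,
              format(x$stimulated_unique_fraction), x$denominator))
  invisible(x)
}

#' Turn a dose profile into a writable data.frame
#' @param profile a [dose_unique_profile()] result.
#' @return data.frame with columns `dose`, `unique_count`, `unique_fraction`,
#'   `unique_fraction_raw`.
#' @export
dose_profile_table <- function(profile) {
  data.frame(
    dose = profile$dose_names,
    unique_count = unname(profile$unique_counts),
    unique_fraction = unname(profile$unique_fractions),
    unique_fraction_raw = unname(profile$unique_fractions_raw),
    stringsAsFactors = FALSE
  )
}

#' Dose-by-dose comparison of two cellular contexts
#'
#' For two collections sharing the same ordered condition names (reference
#' plus doses), reports per condition the two set sizes and their
#' intersection under canonical label comparison — the "minimal cross-over"
#' check between contexts.
#'
#' @param collection_a,collection_b two [set_collection()]s with identical
#'   condition (set) name sequences.
#' @return data.frame with columns `condition`, `size_a`, `size_b`, `overlap`.
#' @export
cross_context_compare <- function(collection_a, collection_b) {
  nm_a <- names(collection_a$sets)
  nm_b <- names(collection_b$sets)
  if (!identical(nm_a, nm_b)) {
    stop_cogwheel("condition_mismatch", sprintf(
      "condition names differ between contexts: [%s] vs [%s]",
      paste(nm_a, collapse = ", "), paste(nm_b, collapse = ", ")))
  }
  cs <- collection_a$case_sensitive && collection_b$case_sensitive
  rows <- lapply(seq_along(nm_a), function(i) {
    a <- label_key(collection_a$sets[[i]], cs)
    b <- label_key(collection_b$sets[[i]], cs)
    data.frame(condition = nm_a[i], size_a = length(a), size_b = length(b),
               overlap = length(intersect(a, b)), stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
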