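# ---- label canonicalization -------------------------------------------------

#' Canonicalize raw spreadsheet cells into a set of labels
#'
#' Trims whitespace, drops empty and whitespace-only cells, and collapses
#' duplicates. Case is always preserved in the returned labels; when
#' `case_sensitive = FALSE`, duplicates are detected case-insensitively and the
#' first-seen spelling is kept.
#'
#' @param raw_cells character vector of raw cell contents (may contain `NA`,
#'   empty strings, duplicates).
#' @param case_sensitive logical; compare labels case-sensitively (default).
#'   Gene symbols are case-meaningful, so the default is strict.
#' @param strip logical; trim leading/trailing whitespace first.
#' @return character vector of unique labels in first-appearance order, with
#'   attribute `"n_dropped"` giving the number of duplicate cells collapsed.
#' @examples
#' canonicalize_entries(c("GIT1", " GIT1", "", "PAK1"))
#' canonicalize_entries(c("git1", "GIT1"), case_sensitive = FALSE)
#' @export
canonicalize_entries <- function(raw_cells, case_sensitive = TRUE, strip = TRUE) {
  x <- as.character(raw_cells)
  x <- x[!is.na(x)]
  if (strip) x <- trimws(x)
  x <- x[nzchar(x)]
  key <- label_key(x, case_sensitive)
  dup <- duplicated(key)
  out <- x[!dup]
  attr(out, "n_dropped") <- sum(dup)
  out
}

label_key <- function(x, case_sensitive) {
  if (case_sensitive) x else tolower(x)
}

# ---- collections ------------------------------------------------------------

#' Assemble an ordered collection of 2--6 named sets
#'
#' The collection is the in-memory form of a spreadsheet whose columns are
#' sets: column order is set order, set 1 first. Members are canonicalized via
#' [canonicalize_entries()].
#'
#' @param sets named list of character vectors (raw members). 2 to 6 elements;
#'   names must be unique and non-empty.
#' @param case_sensitive,strip passed to [canonicalize_entries()].
#' @return an object of class `set_collection` with elements `sets` (named
#'   list of canonical labels), `n`, and `case_sensitive`.
#' @seealso [compute_partition()], [read_collection()]
#' @export
set_collection <- function(sets, case_sensitive = TRUE, strip = TRUE) {
  if (!is.list(sets)) stop("`sets` must be a named list of character vectors")
  n <- length(sets)
  if (n < 2L || n > 6L) {
    stop_cogwheel("set_count",
                  sprintf("unsupported set count: %d (2 to 6 sets required)", n))
  }
  nm <- names(sets)
  if (is.null(nm) || any(!nzchar(nm))) {
    stop_cogwheel("format", "every set needs a non-empty name")
  }
  if (anyDuplicated(nm)) {
    stop_cogwheel("format",
                  sprintf("duplicate set names: %s",
                          paste(unique(nm[duplicated(nm)]), collapse = ", ")))
  }
  canon <- lapply(sets, canonicalize_entries,
                  case_sensitive = case_sensitive, strip = strip)
  dropped <- sum(vapply(canon, function(s) attr(s, "n_dropped"), integer(1)))
  canon <- lapply(canon, function(s) { attributes(s) <- NULL; s })
  structure(
    list(sets = canon, n = n, case_sensitive = case_sensitive,
         n_duplicates_collapsed = dropped),
    class = "set_collection"
  )
}

#' @export
print.set_collection <- function(x, ...) {
  cat(sprintf("<set_collection> %d sets, union size %d\n",
              x$n, length(collection_union(x))))
  sizes <- vapply(x$sets, length, integer(1))
  for (i in seq_len(x$n)) {
    cat(sprintf("  set %d  %-20s %d members\n", i, names(x$sets)[i], sizes[i]))
  }
  invisible(x)
}

collection_union <- function(collection) {
  all <- unlist(collection$sets, use.names = FALSE)
  all[!duplicated(label_key(all, collection$case_sensitive))]
}

# ---- region signatures ------------------------------------------------------

#' Region index of a membership signature
#'
#' A region of the n-set Venn partition is named by its membership mask: bit
#' `i - 1` is set iff the region lies inside set `i` (set 1 is the least
#' significant bit). The region index is the integer value of that mask, a
#' bijection onto `1 .. 2^n - 1`; the all-zero mask ("outside every set") is
#' not a region.
#'
#' @param sig integer mask(s), `1 <= sig <= 2^n - 1`.
#' @param n set count (2--6).
#' @return integer index, identical to the validated mask.
#' @examples
#' signature_index(1L, 6)            # set 1 only -> 1
#' signature_index(63L, 6)           # all six sets -> 63
#' signature_index(bitwOr(2L, 8L), 4) # sets 2 and 4 -> 10
#' @export
signature_index <- function(sig, n) {
  check_n(n)
  sig <- as.integer(sig)
  if (any(is.na(sig)) || any(sig < 1L) || any(sig > 2L^n - 1L)) {
    stop(sprintf("signature mask must lie in 1 .. %d for n = %d", 2L^n - 1L, n))
  }
  sig
}

#' Which sets make up a signature
#'
#' @param sig integer mask.
#' @param n set count.
#' @return integer vector of 1-based set positions whose bit is set.
#' @export
signature_sets <- function(sig, n) {
  sig <- signature_index(sig, n)
  stopifnot(length(sig) == 1L)
  which(bitwAnd(sig, 2L^(seq_len(n) - 1L)) > 0L)
}

#' Human-readable signature label
#'
#' @param sig integer mask.
#' @param set_names character vector of all set names, in set order.
#' @param sep separator between set names (defaults to the intersection sign).
#' @return a single string, e.g. `"A∩B"`.
#' @export
signature_label <- function(sig, set_names, sep = "∩") {
  paste(set_names[signature_sets(sig, length(set_names))], collapse = sep)
}

bit_count <- function(sig, n) {
  rowSums(outer(as.integer(sig), 2L^(seq_len(n) - 1L),
                function(a, b) bitwAnd(a, b) > 0L))
}

check_n <- function(n) {
  if (length(n) != 1L || is.na(n) || n < 2 || n > 6 || n != as.integer(n)) {
    stop_cogwheel("set_count",
                  sprintf("unsupported set count: %s (2 to 6 sets required)",
                          paste(n, collapse = ",")))
  }
  invisible(as.integer(n))
}

# ---- the disjoint partition -------------------------------------------------

#' Compute the complete disjoint intersection partition
#'
#' Every member of the union of the input sets is assigned to exactly one of
#' the `2^n - 1` regions, the one whose membership mask matches the member's
#' presence across all n sets. Empty regions are kept as empty entries, so the
#' partition always has exactly `2^n - 1` keys (63 for six sets).
#'
#' @param collection a [set_collection()].
#' @return an object of class `venn_partition`: list with `collection`, `n`,
#'   and `regions`, a named list (names `"1" .. "2^n-1"`, the region indices)
#'   of sorted member vectors.
#' @examples
#' cl <- set_collection(list(A = "a", B = "b"))
#' p <- compute_partition(cl)
#' region_members(p, 3) # empty: a and b do not overlap
#' @export
compute_partition <- function(collection) {
  if (!inherits(collection, "set_collection")) {
    stop("`collection` must be a set_collection")
  }
  n <- check_n(collection$n)
  union_labels <- collection_union(collection)
  ukey <- label_key(union_labels, collection$case_sensitive)
  mask <- integer(length(union_labels))
  for (i in seq_len(n)) {
    skey <- label_key(collection$sets[[i]], collection$case_sensitive)
    mask <- mask + 2L^(i - 1L) * (ukey %in% skey)
  }
  idx <- seq_len(2L^n - 1L)
  regions <- lapply(idx, function(m) sort(union_labels[mask == m]))
  names(regions) <- as.character(idx)
  structure(list(collection = collection, n = n, regions = regions),
            class = "venn_partition")
}

#' @export
print.venn_partition <- function(x, ...) {
  sizes <- region_sizes(x)
  cat(sprintf("<venn_partition> n = %d sets, %d regions (%d non-empty), union size %d\n",
              x$n, length(sizes), sum(sizes > 0), sum(sizes)))
  invisible(x)
}

#' Members of one region
#' @param partition a [compute_partition()] result.
#' @param sig region index / mask.
#' @return sorted character vector (possibly empty).
#' @export
region_members <- function(partition, sig) {
  partition$regions[[as.character(signature_index(sig, partition$n))]]
}

#' Sizes of all regions, in region-index order
#' @param partition a `venn_partition`.
#' @return named integer vector of length `2^n - 1`.
#' @export
region_sizes <- function(partition) {
  vapply(partition$regions, length, integer(1))
}

# ---- five-colour classification against a reference set ---------------------

#' Classify a region relative to a reference (non-stimulated) set
#'
#' The five codes tile the signature space:
#' \describe{
#'   \item{GREEN}{common to all doses and the reference set (all bits set).}
#'   \item{BLUE}{unique to the reference set only.}
#'   \item{RED}{unique to a single non-reference (dose) set, absent from the
#'     reference — the "dose-unique" category.}
#'   \item{GREY}{common to two or more dose sets, absent from the reference.}
#'   \item{BLACK}{present in the reference plus at least one (but not every)
#'     dose set.}
#' }
#' For six sets with reference 1 the census over all 63 signatures is
#' BLUE 1, RED 5, GREY 26, BLACK 30, GREEN 1.
#'
#' @param sig integer mask(s).
#' @param reference_index 1-based position of the reference set.
#' @param n set count.
#' @return character vector of codes, one per signature.
#' @export
classify_region <- function(sig, reference_index, n) {
  n <- check_n(n)
  if (length(reference_index) != 1L || is.na(reference_index) ||
      reference_index < 1 || reference_index > n) {
    stop(sprintf("reference_index must lie in 1 .. %d", n))
  }
  sig <- signature_index(sig, n)
  ref_bit <- 2L^(as.integer(reference_index) - 1L)
  in_ref <- bitwAnd(sig, ref_bit) > 0L
  n_dose <- bit_count(sig, n) - in_ref
  out <- character(length(sig))
  out[sig == 2L^n - 1L] <- "GREEN"
  out[out == "" & in_ref & n_dose == 0L] <- "BLUE"
  out[out == "" & !in_ref & n_dose == 1L] <- "RED"
  out[out == "" & !in_ref] <- "GREY"
  out[out == ""] <- "BLACK"
  out
}

#' Category codes in display order
#' @return character vector of the five codes.
#' @export
category_codes <- function() c("BLUE", "RED", "GREY", "BLACK", "GREEN")

#' Dose-unique members per non-reference set
#'
#' For each non-reference set, the members of the region containing exactly
#' that set (its RED region): labels present at a single dose and absent from
#' the reference condition.
#'
#' @param partition a `venn_partition`.
#' @param reference_index 1-based reference set position (default 1: the
#'   non-stimulated condition is conventionally the first column).
#' @return named list (one element per non-reference set, in set order) of
#'   sorted member vectors.
#' @export
dose_unique_members <- function(partition, reference_index = 1L) {
  n <- partition$n
  classify_region(1L, reference_index, n) # validates reference_index
  doses <- setdiff(seq_len(n), as.integer(reference_index))
  out <- lapply(doses, function(i) region_members(partition, 2L^(i - 1L)))
  names(out) <- names(partition$collection$sets)[doses]
  out
}

# ---- condition helpers -------------------------------------------------------

stop_cogwheel <- function(kind, message) {
  stop(structure(
    class = c(paste0("cogwheel_", kind), "cogwheel_error", "error", "condition"),
    list(message = message, call = sys.call(-1))
  ))
}

resolve_reference <- function(collection, reference) {
  nm <- names(collection$sets)
  if (is.character(reference)) {
    i <- match(reference, nm)
    if (is.na(i)) {
      stop_cogwheel("format", sprintf("no set named '%s' (sets: %s)",
                                      reference, paste(nm, collapse = ", ")))
    }
    return(i)
  }
  i <- as.integer(reference)
  if (is.na(i) || i < 1L || i > collection$n) {
    stop(sprintf("reference must be a set name or an index in 1 .. %d",
                 collection$n))
  }
  i
}
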