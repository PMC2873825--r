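## Contact map construction and long-range pair enumeration.
##
## A pair (i, j) is a long-range contact when the C-alpha distance
## d(i, j) <= cutoff (8 A by default) and the sequence separation
## j - i >= min_sep (24 by default, "separated at least 24 residues").

#' Build the long-range contact map of a chain
#'
#' A pair enters the map iff both C-alpha atoms are present, the Euclidean
#' C-alpha distance is at most `cutoff`, and `j - i >= min_sep`. Only the
#' upper triangle (i < j) is stored.
#'
#' @param trace A `ca_trace` object.
#' @param cutoff Distance cutoff in Angstrom (default 8).
#' @param min_sep Minimum sequence separation (default 24).
#' @return An object of class `contact_map`: list with `chain_id`, `L`,
#'   `cutoff`, `min_sep`, `contact_pairs` (n x 2 integer matrix, i < j)
#'   and `missing_mask`.
#' @export
build_contact_map <- function(trace, cutoff = 8, min_sep = 24) {
  L <- length(trace$residue_numbers)
  present <- !trace$missing_mask
  pairs <- matrix(integer(), 0, 2, dimnames = list(NULL, c("i", "j")))
  if (sum(present) >= 2L) {
    d <- as.matrix(stats::dist(trace$coords[present, , drop = FALSE]))
    idx <- which(present)
    hit <- which(upper.tri(d) & d <= cutoff, arr.ind = TRUE)
    if (nrow(hit) > 0) {
      i <- idx[hit[, 1]]; j <- idx[hit[, 2]]
      keep <- (j - i) >= min_sep
      if (any(keep)) {
        pairs <- cbind(i = i[keep], j = j[keep])
        pairs <- pairs[order(pairs[, 1], pairs[, 2]), , drop = FALSE]
      }
    }
  }
  structure(list(chain_id = trace$chain_id, L = L, cutoff = cutoff,
                 min_sep = min_sep, contact_pairs = pairs,
                 missing_mask = trace$missing_mask),
            class = "contact_map")
}

#' Enumerate all long-range residue pairs of a chain
#'
#' All (i, j) with 1 <= i < j <= L and j - i >= min_sep, in lexicographic
#' order. The count is (L - s)(L - s + 1)/2 for L > s, else zero.
#'
#' @param L Chain length.
#' @param min_sep Minimum sequence separation (default 24).
#' @return Integer matrix with columns `i`, `j`.
#' @export
enumerate_long_range_pairs <- function(L, min_sep = 24) {
  s <- min_sep
  if (L <= s) return(matrix(integer(), 0, 2, dimnames = list(NULL, c("i", "j"))))
  i <- rep.int(seq_len(L - s), times = (L - s):1)
  j <- unlist(lapply(seq_len(L - s), function(k) seq.int(k + s, L)))
  cbind(i = i, j = as.integer(j))
}

#' Label every long-range pair of a chain
#'
#' Enumerates all long-range pairs, drops pairs touching a residue with a
#' missing C-alpha (the distance is undefined), and labels the rest:
#' 1 = contact (positive class), 0 = non-contact (negative class).
#'
#' @param cm A `contact_map`.
#' @return Data frame with columns `i`, `j`, `label`.
#' @export
label_long_range_pairs <- function(cm) {
  pairs <- enumerate_long_range_pairs(cm$L, cm$min_sep)
  if (nrow(pairs) == 0)
    return(data.frame(i = integer(), j = integer(), label = integer()))
  if (any(cm$missing_mask)) {
    bad <- which(cm$missing_mask)
    keep <- !(pairs[, 1] %in% bad | pairs[, 2] %in% bad)
    pairs <- pairs[keep, , drop = FALSE]
  }
  key <- pairs[, 1] * (cm$L + 1) + pairs[, 2]
  ckey <- if (nrow(cm$contact_pairs) > 0)
    cm$contact_pairs[, 1] * (cm$L + 1) + cm$contact_pairs[, 2] else integer()
  data.frame(i = unname(pairs[, 1]), j = unname(pairs[, 2]),
             label = as.integer(key %in% ckey), row.names = NULL)
}
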