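## Window encoding of residue pairs into sequence-profile (SP) vectors and
## sequence-profile centers (SPCs).
##
## A pair (i, j) is encoded by concatenating the profile rows of three
## windows: width w_flank centered at i, width w_mid centered at the
## midpoint int((i+j)/2), and width w_flank centered at j. With the
## defaults 9/5/9 that is 23 residues x 20 profile columns = 460 features.
## Rows falling outside 1..L are zero vectors (termini padding); the
## concatenated vector is L1-normalized.

#' Encode one residue pair as an SP vector
#'
#' @param profile A `profile_matrix`.
#' @param i,j Residue indices, 1 <= i < j <= L (sequential numbering).
#' @param w_flank Width of the two windows centered at i and j (odd,
#'   default 9).
#' @param w_mid Width of the central window at `floor((i+j)/2)` (odd,
#'   default 5).
#' @return Numeric vector of length `20 * (2 * w_flank + w_mid)`,
#'   L1-normalized (all-zero content is returned all-zero).
#' @export
encode_pair <- function(profile, i, j, w_flank = 9, w_mid = 5) {
  if (i >= j) stop_gac("encode_pair requires i < j (got %d, %d)", i, j)
  encode_pairs(profile, cbind(i = i, j = j), w_flank, w_mid)[1, ]
}

#' Encode many residue pairs at once
#'
#' Vectorized form of [encode_pair()]: one row per pair.
#'
#' @param profile A `profile_matrix`.
#' @param pairs Two-column matrix or data frame of (i, j) indices.
#' @param w_flank,w_mid Window widths as in [encode_pair()].
#' @return Numeric matrix, one L1-normalized row per pair.
#' @export
encode_pairs <- function(profile, pairs, w_flank = 9, w_mid = 5) {
  if (w_flank %% 2 == 0 || w_mid %% 2 == 0)
    stop_gac("window sizes must be odd (got w_flank=%d, w_mid=%d)", w_flank, w_mid)
  pairs <- as.matrix(pairs)
  if (any(pairs[, 1] >= pairs[, 2])) stop_gac("encode_pairs requires i < j")
  P <- profile$matrix
  L <- profile$L
  n <- nrow(pairs)
  hf <- (w_flank - 1L) %/% 2L
  hm <- (w_mid - 1L) %/% 2L
  centers <- cbind(matrix(rep(pairs[, 1], w_flank), n),
                   matrix(rep((pairs[, 1] + pairs[, 2]) %/% 2L, w_mid), n),
                   matrix(rep(pairs[, 2], w_flank), n))
  offsets <- c(-hf:hf, -hm:hm, -hf:hf)
  nwin <- length(offsets)
  out <- matrix(0, n, 20L * nwin)
  for (s in seq_len(nwin)) {
    rows <- centers[, s] + offsets[s]
    ok <- rows >= 1L & rows <= L
    cols <- ((s - 1L) * 20L + 1L):(s * 20L)
    if (any(ok)) out[ok, cols] <- P[rows[ok], , drop = FALSE]
  }
  l1_normalize_rows(out)
}

#' Per-chain sequence profile center
#'
#' The SPC of one contact class within one chain is the arithmetic mean of
#' all that chain's SP vectors of the class.
#'
#' @param sp Matrix of SP vectors (one row per pair).
#' @param labels Integer 0/1 vector, one per row of `sp`.
#' @param class_id Class to average (0 or 1).
#' @param chain_id Optional chain identifier for provenance.
#' @return An object of class `sp_center`: list with `class_id`, `vector`,
#'   `m` (number of vectors averaged) and `provenance = "per_chain"`.
#' @export
spc_per_chain <- function(sp, labels, class_id, chain_id = NA_character_) {
  sel <- labels == class_id
  if (!any(sel)) stop_gac("empty class: chain has no samples of class %d", class_id)
  structure(list(class_id = class_id, chain_id = chain_id,
                 vector = colMeans(sp[sel, , drop = FALSE]),
                 m = sum(sel), provenance = "per_chain"),
            class = "sp_center")
}

#' Pooled sequence profile center for test chains
#'
#' Test chains have unknown structure, so their SPC is the mean of the
#' per-chain SPCs of the training chains; every test chain uses the same
#' pooled center.
#'
#' @param centers List of `sp_center` objects (all the same class and
#'   dimension).
#' @param class_id Class the centers belong to.
#' @return An `sp_center` with `provenance = "test_pooled"` and `m` = the
#'   number of training chains averaged.
#' @export
spc_for_test <- function(centers, class_id) {
  if (length(centers) == 0) stop_gac("empty class: no training-chain centers for class %d", class_id)
  if (any(vapply(centers, function(x) x$class_id, 0) != class_id))
    stop_gac("all centers must belong to class %d", class_id)
  mat <- do.call(rbind, lapply(centers, `[[`, "vector"))
  structure(list(class_id = class_id, chain_id = NA_character_,
                 vector = colMeans(mat), m = length(centers),
                 provenance = "test_pooled"),
            class = "sp_center")
}

#' Amino-acid composition of contact and non-contact pairs
#'
#' For each class, counts every residue occurrence among pairs of that
#' class (both pair members are counted) and normalizes to fractions.
#'
#' @param pairs Data frame with columns `i`, `j`, `label` (and optionally
#'   `chain_id` when `residues` is a named list).
#' @param residues One-letter residue string for the chain, or a named
#'   list of such strings keyed by `chain_id`.
#' @return A 20 x 2 matrix of fractions (rows in canonical order, columns
#'   `contact` and `noncontact`); attribute `n_unknown` counts residue
#'   letters outside the standard 20 that were excluded.
#' @export
aa_contact_composition <- function(pairs, residues) {
  if (is.list(residues)) {
    if (is.null(pairs$chain_id)) stop_gac("pairs need a chain_id column for multi-chain residues")
    aa_i <- substr(residues[pairs$chain_id], pairs$i, pairs$i)
    aa_j <- substr(residues[pairs$chain_id], pairs$j, pairs$j)
  } else {
    aa_i <- substr(rep(residues, nrow(pairs)), pairs$i, pairs$i)
    aa_j <- substr(rep(residues, nrow(pairs)), pairs$j, pairs$j)
  }
  aa <- c(aa_i, aa_j)
  lab <- rep(pairs$label, 2)
  known <- aa %in% AA_ORDER
  n_unknown <- sum(!known)
  if (n_unknown > 0) {
    warning(sprintf("%d residue occurrences with unknown letters excluded", n_unknown))
    aa <- aa[known]; lab <- lab[known]
  }
  out <- matrix(0, 20, 2, dimnames = list(AA_ORDER, c("contact", "noncontact")))
  for (k in c(1L, 0L)) {
    col <- if (k == 1L) "contact" else "noncontact"
    sel <- lab == k
    if (!any(sel)) stop_gac("no class-%d pairs: composition undefined", k)
    tab <- table(factor(aa[sel], levels = AA_ORDER))
    out[, col] <- as.numeric(tab) / sum(tab)
  }
  attr(out, "n_unknown") <- n_unknown
  out
}

#' Log2 contact propensity per amino acid
#'
#' `log2(fraction in contacts / fraction in non-contacts)`; amino acids
#' absent from either class are reported as `NA` (undefined), never as
#' +/-Inf.
#'
#' @param composition Output of [aa_contact_composition()].
#' @return Named numeric vector of length 20.
#' @export
aa_propensity_log2 <- function(composition) {
  f1 <- composition[, "contact"]
  f0 <- composition[, "noncontact"]
  out <- rep(NA_real_, 20)
  names(out) <- rownames(composition)
  ok <- f1 > 0 & f0 > 0
  out[ok] <- log2(f1[ok] / f0[ok])
  out
}

#' Least-squares line of contact count against chain length
#'
#' Chain length is approximately linear in the number of long-range
#' contacts; this fits the ordinary least-squares line used to summarize a
#' dataset.
#'
#' @param lengths Chain lengths.
#' @param contact_counts Long-range contact counts, one per chain.
#' @return Named numeric vector `c(slope, intercept)`.
#' @export
fit_length_contact_line <- function(lengths, contact_counts) {
  if (length(lengths) != length(contact_counts))
    stop_gac("lengths and contact_counts must have equal length")
  if (length(unique(lengths)) < 2) stop_gac("need at least 2 distinct lengths")
  fit <- stats::lm.fit(cbind(1, lengths), contact_counts)
  c(slope = unname(fit$coefficients[2]), intercept = unname(fit$coefficients[1]))
}
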