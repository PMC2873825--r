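## File I/O: PDB C-alpha traces, per-residue profile tables, CASP RR
## prediction files. Residues are renumbered to sequential 1..L on load;
## all downstream arithmetic (window centers, sequence separation) uses
## these sequential indices.

#' Read C-alpha coordinates for one chain from a PDB-format file
#'
#' Parses ATOM records (fixed-column PDB format) for the requested chain.
#' Residues are identified by their (resSeq, iCode) pair in file order and
#' renumbered sequentially from 1; alternate locations are resolved to the
#' highest occupancy (first record on ties). Residues that have ATOM
#' records but no C-alpha are kept in the sequence and flagged missing.
#'
#' @param path Path to a PDB-format text file.
#' @param chain_id Single chain identifier character (use `" "` for blank).
#' @return An object of class `ca_trace`: a list with `chain_id`,
#'   `residue_numbers` (sequential 1..L), `author_numbers`,
#'   `residue_names` (one-letter codes, `X` for non-standard), `coords`
#'   (L x 3 matrix, `NA` rows where the C-alpha is absent) and
#'   `missing_mask` (logical length L).
#' @export
read_pdb_ca <- function(path, chain_id) {
  lines <- readLines(path, warn = FALSE)
  atoms <- lines[startsWith(lines, "ATOM")]
  if (length(atoms) == 0L) stop_gac("no CA records: file '%s' has no ATOM records", path)
  chain <- substr(atoms, 22, 22)
  atoms <- atoms[chain == chain_id]
  if (length(atoms) == 0L) stop_gac("chain not found: '%s' in '%s'", chain_id, path)

  res_key <- paste0(trimws(substr(atoms, 23, 26)), "|", substr(atoms, 27, 27))
  keys <- unique(res_key)  # file order defines sequence order
  L <- length(keys)

  atom_name <- trimws(substr(atoms, 13, 16))
  occ <- suppressWarnings(as.numeric(substr(atoms, 55, 60)))
  occ[is.na(occ)] <- 1
  is_ca <- atom_name == "CA"

  coords <- matrix(NA_real_, L, 3)
  res_names <- character(L)
  author <- integer(L)
  for (r in seq_len(L)) {
    in_res <- which(res_key == keys[r])
    first <- in_res[1L]
    res_names[r] <- three_to_one(trimws(substr(atoms[first], 18, 20)))
    author[r] <- suppressWarnings(as.integer(trimws(substr(atoms[first], 23, 26))))
    cas <- in_res[is_ca[in_res]]
    if (length(cas) > 0L) {
      best <- cas[which.max(occ[cas])]  # which.max takes the first on ties
      coords[r, ] <- c(
        as.numeric(substr(atoms[best], 31, 38)),
        as.numeric(substr(atoms[best], 39, 46)),
        as.numeric(substr(atoms[best], 47, 54)))
    }
  }
  if (all(is.na(coords[, 1]))) stop_gac("no CA records for chain '%s' in '%s'", chain_id, path)

  structure(list(
    chain_id = chain_id,
    residue_numbers = seq_len(L),
    author_numbers = author,
    residue_names = res_names,
    coords = coords,
    missing_mask = is.na(coords[, 1])
  ), class = "ca_trace")
}

THREE_TO_ONE <- c(
  ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C", GLN = "Q",
  GLU = "E", GLY = "G", HIS = "H", ILE = "I", LEU = "L", LYS = "K",
  MET = "M", PHE = "F", PRO = "P", SER = "S", THR = "T", TRP = "W",
  TYR = "Y", VAL = "V")
ONE_TO_THREE <- setNames(names(THREE_TO_ONE), unname(THREE_TO_ONE))

three_to_one <- function(x) {
  out <- THREE_TO_ONE[x]
  out[is.na(out)] <- "X"
  unname(out)
}

#' Write a C-alpha trace as a minimal PDB file
#'
#' Used by the synthetic generator so the full file pipeline can be
#' exercised. Coordinates are written at standard PDB precision (%8.3f).
#'
#' @param trace A `ca_trace` object.
#' @param path Output path.
#' @export
write_pdb_ca <- function(trace, path) {
  con <- file(path, "w")
  on.exit(close(con))
  serial <- 0L
  for (r in seq_along(trace$residue_numbers)) {
    if (trace$missing_mask[r]) next
    serial <- serial + 1L
    res3 <- ONE_TO_THREE[trace$residue_names[r]]
    if (is.na(res3)) res3 <- "UNK"
    writeLines(sprintf(
      "ATOM  %5d  CA  %3s %s%4d    %8.3f%8.3f%8.3f  1.00  0.00           C",
      serial, res3, trace$chain_id, trace$residue_numbers[r],
      trace$coords[r, 1], trace$coords[r, 2], trace$coords[r, 3]), con)
  }
  writeLines("END", con)
  invisible(path)
}

#' Read a per-residue sequence profile table
#'
#' Expects whitespace/tab-delimited text with a header row naming at least
#' the columns `idx`, `aa` and the 20 standard amino acids (any order).
#' Columns are re-ordered into the canonical order [aa_order()].
#'
#' @param path Path to the profile table.
#' @param chain_id Chain identifier to attach (default: file basename).
#' @return An object of class `profile_matrix`: list with `chain_id`, `L`,
#'   `residues` (one-letter string) and `matrix` (L x 20, canonical column
#'   order, non-negative).
#' @export
read_profile_table <- function(path, chain_id = NULL) {
  df <- utils::read.table(path, header = TRUE, check.names = FALSE,
                          stringsAsFactors = FALSE)
  need <- c("idx", "aa", AA_ORDER)
  missing_cols <- setdiff(need, colnames(df))
  if (length(missing_cols) > 0L)
    stop_gac("profile table missing column(s): %s", paste(missing_cols, collapse = ", "))
  L <- nrow(df)
  if (!identical(as.integer(df$idx), seq_len(L)))
    stop_gac("profile table 'idx' column must be 1..%d in order", L)
  m <- as.matrix(df[, AA_ORDER])
  if (!is.numeric(m)) stop_gac("profile table has non-numeric entries")
  if (anyNA(m)) stop_gac("profile table has missing entries")
  if (any(m < 0)) stop_gac("profile table has negative entries")
  dimnames(m) <- list(NULL, AA_ORDER)
  if (is.null(chain_id)) chain_id <- sub("\\.[^.]*$", "", basename(path))
  structure(list(chain_id = chain_id, L = L,
                 residues = paste(df$aa, collapse = ""), matrix = m),
            class = "profile_matrix")
}

#' Write a profile matrix as a TSV table
#'
#' @param profile A `profile_matrix` object.
#' @param path Output path.
#' @export
write_profile_table <- function(profile, path) {
  df <- data.frame(idx = seq_len(profile$L),
                   aa = strsplit(profile$residues, "")[[1]],
                   profile$matrix, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Build a prediction set for one chain
#'
#' @param chain_id Chain identifier.
#' @param records Data frame with columns `i`, `j`, `score`, `label`
#'   (i < j, sequence separation at least `min_sep`).
#' @param cutoff,min_sep,model_id Metadata recorded with the predictions.
#' @return An object of class `prediction_set`.
#' @export
prediction_set <- function(chain_id, records,
                           cutoff = 8, min_sep = 24, model_id = NA_character_) {
  records <- as.data.frame(records)
  if (nrow(records) > 0) {
    if (any(records$i >= records$j)) stop_gac("prediction records must have i < j")
    if (any(records$j - records$i < min_sep))
      stop_gac("prediction records violate min separation %d", min_sep)
  }
  structure(list(chain_id = chain_id, records = records,
                 cutoff = cutoff, min_sep = min_sep, model_id = model_id),
            class = "prediction_set")
}

#' Write predictions in CASP RR format
#'
#' Emits `PFRMAT RR` header lines then one record per line,
#' `i j 0 <cutoff> p`, where `p = max(1 - score, 0.001)` maps the
#' ensemble score (lower = more contact-like) to an RR probability
#' (higher = more confident). Records must already be ranked most
#' contact-like first.
#'
#' @param predictions A `prediction_set` with records sorted by score
#'   ascending.
#' @param path Output path.
#' @export
write_rr <- function(predictions, path) {
  rec <- predictions$records
  if (nrow(rec) > 1 && is.unsorted(rec$score)) {
    stop_gac("RR records must be sorted most contact-like first (rank before writing)")
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("PFRMAT RR", paste("TARGET", predictions$chain_id), "MODEL 1"), con)
  if (nrow(rec) > 0) {
    p <- pmax(1 - rec$score, 0.001)
    writeLines(sprintf("%d %d 0 %g %.3f", rec$i, rec$j, predictions$cutoff, p), con)
  }
  writeLines("END", con)
  invisible(path)
}

#' Read a CASP RR prediction file
#'
#' @param path Path to an RR file as written by [write_rr()] (or any file
#'   whose record lines are `i j dmin dmax prob`).
#' @return A `prediction_set`; scores are reconstructed as `1 - prob`.
#' @export
read_rr <- function(path) {
  lines <- readLines(path, warn = FALSE)
  chain_id <- NA_character_
  tgt <- grep("^TARGET ", lines, value = TRUE)
  if (length(tgt) > 0) chain_id <- sub("^TARGET ", "", tgt[1])
  body <- grep("^[0-9]+ [0-9]+ ", lines, value = TRUE)
  if (length(body) == 0) {
    rec <- data.frame(i = integer(), j = integer(),
                      score = numeric(), label = integer())
    return(prediction_set(chain_id, rec))
  }
  parts <- do.call(rbind, lapply(strsplit(body, "[[:space:]]+"), as.numeric))
  rec <- data.frame(i = as.integer(parts[, 1]), j = as.integer(parts[, 2]),
                    score = 1 - parts[, 5], label = NA_integer_)
  prediction_set(chain_id, rec, cutoff = parts[1, 4], min_sep = 1)
}
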