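# Fixtures built in code: tiny PDB texts, profile tables and naive
# reference ("oracle") implementations used to cross-check the fast paths.

write_fixture_pdb <- function(coords, path, chain = "A", res = "GLY",
                              skip_ca = integer()) {
  lines <- character()
  serial <- 0L
  for (r in seq_len(nrow(coords))) {
    serial <- serial + 1L
    name <- if (r %in% skip_ca) " N  " else " CA "
    lines <- c(lines, sprintf(
      "ATOM  %5d %s %3s %s%4d    %8.3f%8.3f%8.3f  1.00  0.00           C",
      serial, name, res, chain, r, coords[r, 1], coords[r, 2], coords[r, 3]))
  }
  writeLines(c(lines, "END"), path)
  path
}

uniform_profile <- function(L, value = 0.05, chain_id = "test") {
  structure(list(chain_id = chain_id, L = L,
                 residues = paste(rep("A", L), collapse = ""),
                 matrix = matrix(value, L, 20,
                                 dimnames = list(NULL, aa_order()))),
            class = "profile_matrix")
}

random_profile <- function(L, seed = 1, chain_id = "test") {
  set.seed(seed)
  m <- matrix(stats::runif(L * 20), L, 20, dimnames = list(NULL, aa_order()))
  structure(list(chain_id = chain_id, L = L,
                 residues = paste(sample(aa_order(), L, replace = TRUE),
                                  collapse = ""),
                 matrix = m),
            class = "profile_matrix")
}

# Trace constructed directly from a coordinate matrix.
make_trace <- function(coords, chain_id = "A", missing = rep(FALSE, nrow(coords))) {
  L <- nrow(coords)
  coords[missing, ] <- NA_real_
  structure(list(chain_id = chain_id, residue_numbers = seq_len(L),
                 author_numbers = seq_len(L),
                 residue_names = rep("G", L), coords = coords,
                 missing_mask = missing),
            class = "ca_trace")
}

# Oracle: naive O(L^2) contact scan.
oracle_contacts <- function(coords, missing, cutoff, min_sep) {
  L <- nrow(coords)
  out <- NULL
  for (i in seq_len(L - 1)) {
    for (j in (i + 1):L) {
      if (missing[i] || missing[j]) next
      if (j - i < min_sep) next
      if (sqrt(sum((coords[i, ] - coords[j, ])^2)) <= cutoff)
        out <- rbind(out, c(i, j))
    }
  }
  if (is.null(out)) matrix(integer(), 0, 2) else out
}

# Oracle: single-pass naive chromosome interpreter (independent of
# compile_chromosome): walks the string left to right accumulating runs.
oracle_transform <- function(chromosome, v) {
  ch <- strsplit(chromosome, "")[[1]]
  out <- numeric()
  run_char <- ""
  for (p in seq_along(ch)) {
    if (ch[p] == "a") {
      run_char <- ""
    } else if (ch[p] == run_char) {
      out[length(out)] <- out[length(out)] + v[p]
    } else {
      out <- c(out, v[p])
      run_char <- ch[p]
    }
  }
  s <- sum(out)
  if (length(out) > 0 && s > 0) out / s else out
}

random_chromosome <- function(m) paste(sample(c("a", "b", "c"), m, replace = TRUE),
                                       collapse = "")

# Small trained ensemble on planted data, for IO/prediction tests.
tiny_ensemble <- function(seed = 1, n_gacs = 2, m_noise = 20) {
  d <- planted_separation_dataset(15, 60, 4, m_noise, 1, seed = seed)
  cfg <- ga_config(population_size = 12, stall_generations = 5,
                   max_generations = 12, rng_seed = seed)
  train_ensemble(d$sp[d$labels == 1, ], d$sp[d$labels == 0, ],
                 n_gacs = n_gacs, config = cfg, seed = seed)
}
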