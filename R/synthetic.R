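## Synthetic chains and test harness data.
##
## Chains are compact self-avoiding random walks (3.8 A C-alpha steps,
## excluded volume, confinement sphere). Confinement density controls how
## many geometry-derived long-range contacts appear; the radius scales as
## L^(1/3) so the contact count grows roughly linearly with chain length,
## emulating the observed length/contact-count relationship. Residue
## letters of contact-participating residues are enriched for the
## hydrophobics C/V/I/L and depleted for E/D/K (strength delta), giving
## positive log2 contact propensities for hydrophobics as in real chains.
## Profile rows are Dirichlet draws centered on a blend of the residue's
## identity and its contact-status composition (concentration kappa).

## Confinement radius, calibrated by simulation so the expected
## long-range contact count is ~ slope * L across L in [40, 150] (the
## fraction of residue pairs separated by >= 24 grows with L, so a pure
## L^(1/3) radius would give counts growing faster than L; the log-linear
## multiplier compensates). Contact counts scale roughly as mult^-4, so a
## non-default slope rescales the radius by (SLOPE_CAL/slope)^(1/4).
RADIUS_COEF <- 3.55
SLOPE_CAL <- 1.2
RADIUS_SENS <- 4

walk_radius <- function(L, slope) {
  mult <- min(1.4, max(0.6, -0.365 + 0.30 * log(L)))
  RADIUS_COEF * L^(1 / 3) * mult * (SLOPE_CAL / slope)^(1 / RADIUS_SENS)
}

HYDROPHOBIC_SET <- c("C", "V", "I", "L")
HYDROPHILIC_SET <- c("E", "D", "K")

#' Synthetic dataset configuration
#'
#' @param n_chains Number of chains.
#' @param l_min,l_max Chain length range (uniform; `l_min >= 30`).
#' @param step C-alpha step length in Angstrom (3.8).
#' @param min_dist Excluded-volume minimum distance between non-adjacent
#'   C-alphas, Angstrom.
#' @param slope Target long-range contacts per residue (contacts ~ slope * L).
#' @param delta Hydrophobic enrichment strength for contact residues
#'   (log2 units; 0 disables enrichment).
#' @param kappa Dirichlet concentration of profile rows.
#' @param cutoff,min_sep Contact definition parameters.
#' @param seed Master seed.
#' @return A list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_chains = 30, l_min = 50, l_max = 120,
                             step = 3.8, min_dist = 4.0, slope = 1.2,
                             delta = 0.8, kappa = 40, cutoff = 8,
                             min_sep = 24, seed = 1L) {
  stopifnot(l_min >= 30, l_max >= l_min, delta >= 0, kappa > 0,
            step > 0, min_dist >= 0, slope > 0)
  structure(list(n_chains = as.integer(n_chains), l_min = as.integer(l_min),
                 l_max = as.integer(l_max), step = step, min_dist = min_dist,
                 slope = slope, delta = delta, kappa = kappa,
                 cutoff = cutoff, min_sep = min_sep, seed = as.integer(seed)),
            class = "synthetic_config")
}

## One attempt at a confined self-avoiding walk; NULL on failure.
walk_attempt <- function(L, step, min_dist, radius, max_prop = 80L,
                         max_backtrack = 400L) {
  coords <- matrix(NA_real_, L, 3)
  coords[1, ] <- 0
  i <- 2L
  backtracks <- 0L
  while (i <= L) {
    placed <- FALSE
    for (trial in seq_len(max_prop)) {
      u <- stats::rnorm(3)
      cand <- coords[i - 1L, ] + step * u / sqrt(sum(u^2))
      if (sum(cand^2) > radius^2) next
      if (i > 2L) {
        d2 <- colSums((t(coords[1:(i - 2L), , drop = FALSE]) - cand)^2)
        if (min(d2) < min_dist^2) next
      }
      coords[i, ] <- cand
      placed <- TRUE
      break
    }
    if (placed) {
      i <- i + 1L
    } else {
      backtracks <- backtracks + 1L
      if (backtracks > max_backtrack) return(NULL)
      i <- max(2L, i - 2L)
    }
  }
  coords
}

#' Generate one synthetic chain
#'
#' @param cfg A [synthetic_config()].
#' @param seed Seed for this chain (defaults to the config seed).
#' @param L Optional fixed length (default: uniform in the config range).
#' @return List with `trace` (`ca_trace`) and `profile`
#'   (`profile_matrix`).
#' @export
generate_chain <- function(cfg, seed = cfg$seed, L = NULL) {
  with_seed(seed, {
    if (is.null(L)) {
      lens <- cfg$l_min:cfg$l_max
      L <- lens[sample.int(length(lens), 1L)]
    }
    radius <- walk_radius(L, cfg$slope)
    coords <- NULL
    for (restart in 1:25) {
      coords <- walk_attempt(L, cfg$step, cfg$min_dist, radius)
      if (!is.null(coords)) break
    }
    if (is.null(coords))
      stop_gac("random walk failed to place %d residues after retries", L)

    trace <- structure(list(chain_id = "A", residue_numbers = seq_len(L),
                            author_numbers = seq_len(L),
                            residue_names = rep("G", L), coords = coords,
                            missing_mask = rep(FALSE, L)),
                       class = "ca_trace")
    cm <- build_contact_map(trace, cfg$cutoff, cfg$min_sep)
    in_contact <- rep(FALSE, L)
    if (nrow(cm$contact_pairs) > 0) in_contact[unique(c(cm$contact_pairs))] <- TRUE

    w_contact <- rep(1, 20); names(w_contact) <- AA_ORDER
    w_contact[HYDROPHOBIC_SET] <- 2^cfg$delta
    w_contact[HYDROPHILIC_SET] <- 2^(-cfg$delta)
    q_contact <- w_contact / sum(w_contact)
    q_plain <- rep(1 / 20, 20); names(q_plain) <- AA_ORDER

    letters <- character(L)
    letters[in_contact] <- sample(AA_ORDER, sum(in_contact), replace = TRUE,
                                  prob = q_contact)
    letters[!in_contact] <- sample(AA_ORDER, sum(!in_contact), replace = TRUE,
                                   prob = q_plain)
    trace$residue_names <- letters

    prof <- matrix(0, L, 20, dimnames = list(NULL, AA_ORDER))
    for (r in seq_len(L)) {
      onehot <- 0.8 * (AA_ORDER == letters[r]) + 0.2 / 20
      q <- if (in_contact[r]) q_contact else q_plain
      p <- 0.5 * onehot + 0.5 * q
      g <- stats::rgamma(20, shape = cfg$kappa * p)
      prof[r, ] <- g / sum(g)
    }
    profile <- structure(list(chain_id = "A", L = L,
                              residues = paste(letters, collapse = ""),
                              matrix = prof),
                         class = "profile_matrix")
    list(trace = trace, profile = profile)
  })
}

#' Generate a full synthetic dataset
#'
#' Applies [generate_chain()] `n_chains` times with derived seeds and
#' attaches contact maps and labeled long-range pairs.
#'
#' @param cfg A [synthetic_config()].
#' @return Named list (`chain001`, ...) of chains, each with `trace`,
#'   `profile`, `cm` and `pairs`.
#' @export
generate_dataset <- function(cfg) {
  out <- list()
  for (k in seq_len(cfg$n_chains)) {
    id <- sprintf("chain%03d", k)
    ch <- generate_chain(cfg, seed = derive_seed(cfg$seed, k))
    ch$trace$chain_id <- "A"
    ch$cm <- build_contact_map(ch$trace, cfg$cutoff, cfg$min_sep)
    ch$cm$chain_id <- id
    ch$pairs <- label_long_range_pairs(ch$cm)
    ch$id <- id
    out[[id]] <- ch
  }
  out
}

#' Planted-separation vector set for GA tests
#'
#' Class means differ by `separation` on the informative dimensions only:
#' class 1 is elevated on the odd-indexed informative dimensions and class
#' 0 on the even-indexed ones (a shape difference, so L1 normalization
#' cannot erase it). Noise dimensions are i.i.d. exponential with unit
#' mean, identically distributed across classes; their draw-to-draw
#' variation is what makes chromosomes that keep them classify worse.
#' Vectors are L1-normalized.
#'
#' @param n_pos,n_neg Samples per class.
#' @param n_informative,n_noise Dimension counts.
#' @param separation Class-mean offset on informative dimensions (base
#'   level is 1). The default 1 makes the classes perfectly separable by
#'   a transformation that drops the noise dimensions while leaving a
#'   typical random transformation imperfect, so evolving toward noise
#'   removal is rewarded.
#' @param seed RNG seed.
#' @return List with `sp` (matrix) and `labels` (0/1), plus
#'   `informative_dims` and `noise_dims` index vectors.
#' @export
planted_separation_dataset <- function(n_pos, n_neg, n_informative, n_noise,
                                       separation = 1, seed = 1L) {
  stopifnot(n_informative + n_noise >= 1)
  with_seed(seed, {
    n <- n_pos + n_neg
    labels <- c(rep(1L, n_pos), rep(0L, n_neg))
    m <- n_informative + n_noise
    sp <- matrix(0, n, m)
    if (n_informative > 0) {
      inf_means <- matrix(1, 2, n_informative)
      odd <- seq(1, n_informative, by = 2)
      evn <- setdiff(seq_len(n_informative), odd)
      inf_means[1, odd] <- 1 + separation        # class 1
      if (length(evn) > 0) inf_means[2, evn] <- 1 + separation  # class 0
      sp[, seq_len(n_informative)] <- inf_means[2 - labels, , drop = FALSE]
    }
    if (n_noise > 0) {
      sp[, n_informative + seq_len(n_noise)] <-
        matrix(stats::rexp(n * n_noise), n, n_noise)
    }
    list(sp = l1_normalize_rows(sp), labels = labels,
         informative_dims = seq_len(n_informative),
         noise_dims = n_informative + seq_len(n_noise))
  })
}
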