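## Genetic-algorithm classifier (GaC) core.
##
## A chromosome is a string over {a, b, c} of the feature dimension:
##   * 'a'  — the feature at that position is removed;
##   * maximal runs of identical 'b's or 'c's — the features of the run
##     are merged (summed) into one output feature. Runs are evaluated on
##     the ORIGINAL string: an 'a' or a character change breaks a run, so
##     "cbbabcca" on 8 features removes {4, 8} and yields the 4 groups
##     [1], [2,3], [5], [6,7].
##
## Transformed vectors are L1-normalized. Fitness of a chromosome on a
## labeled sample set is the number of samples whose nearest transformed
## class centroid (Euclidean) matches their true class; it is maximal when
## the imposed class structure coincides with the true one.

CHROM_ALPHABET <- c("a", "b", "c")

chrom_to_int <- function(s) {
  v <- match(strsplit(s, "")[[1]], CHROM_ALPHABET)
  if (anyNA(v)) stop_gac("illegal chromosome character (alphabet is a/b/c)")
  v
}

int_to_chrom <- function(v) paste(CHROM_ALPHABET[v], collapse = "")

#' GA configuration
#'
#' Default training protocol: 150 individuals, top
#' 5% elitism, single-point crossover with probability 0.95, per-position
#' mutation probability 0.01, roulette-wheel selection, and termination
#' when the best fitness has not changed for 120 generations. A hard
#' generation cap guarantees termination.
#'
#' @param population_size Number of chromosomes per generation.
#' @param elite_fraction Fraction copied unchanged to the next generation.
#' @param crossover_prob Probability a selected parent pair is recombined.
#' @param mutation_prob Per-position mutation probability.
#' @param stall_generations Stop after this many generations without
#'   improvement of the best fitness.
#' @param max_generations Hard cap on generations.
#' @param rng_seed Seed making the run reproducible.
#' @return A list of class `ga_config`.
#' @export
ga_config <- function(population_size = 150, elite_fraction = 0.05,
                      crossover_prob = 0.95, mutation_prob = 0.01,
                      stall_generations = 120, max_generations = 2000,
                      rng_seed = 1L) {
  stopifnot(population_size >= 2,
            elite_fraction >= 0, elite_fraction <= 1,
            crossover_prob >= 0, crossover_prob <= 1,
            mutation_prob >= 0, mutation_prob <= 1,
            stall_generations >= 1, max_generations >= 1)
  structure(list(population_size = as.integer(population_size),
                 elite_fraction = elite_fraction,
                 crossover_prob = crossover_prob,
                 mutation_prob = mutation_prob,
                 stall_generations = as.integer(stall_generations),
                 max_generations = as.integer(max_generations),
                 rng_seed = as.integer(rng_seed)),
            class = "ga_config")
}

#' Compile a chromosome into a feature transformation
#'
#' @param chromosome A string over \{a, b, c\}.
#' @return An object of class `ga_transform`: list with `chromosome`, `m`
#'   (input dimension), `removed` (indices marked 'a'), `groups` (list of
#'   index vectors, singletons for kept features, runs for merges) and
#'   `map` (m x n_groups 0/1 matrix so that transformed = v %*% map).
#' @export
compile_chromosome <- function(chromosome) {
  v <- chrom_to_int(chromosome)
  m <- length(v)
  r <- rle(v)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values != 1L
  groups <- mapply(function(s, e) s:e, starts[keep], ends[keep], SIMPLIFY = FALSE)
  removed <- which(v == 1L)
  g <- length(groups)
  map <- matrix(0, m, g)
  if (g > 0) {
    map[cbind(unlist(groups), rep.int(seq_len(g), lengths(groups)))] <- 1
  }
  structure(list(chromosome = chromosome, m = m, removed = removed,
                 groups = groups, map = map),
            class = "ga_transform")
}

#' Fraction of input features discarded by a transformation
#'
#' `(removed + merged-away) / m`: positions marked 'a' plus the reduction
#' from merging (each k-feature group collapses k features into one).
#'
#' @param transform A `ga_transform`.
#' @return Numeric in \[0, 1\].
#' @export
discard_ratio <- function(transform) {
  merged_away <- sum(lengths(transform$groups)) - length(transform$groups)
  (length(transform$removed) + merged_away) / transform$m
}

#' Apply a transformation to SP vectors
#'
#' Each group emits the sum of its members; the result is L1-normalized
#' (an all-zero pre-normalization output stays all-zero).
#'
#' @param transform A `ga_transform`.
#' @param v A numeric vector of length m, or an n x m matrix of rows.
#' @return Transformed vector (or matrix with one row per input row) of
#'   dimension `length(transform$groups)`.
#' @export
apply_transformation <- function(transform, v) {
  if (is.matrix(v)) {
    if (ncol(v) != transform$m)
      stop_gac("dimension mismatch: vectors have %d columns, chromosome has %d", ncol(v), transform$m)
    return(l1_normalize_rows(v %*% transform$map))
  }
  if (length(v) != transform$m)
    stop_gac("dimension mismatch: vector length %d, chromosome length %d", length(v), transform$m)
  l1_normalize(drop(v %*% transform$map))
}

#' Transformed class centroids
#'
#' Per class, the mean of the transformed training vectors.
#'
#' @param transform A `ga_transform`.
#' @param sp Training SP matrix (rows = samples).
#' @param labels 0/1 labels.
#' @return List with `c1` and `c0`, the transformed centroids.
#' @export
centroid_functions <- function(transform, sp, labels) {
  if (!any(labels == 1) || !any(labels == 0))
    stop_gac("empty class: both classes must be present to form centroids")
  tv <- apply_transformation(transform, sp)
  list(c1 = colMeans(tv[labels == 1, , drop = FALSE]),
       c0 = colMeans(tv[labels == 0, , drop = FALSE]))
}

#' Nearest-centroid class assignment
#'
#' Assigns the class of the nearer centroid under Euclidean distance in
#' the transformed space; exact ties go to class 0 (conservative).
#'
#' @param transform A `ga_transform`.
#' @param x Raw SP vector (length m) or n x m matrix.
#' @param c1,c0 Transformed centroids.
#' @return Integer 0/1 (vector for matrix input).
#' @export
assign_nearest_centroid <- function(transform, x, c1, c0) {
  tx <- apply_transformation(transform, x)
  if (!is.matrix(tx)) tx <- matrix(tx, 1)
  d1 <- rowSums((tx - matrix(c1, nrow(tx), length(c1), byrow = TRUE))^2)
  d0 <- rowSums((tx - matrix(c0, nrow(tx), length(c0), byrow = TRUE))^2)
  as.integer(d1 < d0)
}

## Row-wise cumulative sums with a leading zero column: group sums over a
## contiguous run [s, e] are then CS[, e+1] - CS[, s], which lets fitness
## evaluate a chromosome by column differencing instead of a matrix
## product. Computed once per GA run.
make_rowcumsum <- function(sp) {
  m <- ncol(sp)
  U <- matrix(0, m, m)
  U[upper.tri(U, diag = TRUE)] <- 1
  cbind(0, sp %*% U)
}

## Fast internal fitness: chromosome as an integer vector, samples as the
## precomputed cumulative-sum matrix.
fitness_cs <- function(chrom_int, CS, labels) {
  r <- rle(chrom_int)
  gkeep <- r$values != 1L
  if (!any(gkeep)) return(0L)  # all-'a': empty transformation scores 0
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  tv <- CS[, ends[gkeep] + 1L, drop = FALSE] - CS[, starts[gkeep], drop = FALSE]
  rs <- rowSums(tv)
  nz <- rs > 0
  tv[nz, ] <- tv[nz, , drop = FALSE] / rs[nz]
  c1 <- colMeans(tv[labels == 1L, , drop = FALSE])
  c0 <- colMeans(tv[labels == 0L, , drop = FALSE])
  ## d1 < d0  <=>  2 x.(c1-c0) > |c1|^2 - |c0|^2  (ties -> class 0)
  score <- 2 * (tv %*% (c1 - c0)) - (sum(c1^2) - sum(c0^2))
  pred <- as.integer(score > 0)
  sum(pred == labels)
}

fitness_int <- function(chrom_int, sp, labels) {
  fitness_cs(chrom_int, make_rowcumsum(sp), labels)
}

#' Fitness of a chromosome on a labeled sample set
#'
#' Compiles the chromosome, forms transformed centroids from the same
#' samples, and counts how many samples the nearest-centroid rule assigns
#' to their true class. An all-'a' chromosome scores 0 by convention.
#'
#' @param chromosome Chromosome string.
#' @param sp Sample matrix (rows = SP vectors).
#' @param labels 0/1 labels.
#' @return Integer in `[0, nrow(sp)]`.
#' @export
ga_fitness <- function(chromosome, sp, labels) {
  if (!any(labels == 1) || !any(labels == 0))
    stop_gac("fitness requires both classes in the sample set")
  fitness_int(chrom_to_int(chromosome), sp, labels)
}

#' Single-point crossover
#'
#' Cuts both parents at a position uniform in 1..m-1 and swaps suffixes.
#'
#' @param p1,p2 Parent chromosome strings of equal length.
#' @return List of two child chromosome strings.
#' @export
crossover_single_point <- function(p1, p2) {
  a <- chrom_to_int(p1); b <- chrom_to_int(p2)
  if (length(a) != length(b)) stop_gac("parents must have equal length")
  m <- length(a)
  cut <- sample.int(m - 1L, 1L)
  list(int_to_chrom(c(a[1:cut], b[(cut + 1L):m])),
       int_to_chrom(c(b[1:cut], a[(cut + 1L):m])))
}

#' Per-position mutation
#'
#' Each position is independently replaced, with probability `prob`, by a
#' uniformly chosen different character.
#'
#' @param chromosome Chromosome string.
#' @param prob Per-position mutation probability.
#' @return Mutated chromosome string.
#' @export
mutate_chromosome <- function(chromosome, prob) {
  v <- chrom_to_int(chromosome)
  int_to_chrom(mutate_int(v, prob))
}

mutate_int <- function(v, prob) {
  hit <- which(stats::runif(length(v)) < prob)
  if (length(hit) > 0) {
    ## add 1 or 2 mod 3 -> uniformly one of the two other characters
    v[hit] <- ((v[hit] - 1L + sample.int(2L, length(hit), replace = TRUE)) %% 3L) + 1L
  }
  v
}

#' Roulette-wheel selection
#'
#' Samples one population index with probability proportional to fitness;
#' if all fitnesses are zero, selection is uniform.
#'
#' @param fitnesses Non-negative fitness values.
#' @param n Number of indices to draw (with replacement).
#' @return Integer indices into the population.
#' @export
roulette_select <- function(fitnesses, n = 1L) {
  if (any(fitnesses < 0)) stop_gac("fitnesses must be non-negative")
  if (all(fitnesses == 0)) fitnesses <- rep(1, length(fitnesses))
  sample.int(length(fitnesses), n, replace = TRUE, prob = fitnesses)
}

#' Run the genetic algorithm
#'
#' Evolves a population of chromosomes over the sample set: elites (top
#' `elite_fraction`) are copied unchanged; the remainder of the next
#' generation is produced by roulette-selected parents undergoing
#' single-point crossover (with probability `crossover_prob`) and
#' per-position mutation. Terminates when the best fitness has not changed
#' for `stall_generations` generations or at `max_generations`.
#'
#' @param sp Training SP matrix.
#' @param labels 0/1 labels (both classes required).
#' @param config A [ga_config()].
#' @return List with `best_chromosome`, `best_fitness`, `n_generations`
#'   and `history` (data frame: generation, best, mean, best_chromosome).
#' @export
run_ga <- function(sp, labels, config = ga_config()) {
  if (!any(labels == 1) || !any(labels == 0))
    stop_gac("run_ga requires both classes in the sample set")
  m <- ncol(sp)
  CS <- make_rowcumsum(sp)
  with_seed(config$rng_seed, {
    npop <- config$population_size
    pop <- matrix(sample.int(3L, npop * m, replace = TRUE), npop, m)
    n_elite <- max(1L, ceiling(config$elite_fraction * npop))
    best_fit <- -1L
    best_chrom <- NULL
    stall <- 0L
    hist_gen <- integer(); hist_best <- integer(); hist_mean <- numeric()
    hist_chrom <- character()
    gen <- 0L
    fit <- rep(NA_integer_, npop)  # elites keep their cached fitness
    repeat {
      gen <- gen + 1L
      todo <- which(is.na(fit))
      fit[todo] <- vapply(todo, function(k) fitness_cs(pop[k, ], CS, labels), 0L)
      top <- which.max(fit)
      if (fit[top] > best_fit) {
        best_fit <- fit[top]
        best_chrom <- pop[top, ]
        stall <- 0L
      } else {
        stall <- stall + 1L
      }
      hist_gen[gen] <- gen; hist_best[gen] <- best_fit
      hist_mean[gen] <- mean(fit); hist_chrom[gen] <- int_to_chrom(best_chrom)
      if (stall >= config$stall_generations || gen >= config$max_generations) break

      elite_idx <- order(fit, decreasing = TRUE)[seq_len(n_elite)]
      children <- matrix(0L, npop, m)
      children[seq_len(n_elite), ] <- pop[elite_idx, ]
      new_fit <- rep(NA_integer_, npop)
      new_fit[seq_len(n_elite)] <- fit[elite_idx]
      filled <- n_elite
      while (filled < npop) {
        par <- roulette_select(fit, 2L)
        c1 <- pop[par[1], ]; c2 <- pop[par[2], ]
        if (stats::runif(1) < config$crossover_prob) {
          cut <- sample.int(m - 1L, 1L)
          tmp <- c1[(cut + 1L):m]
          c1[(cut + 1L):m] <- c2[(cut + 1L):m]
          c2[(cut + 1L):m] <- tmp
        }
        c1 <- mutate_int(c1, config$mutation_prob)
        filled <- filled + 1L
        children[filled, ] <- c1
        if (filled < npop) {
          c2 <- mutate_int(c2, config$mutation_prob)
          filled <- filled + 1L
          children[filled, ] <- c2
        }
      }
      pop <- children
      fit <- new_fit
    }
    list(best_chromosome = int_to_chrom(best_chrom),
         best_fitness = best_fit,
         n_generations = gen,
         history = data.frame(generation = hist_gen, best = hist_best,
                              mean = hist_mean, best_chromosome = hist_chrom,
                              stringsAsFactors = FALSE))
  })
}
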