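## Undersampling ensemble of GaCs.
##
## Long-range non-contacts vastly outnumber contacts, so the negatives are
## split into disjoint random subsets of roughly positive-set size; each
## GaC trains on (all positives, one negative subset). Each GaC holds two
## GA-evolved sub-classifiers (one per target class, independent seeds);
## the contact-class sub-classifier's nearest-centroid rule provides the
## GaC's label, and its centroid-distance ratio provides a ranking score.
## The default ensemble label uses an OR rule: positive if at least
## one GaC votes positive ("any_positive"); a majority alternative is
## available.

#' Partition negatives into disjoint balanced subsets
#'
#' Draws `n_subsets` pairwise-disjoint random subsets of the negative
#' sample indices, each of size `min(subset_size, floor(n/n_subsets))`.
#'
#' @param n_negatives Number of negative samples.
#' @param n_subsets Number of subsets (one per GaC).
#' @param subset_size Target size, conventionally the positive-set size.
#' @param seed RNG seed.
#' @return List of `n_subsets` integer index vectors.
#' @export
partition_negatives <- function(n_negatives, n_subsets, subset_size, seed = 1L) {
  if (n_negatives < n_subsets)
    stop_gac("insufficient negatives: %d for %d subsets", n_negatives, n_subsets)
  size <- min(subset_size, n_negatives %/% n_subsets)
  with_seed(seed, {
    perm <- sample.int(n_negatives)
    lapply(seq_len(n_subsets), function(k) sort(perm[((k - 1L) * size + 1L):(k * size)]))
  })
}

#' Train one GaC on a positive set and a negative subset
#'
#' Runs the GA twice with independent derived seeds to evolve the two
#' sub-classifiers (target class 1 and target class 0); each stores its
#' compiled transformation and the transformed centroids of the training
#' pair.
#'
#' @param sp_pos,sp_neg Matrices of positive / negative SP vectors.
#' @param config A [ga_config()]; its `rng_seed` is the GaC's base seed.
#' @param subset_id Identifier of the negative subset (metadata).
#' @return An object of class `gac_model` with elements `sub1`, `sub0`,
#'   `subset_id` and `seed`.
#' @export
train_gac <- function(sp_pos, sp_neg, config = ga_config(), subset_id = NA_integer_) {
  if (nrow(sp_pos) == 0 || nrow(sp_neg) == 0)
    stop_gac("train_gac requires non-empty positive and negative sets")
  sp <- rbind(sp_pos, sp_neg)
  labels <- c(rep(1L, nrow(sp_pos)), rep(0L, nrow(sp_neg)))
  subs <- lapply(c(1L, 0L), function(k) {
    cfg <- config
    cfg$rng_seed <- derive_seed(config$rng_seed, k)
    res <- run_ga(sp, labels, cfg)
    tr <- compile_chromosome(res$best_chromosome)
    cen <- centroid_functions(tr, sp, labels)
    list(target_class = k, chromosome = res$best_chromosome,
         transform = tr, c1 = cen$c1, c0 = cen$c0,
         fitness = res$best_fitness, history = res$history)
  })
  structure(list(sub1 = subs[[1]], sub0 = subs[[2]],
                 subset_id = subset_id, seed = config$rng_seed,
                 n_train = nrow(sp)),
            class = "gac_model")
}

#' Label SP vectors with one GaC
#'
#' Default rule: the class-1 sub-classifier's nearest-centroid assignment.
#' Rule `"agreement"`: positive only if both sub-classifiers assign
#' class 1.
#'
#' @param model A `gac_model`.
#' @param x SP vector or matrix of rows.
#' @param rule `"sub1"` (default) or `"agreement"`.
#' @return Integer 0/1 labels.
#' @export
gac_label <- function(model, x, rule = c("sub1", "agreement")) {
  rule <- match.arg(rule)
  a1 <- assign_nearest_centroid(model$sub1$transform, x, model$sub1$c1, model$sub1$c0)
  if (rule == "sub1") return(a1)
  a0 <- assign_nearest_centroid(model$sub0$transform, x, model$sub0$c1, model$sub0$c0)
  as.integer(a1 == 1L & a0 == 1L)
}

## Per-GaC ranking score d1/(d1+d0) in the class-1 sub-classifier's
## transformed space; lower = more contact-like; 0.5 when both distances
## vanish. Dimensionless, hence comparable across GaCs with transformed
## spaces of different dimension.
gac_score <- function(model, x) {
  tx <- apply_transformation(model$sub1$transform, x)
  if (!is.matrix(tx)) tx <- matrix(tx, 1)
  c1 <- model$sub1$c1; c0 <- model$sub1$c0
  d1 <- sqrt(rowSums((tx - matrix(c1, nrow(tx), length(c1), byrow = TRUE))^2))
  d0 <- sqrt(rowSums((tx - matrix(c0, nrow(tx), length(c0), byrow = TRUE))^2))
  tot <- d1 + d0
  s <- rep(0.5, length(d1))
  s[tot > 0] <- d1[tot > 0] / tot[tot > 0]
  s
}

#' Train a GaC ensemble
#'
#' Partitions the negatives into disjoint balanced subsets and trains one
#' GaC per subset with deterministically derived seeds.
#'
#' @param sp_pos,sp_neg Positive / negative SP matrices.
#' @param n_gacs Number of GaCs (default 20).
#' @param config A [ga_config()].
#' @param seed Master seed; all child seeds derive from it.
#' @param vote_rule `"any_positive"` (default) or
#'   `"majority"`.
#' @return An object of class `gac_ensemble`.
#' @export
train_ensemble <- function(sp_pos, sp_neg, n_gacs = 20, config = ga_config(),
                           seed = 1L, vote_rule = c("any_positive", "majority")) {
  vote_rule <- match.arg(vote_rule)
  subsets <- partition_negatives(nrow(sp_neg), n_gacs, nrow(sp_pos),
                                 seed = derive_seed(seed, 0L))
  gacs <- lapply(seq_len(n_gacs), function(g) {
    cfg <- config
    cfg$rng_seed <- derive_seed(seed, g)
    train_gac(sp_pos, sp_neg[subsets[[g]], , drop = FALSE], cfg, subset_id = g)
  })
  structure(list(gacs = gacs, vote_rule = vote_rule, seed = seed,
                 n_features = ncol(sp_pos), config = config,
                 test_spc = NULL),
            class = "gac_ensemble")
}

#' Ensemble label by voting
#'
#' `any_positive`: positive iff at least one GaC labels positive (the
#' default rule). `majority`: positive iff more than half do.
#'
#' @param ensemble A `gac_ensemble`.
#' @param x SP vector or matrix.
#' @param vote_rule Override of the ensemble's stored rule.
#' @return Integer 0/1 labels.
#' @export
ensemble_label <- function(ensemble, x, vote_rule = NULL) {
  rule <- if (is.null(vote_rule)) ensemble$vote_rule else
    match.arg(vote_rule, c("any_positive", "majority"))
  votes <- vapply(ensemble$gacs, function(g) gac_label(g, x),
                  integer(if (is.matrix(x)) nrow(x) else 1L))
  if (!is.matrix(votes)) votes <- matrix(votes, 1)
  n_pos <- rowSums(votes)
  if (rule == "any_positive") as.integer(n_pos >= 1L)
  else as.integer(n_pos > length(ensemble$gacs) / 2)
}

#' Ensemble contact score
#'
#' Mean over GaCs of the centroid-distance ratio `d1/(d1+d0)`; lower
#' scores are more contact-like, so ranking ascending orders pairs by
#' predicted closeness to the contact center.
#'
#' @param ensemble A `gac_ensemble`.
#' @param x SP vector or matrix.
#' @return Numeric scores in \[0, 1\].
#' @export
ensemble_score <- function(ensemble, x) {
  s <- vapply(ensemble$gacs, function(g) gac_score(g, x),
              numeric(if (is.matrix(x)) nrow(x) else 1L))
  if (!is.matrix(s)) s <- matrix(s, 1)
  rowMeans(s)
}

#' Random chain-level two-fold split
#'
#' @param chain_ids Character vector of chain identifiers (>= 2).
#' @param seed RNG seed.
#' @return List with elements `a` and `b`, disjoint, sizes differing by at
#'   most one.
#' @export
two_fold_split <- function(chain_ids, seed = 1L) {
  n <- length(chain_ids)
  if (n < 2) stop_gac("two-fold split needs at least 2 chains")
  with_seed(seed, {
    perm <- sample(chain_ids)
    half <- ceiling(n / 2)
    list(a = sort(perm[seq_len(half)]), b = sort(perm[(half + 1L):n]))
  })
}

## Encode and pool the labeled long-range pairs of a set of chains.
pool_training_pairs <- function(dataset, chain_ids, w_flank, w_mid,
                                max_pos_per_chain = Inf) {
  pos <- list(); neg <- list()
  for (id in chain_ids) {
    ch <- dataset[[id]]
    lp <- ch$pairs
    if (nrow(lp) == 0) next
    p <- lp[lp$label == 1, , drop = FALSE]
    if (is.finite(max_pos_per_chain) && nrow(p) > max_pos_per_chain)
      p <- p[seq_len(max_pos_per_chain), , drop = FALSE]
    n <- lp[lp$label == 0, , drop = FALSE]
    if (nrow(p) > 0)
      pos[[id]] <- encode_pairs(ch$profile, p[, c("i", "j")], w_flank, w_mid)
    if (nrow(n) > 0)
      neg[[id]] <- encode_pairs(ch$profile, n[, c("i", "j")], w_flank, w_mid)
  }
  list(pos = do.call(rbind, pos), neg = do.call(rbind, neg))
}

#' Two-fold cross-validation of the full pipeline
#'
#' Splits chains into two folds; for each fold, trains an ensemble on the
#' other fold's pooled pairs, records the pooled test SPCs (mean of the
#' training chains' per-chain centers), then scores and labels every
#' long-range pair of each test chain.
#'
#' @param dataset Named list of chains; each element needs `profile`
#'   (`profile_matrix`), `cm` (`contact_map`) and `pairs` (labeled pairs
#'   from [label_long_range_pairs()]).
#' @param n_gacs Ensemble size.
#' @param config A [ga_config()].
#' @param seed Master seed.
#' @param w_flank,w_mid Encoder window widths.
#' @param fractions Top-K levels for the per-chain reports.
#' @param max_pos_per_chain Optional cap on positives pooled per training
#'   chain (runtime control for large simulations).
#' @return List with `predictions` (named list of `prediction_set`),
#'   `reports` (named list of top-K reports), `folds`, and `models` (one
#'   `gac_ensemble` per fold).
#' @export
run_cross_validation <- function(dataset, n_gacs = 20, config = ga_config(),
                                 seed = 1L, w_flank = 9, w_mid = 5,
                                 fractions = c(2, 1, 0.5, 0.2, 0.1, 0.05),
                                 max_pos_per_chain = Inf) {
  ids <- names(dataset)
  folds <- two_fold_split(ids, seed = derive_seed(seed, 99L))
  models <- list()
  predictions <- list()
  reports <- list()
  for (f in 1:2) {
    train_ids <- if (f == 1) folds$a else folds$b
    test_ids <- if (f == 1) folds$b else folds$a
    stopifnot(length(intersect(train_ids, test_ids)) == 0)  # fold separation
    pooled <- pool_training_pairs(dataset, train_ids, w_flank, w_mid,
                                  max_pos_per_chain)
    if (is.null(pooled$pos) || is.null(pooled$neg))
      stop_gac("training fold %d lacks a class", f)
    ens <- train_ensemble(pooled$pos, pooled$neg, n_gacs = n_gacs,
                          config = config, seed = derive_seed(seed, f))
    ens$test_spc <- pooled_test_spc(dataset, train_ids, w_flank, w_mid)
    models[[f]] <- ens
    for (id in test_ids) {
      ch <- dataset[[id]]
      ps <- predict_chain(ens, ch$profile, min_sep = ch$cm$min_sep,
                          cutoff = ch$cm$cutoff, w_flank = w_flank,
                          w_mid = w_mid)
      predictions[[id]] <- ps
      reports[[id]] <- topk_accuracy_levels(ps$records, ch$cm, fractions)
    }
  }
  list(predictions = predictions, reports = reports, folds = folds,
       models = models)
}

## Pooled test-time SPCs: mean over training chains of per-chain centers.
## Chains lacking a class (e.g. zero contacts) are excluded from that
## class's average.
pooled_test_spc <- function(dataset, train_ids, w_flank, w_mid) {
  per_chain <- list(c1 = list(), c0 = list())
  for (id in train_ids) {
    ch <- dataset[[id]]
    lp <- ch$pairs
    if (nrow(lp) == 0) next
    sp <- encode_pairs(ch$profile, lp[, c("i", "j")], w_flank, w_mid)
    if (any(lp$label == 1))
      per_chain$c1[[id]] <- spc_per_chain(sp, lp$label, 1L, chain_id = id)
    if (any(lp$label == 0))
      per_chain$c0[[id]] <- spc_per_chain(sp, lp$label, 0L, chain_id = id)
  }
  list(c1 = spc_for_test(unname(per_chain$c1), 1L),
       c0 = spc_for_test(unname(per_chain$c0), 0L))
}

#' Score and label every long-range pair of a chain
#'
#' @param ensemble A trained `gac_ensemble`.
#' @param profile The chain's `profile_matrix`.
#' @param min_sep,cutoff Pair definition parameters.
#' @param w_flank,w_mid Encoder windows (must match training).
#' @return A `prediction_set` with records ranked most contact-like first
#'   (ascending score, ties by (i, j)).
#' @export
predict_chain <- function(ensemble, profile, min_sep = 24, cutoff = 8,
                          w_flank = 9, w_mid = 5) {
  pairs <- enumerate_long_range_pairs(profile$L, min_sep)
  if (nrow(pairs) == 0) {
    warning(sprintf("chain %s shorter than min_sep+1: no long-range pairs",
                    profile$chain_id))
    rec <- data.frame(i = integer(), j = integer(), score = numeric(),
                      label = integer())
    return(prediction_set(profile$chain_id, rec, cutoff, min_sep))
  }
  sp <- encode_pairs(profile, pairs, w_flank, w_mid)
  if (ncol(sp) != ensemble$n_features)
    stop_gac("dimension mismatch: model expects %d features, encoding gives %d",
             ensemble$n_features, ncol(sp))
  rec <- data.frame(i = pairs[, 1], j = pairs[, 2],
                    score = ensemble_score(ensemble, sp),
                    label = ensemble_label(ensemble, sp))
  rec <- rec[order(rec$score, rec$i, rec$j), ]
  rownames(rec) <- NULL
  prediction_set(profile$chain_id, rec, cutoff, min_sep,
                 model_id = sprintf("ensemble-%d", ensemble$seed))
}
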