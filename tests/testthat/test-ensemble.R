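test_that("negative partition gives disjoint balanced subsets", {
  subs <- partition_negatives(100, 5, 20, seed = 1)
  expect_length(subs, 5)
  expect_true(all(lengths(subs) == 20))
  expect_equal(length(unique(unlist(subs))), 100)

  subs2 <- partition_negatives(30, 5, 20, seed = 1)
  expect_true(all(lengths(subs2) == 6))  # capped at floor(30/5)

  expect_error(partition_negatives(4, 5, 20), "insufficient negatives")

  # property over random draws: no duplicates, all within range
  for (s in 1:100) {
    n <- sample(25:200, 1); k <- sample(2:8, 1)
    subs <- partition_negatives(n, k, sample(5:50, 1), seed = s)
    u <- unlist(subs)
    expect_equal(anyDuplicated(u), 0)
    expect_true(all(u >= 1 & u <= n))
  }
})

test_that("train_gac evolves two sub-classifiers deterministically", {
  d <- planted_separation_dataset(15, 15, 4, 8, 2, seed = 2)
  cfg <- ga_config(population_size = 15, stall_generations = 6,
                   max_generations = 25, rng_seed = 7)
  g1 <- train_gac(d$sp[d$labels == 1, ], d$sp[d$labels == 0, ], cfg)
  g2 <- train_gac(d$sp[d$labels == 1, ], d$sp[d$labels == 0, ], cfg)
  expect_identical(g1$sub1$chromosome, g2$sub1$chromosome)
  expect_identical(g1$sub0$chromosome, g2$sub0$chromosome)

  # clearly separable data: both sub-classifiers reach maximal fitness
  expect_equal(g1$sub1$fitness, 30)
  expect_equal(g1$sub0$fitness, 30)

  # identical vectors with opposite labels: ties go to class 0, so at
  # most the negatives can be classified correctly
  sp <- matrix(runif(10), 5, 10, byrow = TRUE); sp <- sp / rowSums(sp)
  same <- rbind(sp, sp)
  g3 <- train_gac(same[1:5, ], same[6:10, ],
                  ga_config(population_size = 8, stall_generations = 3,
                            max_generations = 6, rng_seed = 1))
  expect_s3_class(g3, "gac_model")
  expect_lte(g3$sub1$fitness, 5)
})

test_that("gac_label follows the class-1 sub-classifier", {
  ens <- tiny_ensemble(seed = 3)
  g <- ens$gacs[[1]]
  set.seed(4)
  x <- matrix(runif(40 * ens$n_features), 40); x <- x / rowSums(x)
  got <- gac_label(g, x)
  oracle <- assign_nearest_centroid(g$sub1$transform, x, g$sub1$c1, g$sub1$c0)
  expect_equal(got, oracle)
  # agreement rule is at most as positive as the default rule
  agree <- gac_label(g, x, rule = "agreement")
  expect_true(all(agree <= got))
})

test_that("ensemble voting: any_positive is the OR rule, majority stricter", {
  # hand-built GaCs with identity transform and fixed centroids
  mk_gac <- function(c1, c0) {
    tr <- compile_chromosome(paste(rep(c("b", "c"), 2), collapse = ""))
    sub <- list(target_class = 1L, chromosome = tr$chromosome, transform = tr,
                c1 = c1, c0 = c0, fitness = 0L, history = NULL)
    structure(list(sub1 = sub, sub0 = sub, subset_id = 1L, seed = 1L,
                   n_train = 0L), class = "gac_model")
  }
  near1 <- c(0.7, 0.1, 0.1, 0.1); near0 <- c(0.1, 0.7, 0.1, 0.1)
  # one GaC votes positive for x near near1; two GaCs never do
  g_yes <- mk_gac(near1, near0)
  g_no <- mk_gac(c(0, 0, 0.5, 0.5), near0)
  ens <- structure(list(gacs = list(g_yes, g_no, g_no),
                        vote_rule = "any_positive", seed = 1,
                        n_features = 4, config = ga_config(), test_spc = NULL),
                   class = "gac_ensemble")
  x <- near1
  expect_equal(ensemble_label(ens, x), 1L)                       # OR rule
  expect_equal(ensemble_label(ens, x, vote_rule = "majority"), 0L)
  x0 <- near0
  expect_equal(ensemble_label(ens, x0), 0L)
  expect_equal(ensemble_label(ens, x0, vote_rule = "majority"), 0L)

  # monotone: any_positive positives are a superset of majority positives
  real <- tiny_ensemble(seed = 6, n_gacs = 3)
  set.seed(7)
  xs <- matrix(runif(500 * real$n_features), 500); xs <- xs / rowSums(xs)
  any_p <- ensemble_label(real, xs, vote_rule = "any_positive")
  maj_p <- ensemble_label(real, xs, vote_rule = "majority")
  expect_true(all(maj_p <= any_p))
})

test_that("ensemble score is the mean centroid-distance ratio", {
  ens <- tiny_ensemble(seed = 8, n_gacs = 2)
  set.seed(9)
  xs <- matrix(runif(200 * ens$n_features), 200); xs <- xs / rowSums(xs)
  got <- ensemble_score(ens, xs)
  brute <- sapply(seq_len(200), function(r) {
    mean(sapply(ens$gacs, function(g) {
      tx <- apply_transformation(g$sub1$transform, xs[r, ])
      d1 <- sqrt(sum((tx - g$sub1$c1)^2)); d0 <- sqrt(sum((tx - g$sub1$c0)^2))
      if (d1 + d0 == 0) 0.5 else d1 / (d1 + d0)
    }))
  })
  expect_equal(got, brute, tolerance = 1e-12)
  expect_equal(order(got), order(brute))
  expect_true(all(got >= 0 & got <= 1))
})

test_that("two-fold split is balanced, disjoint and reproducible", {
  ids <- sprintf("c%02d", 1:4)
  f <- two_fold_split(ids, seed = 1)
  expect_length(f$a, 2); expect_length(f$b, 2)
  expect_length(intersect(f$a, f$b), 0)
  expect_setequal(c(f$a, f$b), ids)

  f5 <- two_fold_split(sprintf("c%02d", 1:5), seed = 2)
  expect_equal(sort(c(length(f5$a), length(f5$b))), c(2, 3))
  expect_identical(f5, two_fold_split(sprintf("c%02d", 1:5), seed = 2))
  expect_error(two_fold_split("only"), "at least 2")
})

test_that("cross-validation is deterministic and keeps folds separate", {
  cfg <- synthetic_config(n_chains = 6, l_min = 40, l_max = 48, seed = 5)
  ds <- generate_dataset(cfg)
  gcfg <- ga_config(population_size = 8, stall_generations = 3,
                    max_generations = 6)
  r1 <- run_cross_validation(ds, n_gacs = 2, config = gcfg, seed = 17,
                             w_flank = 3, w_mid = 1, fractions = c(1, 0.2))
  r2 <- run_cross_validation(ds, n_gacs = 2, config = gcfg, seed = 17,
                             w_flank = 3, w_mid = 1, fractions = c(1, 0.2))
  expect_identical(lapply(r1$predictions, `[[`, "records"),
                   lapply(r2$predictions, `[[`, "records"))
  expect_length(intersect(r1$folds$a, r1$folds$b), 0)
  expect_setequal(names(r1$predictions), names(ds))
  # every test chain got a full ranking of its long-range pairs
  for (id in names(ds)) {
    expect_equal(nrow(r1$predictions[[id]]$records),
                 nrow(ds[[id]]$pairs))
  }
  # pooled test SPCs recorded per fold
  expect_equal(r1$models[[1]]$test_spc$c1$provenance, "test_pooled")
})
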