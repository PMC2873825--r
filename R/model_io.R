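## Versioned JSON serialization of trained ensembles. Chromosomes are
## stored as plain a/b/c strings and recompiled on load, so the file is
## human-inspectable structured text and round-trips losslessly.

MODEL_FORMAT_VERSION <- 1L

## Doubles are stored as %.17g strings: 17 significant digits round-trip
## every finite double exactly, which JSON number emission does not
## guarantee, and bit-identical predictions after load are part of the
## serialization contract.
num_out <- function(x) sprintf("%.17g", x)
num_in <- function(x) as.numeric(x)

#' Save a trained ensemble to a JSON model file
#'
#' @param ensemble A `gac_ensemble`.
#' @param path Output path.
#' @export
save_model <- function(ensemble, path) {
  if (length(ensemble$gacs) == 0) stop_gac("no classifiers: refusing to save an empty ensemble")
  ser_sub <- function(s) list(target_class = s$target_class,
                              chromosome = s$chromosome,
                              c1 = num_out(s$c1), c0 = num_out(s$c0),
                              fitness = s$fitness)
  obj <- list(
    format = "gacontact-model",
    version = MODEL_FORMAT_VERSION,
    n_features = ensemble$n_features,
    seed = ensemble$seed,
    vote_rule = ensemble$vote_rule,
    config = unclass(ensemble$config),
    test_spc = if (is.null(ensemble$test_spc)) NULL else list(
      c1 = list(vector = num_out(ensemble$test_spc$c1$vector),
                m = ensemble$test_spc$c1$m),
      c0 = list(vector = num_out(ensemble$test_spc$c0$vector),
                m = ensemble$test_spc$c0$m)),
    gacs = lapply(ensemble$gacs, function(g) list(
      subset_id = g$subset_id, seed = g$seed, n_train = g$n_train,
      sub1 = ser_sub(g$sub1), sub0 = ser_sub(g$sub0)))
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Load an ensemble from a JSON model file
#'
#' @param path Path to a file written by [save_model()].
#' @return A `gac_ensemble` whose predictions are identical to the saved
#'   model's.
#' @export
load_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  if (!identical(obj$format, "gacontact-model"))
    stop_gac("not a gacontact model file: %s", path)
  if (!identical(as.integer(obj$version), MODEL_FORMAT_VERSION))
    stop_gac("model version mismatch: file has %s, package reads %d",
             obj$version, MODEL_FORMAT_VERSION)
  if (length(obj$gacs) == 0) stop_gac("no classifiers in model file")
  de_sub <- function(s) {
    if (!grepl("^[abc]+$", s$chromosome))
      stop_gac("corrupted field: illegal chromosome character in model file")
    tr <- compile_chromosome(s$chromosome)
    if (length(tr$groups) != length(s$c1))
      stop_gac("corrupted field: centroid dimension does not match chromosome")
    list(target_class = s$target_class, chromosome = s$chromosome,
         transform = tr, c1 = num_in(s$c1), c0 = num_in(s$c0),
         fitness = s$fitness, history = NULL)
  }
  gacs <- lapply(obj$gacs, function(g) structure(
    list(sub1 = de_sub(g$sub1), sub0 = de_sub(g$sub0),
         subset_id = g$subset_id, seed = g$seed, n_train = g$n_train),
    class = "gac_model"))
  cfg <- obj$config
  config <- ga_config(cfg$population_size, cfg$elite_fraction,
                      cfg$crossover_prob, cfg$mutation_prob,
                      cfg$stall_generations, cfg$max_generations,
                      cfg$rng_seed)
  test_spc <- NULL
  if (!is.null(obj$test_spc)) {
    test_spc <- list(
      c1 = structure(list(class_id = 1L, chain_id = NA_character_,
                          vector = num_in(obj$test_spc$c1$vector),
                          m = obj$test_spc$c1$m, provenance = "test_pooled"),
                     class = "sp_center"),
      c0 = structure(list(class_id = 0L, chain_id = NA_character_,
                          vector = num_in(obj$test_spc$c0$vector),
                          m = obj$test_spc$c0$m, provenance = "test_pooled"),
                     class = "sp_center"))
  }
  structure(list(gacs = gacs, vote_rule = obj$vote_rule, seed = obj$seed,
                 n_features = obj$n_features, config = config,
                 test_spc = test_spc),
            class = "gac_ensemble")
}
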