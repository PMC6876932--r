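#' Model factory: discriminant reduction + neural classifier
#'
#' Builds the `model_factory` used by [evaluate_loso()] and
#' [evaluate_cross_database()]: given training rows it z-scores the
#' features and fits the Fisher projection on them (training statistics
#' only — nothing of the held-out data enters the fit), projects to
#' `C - 1` dimensions, trains the network of the given architecture,
#' and returns a probability predictor that applies the same
#' projection to new rows.
#'
#' @param genome An [architecture_genome()] or integer vector of
#'   hidden-layer sizes.
#' @param optimizer Passed to [train_network()].
#' @param maxit,l2 Passed to [train_network()].
#' @param use_lda Apply the Fisher reduction before the network
#'   (default `TRUE`); `FALSE` trains on the raw (z-scored) features.
#' @param shrinkage Within-scatter shrinkage passed to
#'   [fit_projection()]; the pipeline defaults to the Ledoit-Wolf
#'   estimated intensity, the regularized-discriminant choice suited to
#'   per-fold sample sizes close to the feature count.
#' @return Function `(X_train, y_train, seed)` returning
#'   `(X_new) -> PD probability` — the factory contract of the
#'   validators.
#' @export
nn_lda_factory <- function(genome, optimizer = "quasi_newton",
                           maxit = 500L, l2 = 1e-4, use_lda = TRUE,
                           shrinkage = "ledoit_wolf") {
  if (!inherits(genome, "architecture_genome")) {
    genome <- architecture_genome(genome)
  }
  function(X_train, y_train, seed = 1L) {
    if (use_lda) {
      proj <- fit_projection(X_train, y_train, k = "auto",
                             shrinkage = shrinkage)
      Xr <- lda_transform(proj, X_train)
    } else {
      ctr <- colMeans(X_train)
      scl <- apply(X_train, 2L, stats::sd)
      scl[scl == 0 | !is.finite(scl)] <- 1
      Xr <- sweep(sweep(X_train, 2L, ctr), 2L, scl, `/`)
    }
    net <- train_network(Xr, y_train, genome, optimizer = optimizer,
                         seed = seed, maxit = maxit, l2 = l2)
    function(X_new) {
      Xn <- if (use_lda) {
        lda_transform(proj, X_new)
      } else {
        sweep(sweep(as.matrix(X_new), 2L, ctr), 2L, scl, `/`)
      }
      predict(net, Xn)
    }
  }
}

#' LOSO fitness function over architectures
#'
#' Wraps a dataset into the fitness the genetic search maximizes: the
#' leave-one-subject-out accuracy (or, for `fitness_kind = "loss"`, the
#' negated subject misclassification rate) of the
#' reduction-plus-network model built by [nn_lda_factory()]. The
#' evaluation seed is fixed into the closure so fitness is a pure
#' function of the genome, as the GA's evaluation cache requires.
#'
#' @param db A `phonation_db` (typically a single-vowel dataset).
#' @param eval_seed Seed fixed for every fitness evaluation.
#' @param fitness_kind `"accuracy"` or `"loss"` (negated
#'   misclassification rate; identical ordering, provided for the
#'   loss-style formulation of the search objective).
#' @param optimizer,maxit,l2,use_lda Passed to [nn_lda_factory()].
#' @return Function `architecture_genome -> fitness`.
#' @export
loso_fitness <- function(db, eval_seed = 1L,
                         fitness_kind = c("accuracy", "loss"),
                         optimizer = "quasi_newton", maxit = 500L,
                         l2 = 1e-4, use_lda = TRUE) {
  fitness_kind <- match.arg(fitness_kind)
  function(genome) {
    factory <- nn_lda_factory(genome, optimizer = optimizer,
                              maxit = maxit, l2 = l2, use_lda = use_lda)
    rep <- evaluate_loso(db, factory, seed = eval_seed)
    if (fitness_kind == "accuracy") rep$metrics$accuracy
    else -(1 - rep$metrics$accuracy)
  }
}

#' Run one per-vowel architecture-search experiment
#'
#' The single-vowel experiment: restrict the training database to one
#' sustained vowel (one recording per training subject), optionally
#' drop the gender-dependent features, run `K` independent genetic
#' searches whose fitness is the LOSO accuracy of the
#' reduction-plus-network model, and report the best architecture's
#' LOSO evaluation.
#'
#' @param db Training `phonation_db` containing the requested vowel.
#' @param vowel `"vowel_a"`, `"vowel_o"` or `"vowel_u"`.
#' @param ga_cfg A [ga_config()].
#' @param remove_gender Drop the 11 gender-dependent features first.
#' @param optimizer,maxit,l2 Network training settings.
#' @param seed Experiment seed (overrides `ga_cfg$seed`).
#' @return List of class `vowel_experiment`: `vowel`, `report`
#'   (evaluation of the best architecture), `best` (its genome and
#'   fitness), `candidates` (per-run best genomes), `ga` (the
#'   `ga_runs` object), `n_features`, `seed`.
#' @export
run_vowel_experiment <- function(db, vowel, ga_cfg = ga_config(),
                                 remove_gender = FALSE,
                                 optimizer = "quasi_newton",
                                 maxit = 500L, l2 = 1e-4, seed = NULL) {
  if (!is.null(seed)) ga_cfg$seed <- as.integer(seed)
  ds <- build_vowel_dataset(db, vowel)
  if (nrow(ds) == 0L) stop("no '", vowel, "' rows in the database")
  if (remove_gender) ds <- remove_gender_dependent_features(ds)
  runs <- repeated_runs(
    cfg = ga_cfg,
    make_fitness = function(run_seed) {
      loso_fitness(ds, eval_seed = run_seed,
                   fitness_kind = ga_cfg$fitness_kind,
                   optimizer = optimizer, maxit = maxit, l2 = l2)
    })
  best <- runs$best[[1L]]
  factory <- nn_lda_factory(best$genome, optimizer = optimizer,
                            maxit = maxit, l2 = l2)
  report <- evaluate_loso(ds, factory, seed = runs$seeds[1L])
  structure(list(
    vowel = vowel,
    report = report,
    best = best,
    candidates = lapply(runs$best, `[[`, "genome"),
    ga = runs,
    n_features = nrow(db_schema(ds)),
    seed = ga_cfg$seed
  ), class = "vowel_experiment")
}

#' @export
print.vowel_experiment <- function(x, ...) {
  cat(sprintf("Vowel experiment [%s], %d features, seed %d\n",
              x$vowel, x$n_features, x$seed))
  cat("  best architecture:", format(x$best$genome), "\n")
  print(x$report)
  invisible(x)
}

#' Run the full diagnostic-system protocol
#'
#' End-to-end experiment: the three per-vowel architecture searches on
#' the training database, cross-dataset model selection, and final
#' validation on the testing database.
#'
#' Candidates (every per-run best architecture from the three vowel
#' searches, de-duplicated) are scored by their LOSO accuracy on each
#' vowel dataset and their per-subject accuracy when trained on the
#' full training database and applied to the testing database; the
#' architecture maximizing the minimum of these accuracies is selected
#' ([select_generalizing_model()]). The selected network is then
#' retrained on the full training database and evaluated once per
#' testing subject. When the testing cohort is single-class (all
#' patients), the final report flags specificity and MCC undefined.
#'
#' @param train_db,test_db Training and testing `phonation_db` objects
#'   sharing one schema.
#' @param ga_cfg A [ga_config()].
#' @param remove_gender Drop the gender-dependent features throughout.
#' @param optimizer,maxit,l2 Network training settings.
#' @param seed Protocol seed.
#' @return List of class `full_protocol`: `vowel_experiments` (named
#'   list), `candidates`, `accuracy_matrix` (candidates x datasets:
#'   three vowels + testing), `selected` (the winning genome),
#'   `final_report` (per-testing-subject evaluation),
#'   `selected_loso_accuracy` (max-min value), `n_features`,
#'   `provenance` (seed and config fingerprint embedded in every
#'   serialized artifact).
#' @export
run_full_protocol <- function(train_db, test_db, ga_cfg = ga_config(),
                              remove_gender = FALSE,
                              optimizer = "quasi_newton", maxit = 500L,
                              l2 = 1e-4, seed = 1L) {
  if (!identical(db_schema(train_db)$name, db_schema(test_db)$name)) {
    stop("training and testing schemas differ")
  }
  seed <- as.integer(seed)
  vowels <- c("vowel_a", "vowel_o", "vowel_u")
  experiments <- lapply(seq_along(vowels), function(i) {
    run_vowel_experiment(train_db, vowels[i], ga_cfg = ga_cfg,
                         remove_gender = remove_gender,
                         optimizer = optimizer, maxit = maxit, l2 = l2,
                         seed = seed + 131L * i)
  })
  names(experiments) <- vowels

  candidates <- unlist(lapply(experiments, `[[`, "candidates"),
                       recursive = FALSE)
  keys <- vapply(candidates,
                 function(g) paste(g$neurons_per_layer, collapse = ","),
                 "")
  candidates <- candidates[!duplicated(keys)]

  tr_db <- if (remove_gender) {
    remove_gender_dependent_features(train_db)
  } else train_db
  te_db <- if (remove_gender) {
    remove_gender_dependent_features(test_db)
  } else test_db
  vowel_sets <- lapply(vowels, function(v) build_vowel_dataset(tr_db, v))

  acc <- vapply(candidates, function(g) {
    factory <- nn_lda_factory(g, optimizer = optimizer, maxit = maxit,
                              l2 = l2)
    loso_accs <- vapply(vowel_sets, function(ds) {
      evaluate_loso(ds, factory, seed = seed)$metrics$accuracy
    }, 0)
    cross <- evaluate_cross_database(tr_db, te_db, factory,
                                     seed = seed)$metrics$accuracy
    c(loso_accs, cross)
  }, numeric(length(vowels) + 1L))
  acc <- t(acc)
  colnames(acc) <- c(vowels, "testing")

  sel <- select_generalizing_model(candidates, acc)
  factory <- nn_lda_factory(sel$genome, optimizer = optimizer,
                            maxit = maxit, l2 = l2)
  final_report <- evaluate_cross_database(tr_db, te_db, factory,
                                          seed = seed)

  structure(list(
    vowel_experiments = experiments,
    candidates = candidates,
    accuracy_matrix = acc,
    selected = sel$genome,
    selected_min_accuracy = sel$min_accuracy,
    final_report = final_report,
    n_features = nrow(db_schema(tr_db)),
    provenance = list(seed = seed,
                      config_fingerprint = .config_fingerprint(
                        ga_cfg, remove_gender, optimizer, maxit, l2))
  ), class = "full_protocol")
}

# short deterministic fingerprint of the experiment settings, embedded in
# serialized reports for provenance
.config_fingerprint <- function(...) {
  txt <- paste(utils::capture.output(utils::str(list(...))),
               collapse = "\n")
  # polynomial rolling hash mod 2^31-1; dependency-free and stable
  bytes <- utf8ToInt(txt)
  h <- 0
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}

#' @export
print.full_protocol <- function(x, ...) {
  cat(sprintf("Full protocol (%d features, seed %d, config %s)\n",
              x$n_features, x$provenance$seed,
              x$provenance$config_fingerprint))
  cat("  selected architecture:", format(x$selected),
      sprintf("(min accuracy across datasets %.4f)\n",
              x$selected_min_accuracy))
  cat("  accuracy matrix (candidates x datasets):\n")
  print(round(x$accuracy_matrix, 4))
  cat("  testing-database evaluation:\n  ")
  print(x$final_report$metrics)
  invisible(x)
}

#' Serialize a full-protocol result as JSON
#'
#' Writes the selection table, the chosen architecture, the final
#' per-subject report and the provenance block (seed + configuration
#' fingerprint) as one JSON document.
#'
#' @param protocol A `full_protocol`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
protocol_to_json <- function(protocol, path) {
  jsonlite::write_json(list(
    provenance = protocol$provenance,
    n_features = protocol$n_features,
    selected = list(
      n_hidden_layers = protocol$selected$n_hidden_layers,
      neurons_per_layer = protocol$selected$neurons_per_layer),
    selected_min_accuracy = protocol$selected_min_accuracy,
    accuracy_matrix = as.data.frame(protocol$accuracy_matrix),
    candidates = lapply(protocol$candidates,
                        function(g) g$neurons_per_layer),
    final = list(
      accuracy = protocol$final_report$metrics$accuracy,
      sensitivity = protocol$final_report$metrics$sensitivity,
      specificity_defined =
        protocol$final_report$metrics$specificity_defined,
      mcc_defined = protocol$final_report$metrics$mcc_defined,
      counts = unclass(protocol$final_report$counts))
  ), path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}
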