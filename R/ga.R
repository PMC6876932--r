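#' Genetic-algorithm configuration
#'
#' Settings of the evolutionary architecture search. Defaults follow
#' the experimental protocol the package implements: population 15, 10
#' generations, gene mutation probability 0.10, tournament selection of
#' size 3. Crossover probability (0.9 per selected pair), elitism (1)
#' and the search-space bounds (one or two hidden layers, 1..64 neurons
#' each) are this package's documented choices.
#'
#' @param population_size Chromosomes per generation.
#' @param n_generations Total generations (the random initial
#'   population counts as generation 1).
#' @param mutation_prob Per-gene mutation probability.
#' @param tournament_size Contestants per tournament.
#' @param crossover_prob Probability a selected parent pair is crossed.
#' @param l_range Bounds `c(min, max)` on the number of hidden layers.
#' @param h_range Bounds on neurons per hidden layer.
#' @param elitism Number of best individuals copied unchanged into the
#'   next generation.
#' @param n_runs Number of independent repetitions `K` used by
#'   [repeated_runs()].
#' @param fitness_kind `"accuracy"` (maximized; values in `[0, 1]`) or
#'   `"loss"` (fitness is the negated validation loss).
#' @param seed Integer master seed.
#' @return Validated list of class `ga_config`.
#' @export
ga_config <- function(population_size = 15L, n_generations = 10L,
                      mutation_prob = 0.10, tournament_size = 3L,
                      crossover_prob = 0.9, l_range = c(1L, 2L),
                      h_range = c(1L, 64L), elitism = 1L, n_runs = 5L,
                      fitness_kind = c("accuracy", "loss"), seed = 1L) {
  fitness_kind <- match.arg(fitness_kind)
  cfg <- list(population_size = as.integer(population_size),
              n_generations = as.integer(n_generations),
              mutation_prob = mutation_prob,
              tournament_size = as.integer(tournament_size),
              crossover_prob = crossover_prob,
              l_range = as.integer(l_range),
              h_range = as.integer(h_range),
              elitism = as.integer(elitism),
              n_runs = as.integer(n_runs),
              fitness_kind = fitness_kind,
              seed = as.integer(seed))
  stopifnot(cfg$population_size >= 1L, cfg$n_generations >= 1L,
            cfg$mutation_prob >= 0, cfg$mutation_prob <= 1,
            cfg$crossover_prob >= 0, cfg$crossover_prob <= 1,
            cfg$tournament_size >= 1L,
            cfg$tournament_size <= cfg$population_size,
            length(cfg$l_range) == 2L, cfg$l_range[1L] >= 1L,
            cfg$l_range[1L] <= cfg$l_range[2L],
            length(cfg$h_range) == 2L, cfg$h_range[1L] >= 1L,
            cfg$h_range[1L] <= cfg$h_range[2L],
            cfg$elitism >= 0L, cfg$elitism < cfg$population_size,
            cfg$n_runs >= 1L)
  class(cfg) <- "ga_config"
  cfg
}

# --- gene-string representation -------------------------------------------

#' Gene-string coding of architectures
#'
#' A chromosome is the integer vector `c(L, H_1, ..., H_Lmax)`:
#' variable-length genomes are padded to the maximum layer count so
#' one-point crossover is well defined; inactive neuron genes carry
#' values but are ignored when decoding.
#'
#' @param genes Integer gene string.
#' @param genome An [architecture_genome()].
#' @param cfg A [ga_config()] providing the padding bounds.
#' @return `genes_to_genome()` an `architecture_genome`;
#'   `genome_to_genes()` the padded integer string.
#' @export
genes_to_genome <- function(genes) {
  architecture_genome(genes[1L + seq_len(genes[1L])])
}

#' @rdname genes_to_genome
#' @export
genome_to_genes <- function(genome, cfg) {
  h <- genome$neurons_per_layer
  pad <- cfg$l_range[2L] - length(h)
  if (pad < 0L) stop("genome exceeds the configured maximum layers")
  c(length(h), h, rep(cfg$h_range[1L], pad))
}

.clamp_genes <- function(genes, cfg) {
  genes[1L] <- min(max(genes[1L], cfg$l_range[1L]), cfg$l_range[2L])
  genes[-1L] <- pmin(pmax(genes[-1L], cfg$h_range[1L]), cfg$h_range[2L])
  as.integer(genes)
}

.random_genes <- function(cfg) {
  c(sample(cfg$l_range[1L]:cfg$l_range[2L], 1L),
    sample(cfg$h_range[1L]:cfg$h_range[2L], cfg$l_range[2L],
           replace = TRUE))
}

.gene_key <- function(genes) paste(genes, collapse = ",")

#' Tournament selection
#'
#' Draws `size` contestants uniformly from the population (without
#' replacement when the population is large enough, with replacement
#' otherwise) and returns the contestant with the highest fitness (ties
#' broken by draw order). Uses the current RNG state; seed the stream
#' with [withr::with_seed()] for reproducibility.
#'
#' @param population Non-empty list of entries with elements `genes`
#'   (or `genome`) and `fitness`.
#' @param size Tournament size.
#' @return The winning population entry.
#' @export
tournament_select <- function(population, size = 3L) {
  n <- length(population)
  if (n == 0L) stop("population is empty")
  idx <- sample.int(n, size, replace = size > n)
  fits <- vapply(population[idx], function(e) e$fitness, 0)
  population[[idx[which.max(fits)]]]
}

#' One-point crossover of two chromosomes
#'
#' Cuts the padded gene strings `c(L, H1, ..., H_Lmax)` at one random
#' position and swaps the tails; children are clamped into the search
#' space bounds. Uses the current RNG state.
#'
#' @param a,b Integer gene strings of equal length (see
#'   [genome_to_genes()]).
#' @param cfg A [ga_config()] providing the bounds.
#' @return List of two child gene strings.
#' @export
ga_crossover <- function(a, b, cfg) {
  stopifnot(length(a) == length(b), length(a) >= 2L)
  cut <- sample.int(length(a) - 1L, 1L)
  child1 <- c(a[seq_len(cut)], b[-seq_len(cut)])
  child2 <- c(b[seq_len(cut)], a[-seq_len(cut)])
  list(.clamp_genes(child1, cfg), .clamp_genes(child2, cfg))
}

#' Per-gene uniform mutation
#'
#' Each gene is independently resampled uniformly within its bounds
#' with probability `prob` (the layer gene within `l_range`, neuron
#' genes within `h_range`). Uses the current RNG state.
#'
#' @param genes Integer gene string.
#' @param prob Mutation probability per gene.
#' @param cfg A [ga_config()].
#' @return Mutated gene string.
#' @export
ga_mutate <- function(genes, prob, cfg) {
  stopifnot(prob >= 0, prob <= 1)
  hit <- stats::runif(length(genes)) < prob
  if (hit[1L]) {
    genes[1L] <- sample(cfg$l_range[1L]:cfg$l_range[2L], 1L)
  }
  for (j in which(hit[-1L]) + 1L) {
    genes[j] <- sample(cfg$h_range[1L]:cfg$h_range[2L], 1L)
  }
  as.integer(genes)
}

#' Evolve network architectures by genetic search
#'
#' Generational loop of tournament selection, one-point crossover,
#' per-gene mutation and elitist replacement, maximizing a user fitness
#' over architecture genomes. Fitness evaluations are cached by gene
#' string, so a genome recurring across generations costs one
#' evaluation, and the entire run is a deterministic function of
#' `cfg$seed` (the fitness function must itself be deterministic, which
#' holds when it fixes its own evaluation seed — required for cache
#' coherence).
#'
#' @param fitness_fn Function `architecture_genome -> scalar fitness`
#'   (higher is better).
#' @param cfg A [ga_config()].
#' @return List of class `ga_run`: `best` (list with `genome`, `genes`,
#'   `fitness`), `history` (data frame: generation, genes, fitness, one
#'   row per evaluated individual slot), `best_by_generation`,
#'   `n_evaluations` (distinct fitness calls), `seed`.
#' @export
ga_evolve <- function(fitness_fn, cfg) {
  stopifnot(inherits(cfg, "ga_config"))
  cache <- new.env(parent = emptyenv())
  n_eval <- 0L
  evaluate <- function(genes) {
    key <- .gene_key(genes)
    if (!is.null(cache[[key]])) return(cache[[key]])
    fit <- fitness_fn(genes_to_genome(genes))
    if (!is.finite(fit)) {
      stop("fitness function returned a non-finite value for genome ",
           format(genes_to_genome(genes)))
    }
    n_eval <<- n_eval + 1L
    cache[[key]] <- fit
    fit
  }

  withr::with_seed(cfg$seed, {
    pop <- lapply(seq_len(cfg$population_size), function(i) {
      genes <- .random_genes(cfg)
      list(genes = genes, fitness = evaluate(genes))
    })
    history <- list()
    record <- function(gen, pop) {
      history[[length(history) + 1L]] <<- data.frame(
        generation = gen,
        genes = vapply(pop, function(e) .gene_key(e$genes), ""),
        fitness = vapply(pop, function(e) e$fitness, 0),
        stringsAsFactors = FALSE)
    }
    record(1L, pop)
    best <- pop[[which.max(vapply(pop, function(e) e$fitness, 0))]]

    for (gen in seq_len(cfg$n_generations - 1L) + 1L) {
      fits <- vapply(pop, function(e) e$fitness, 0)
      elite <- pop[order(-fits)][seq_len(cfg$elitism)]
      children <- list()
      while (length(children) < cfg$population_size - cfg$elitism) {
        p1 <- tournament_select(pop, cfg$tournament_size)
        p2 <- tournament_select(pop, cfg$tournament_size)
        pair <- if (stats::runif(1L) < cfg$crossover_prob) {
          ga_crossover(p1$genes, p2$genes, cfg)
        } else {
          list(p1$genes, p2$genes)
        }
        for (genes in pair) {
          if (length(children) >= cfg$population_size - cfg$elitism) break
          genes <- ga_mutate(genes, cfg$mutation_prob, cfg)
          children[[length(children) + 1L]] <-
            list(genes = genes, fitness = evaluate(genes))
        }
      }
      pop <- c(elite, children)
      record(gen, pop)
      gen_best <- pop[[which.max(vapply(pop, function(e) e$fitness, 0))]]
      if (gen_best$fitness > best$fitness) best <- gen_best
    }

    history <- do.call(rbind, history)
    best_by_gen <- vapply(split(history$fitness, history$generation),
                          max, 0)
    structure(list(
      best = list(genome = genes_to_genome(best$genes),
                  genes = best$genes, fitness = best$fitness),
      history = history,
      best_by_generation = cummax(best_by_gen),
      n_evaluations = n_eval,
      seed = cfg$seed
    ), class = "ga_run")
  })
}

#' @export
print.ga_run <- function(x, ...) {
  cat("GA run (seed", x$seed, "):", x$n_evaluations,
      "fitness evaluations\n")
  cat("  best:", format(x$best$genome), "fitness",
      signif(x$best$fitness, 5), "\n")
  invisible(x)
}

#' K independent genetic-search repetitions
#'
#' Runs [ga_evolve()] `cfg$n_runs` times with distinct seeds derived
#' deterministically from the master seed, returning the per-run best
#' chromosomes sorted by decreasing fitness. Because the GA is
#' population-based, repetitions typically discover different
#' near-optimal architectures; the cross-dataset selection rule
#' ([select_generalizing_model()]) then picks among them.
#'
#' @param fitness_fn As in [ga_evolve()]; may accept `(genome)` only —
#'   each run fixes its own derived seed into the fitness closure via
#'   the `make_fitness` hook when supplied.
#' @param cfg A [ga_config()].
#' @param make_fitness Optional function `run_seed -> fitness_fn`,
#'   letting each run evaluate fitness under its own fixed seed.
#' @return List of class `ga_runs`: `runs` (the `ga_run` objects, in
#'   run order) and `best` (per-run best entries sorted by fitness,
#'   non-increasing).
#' @export
repeated_runs <- function(fitness_fn = NULL, cfg, make_fitness = NULL) {
  stopifnot(inherits(cfg, "ga_config"))
  if (is.null(fitness_fn) && is.null(make_fitness)) {
    stop("supply fitness_fn or make_fitness")
  }
  seeds <- (cfg$seed + 7919L * seq_len(cfg$n_runs)) %%
    .Machine$integer.max
  runs <- lapply(seq_len(cfg$n_runs), function(k) {
    run_cfg <- cfg
    run_cfg$seed <- seeds[k]
    fn <- if (!is.null(make_fitness)) make_fitness(seeds[k]) else fitness_fn
    ga_evolve(fn, run_cfg)
  })
  best <- lapply(runs, `[[`, "best")
  ord <- order(-vapply(best, `[[`, 0, "fitness"))
  structure(list(runs = runs, best = best[ord], seeds = seeds),
            class = "ga_runs")
}

#' Pick the architecture that generalizes across datasets
#'
#' Given candidate architectures and their accuracy on each of several
#' datasets (the per-vowel training experiments and the cross-database
#' test), returns the candidate maximizing the *minimum* accuracy
#' across datasets — the model that holds up everywhere rather than
#' excelling once. Ties are broken toward fewer total neurons, then
#' fewer layers, preferring the lower-complexity network.
#'
#' @param candidates List of [architecture_genome()] objects.
#' @param accuracy_matrix Numeric matrix, `length(candidates)` rows,
#'   one column per dataset.
#' @return List: `genome` (the winner), `index`, `min_accuracy`.
#' @export
select_generalizing_model <- function(candidates, accuracy_matrix) {
  if (length(candidates) == 0L) stop("no candidate architectures")
  accuracy_matrix <- matrix(accuracy_matrix, nrow = length(candidates))
  min_acc <- apply(accuracy_matrix, 1L, min)
  size <- vapply(candidates,
                 function(g) sum(g$neurons_per_layer), 0L)
  layers <- vapply(candidates, function(g) g$n_hidden_layers, 0L)
  ord <- order(-min_acc, size, layers)
  idx <- ord[1L]
  list(genome = candidates[[idx]], index = idx,
       min_accuracy = min_acc[idx])
}
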