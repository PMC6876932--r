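#' Configuration of the synthetic phonation cohort generator
#'
#' Defines the cohort structure and class-conditional feature
#' distributions of a simulated multi-phonation voice study. Defaults
#' reproduce the structure of the two-part clinical design the package
#' targets: a balanced training database of 20 PD and 20 healthy
#' subjects with 26 recordings each (one sustained vowel "a", "o" and
#' "u" plus words, sentences and numbers), and an all-PD testing
#' database of 28 subjects with three phonations of vowel "a" and three
#' of vowel "o" each.
#'
#' Features are drawn independently per feature (diagonal covariance)
#' from class-conditional Gaussians; only marginal moments are
#' specified, so no correlation structure is imposed unless a
#' correlation matrix is supplied via `cor_matrix`. `separation_scale`
#' scales the PD-healthy contrast: class means are interpolated linearly
#' about their midpoint and class standard deviations geometrically
#' toward the pooled value, so `separation_scale = 0` makes the two
#' class distributions identical (null data) and `1` recovers the
#' stated per-class statistics.
#'
#' Two nuisance components make the simulation honest for
#' subject-aware validation: a per-subject random mean offset (sd
#' `subject_effect_sd` in units of the feature sd) that makes rows of
#' one subject correlated — so leave-one-subject-out is genuinely harder
#' than row-wise splitting — and an additive offset on the
#' gender-dependent features (`gender_offset` feature-sds added for
#' female subjects) so that gender-confounding experiments are
#' reproducible in simulation.
#'
#' @param n_pd_train,n_healthy_train Training subjects per class.
#' @param samples_per_training_subject Recordings per training subject
#'   (>= 3; the first three slots are the sustained vowels a, o, u,
#'   the remainder cycles through word/sentence/number).
#' @param n_pd_test Testing subjects (all PD).
#' @param vowel_a_per_test_subject,vowel_o_per_test_subject Phonations
#'   of each vowel per testing subject.
#' @param class_stats Data frame as returned by
#'   [synthetic_class_stats()]: per-feature `mean_pd`, `sd_pd`,
#'   `mean_healthy`, `sd_healthy`.
#' @param separation_scale Non-negative multiplier of the class contrast.
#' @param gender_ratio Fraction of female subjects in `[0, 1]`. The
#'   source cohorts do not publish per-gender counts, so the default of
#'   0.5 is an arbitrary documented choice.
#' @param subject_effect_sd Subject random-effect sd, in feature-sd units.
#' @param gender_offset Additive offset on gender-dependent features for
#'   female subjects, in feature-sd units.
#' @param cor_matrix Optional feature correlation matrix (defaults to
#'   independence).
#' @param seed Integer seed; generation is fully deterministic given it.
#' @param schema Feature schema.
#' @return A validated list of class `generator_config`.
#' @export
generator_config <- function(n_pd_train = 20L, n_healthy_train = 20L,
                             samples_per_training_subject = 26L,
                             n_pd_test = 28L,
                             vowel_a_per_test_subject = 3L,
                             vowel_o_per_test_subject = 3L,
                             class_stats = synthetic_class_stats(schema),
                             separation_scale = 1,
                             gender_ratio = 0.5,
                             subject_effect_sd = 0.25,
                             gender_offset = 0.5,
                             cor_matrix = NULL,
                             seed = 1L,
                             schema = pd_feature_schema()) {
  cfg <- list(
    n_pd_train = as.integer(n_pd_train),
    n_healthy_train = as.integer(n_healthy_train),
    samples_per_training_subject = as.integer(samples_per_training_subject),
    n_pd_test = as.integer(n_pd_test),
    vowel_a_per_test_subject = as.integer(vowel_a_per_test_subject),
    vowel_o_per_test_subject = as.integer(vowel_o_per_test_subject),
    class_stats = class_stats,
    separation_scale = separation_scale,
    gender_ratio = gender_ratio,
    subject_effect_sd = subject_effect_sd,
    gender_offset = gender_offset,
    cor_matrix = cor_matrix,
    seed = as.integer(seed),
    schema = schema
  )
  counts <- c("n_pd_train", "n_healthy_train",
              "samples_per_training_subject", "n_pd_test",
              "vowel_a_per_test_subject", "vowel_o_per_test_subject")
  for (nm in counts) {
    if (length(cfg[[nm]]) != 1L || is.na(cfg[[nm]]) || cfg[[nm]] < 0L) {
      stop("invalid count for ", nm)
    }
  }
  if (cfg$samples_per_training_subject < 3L &&
      (cfg$n_pd_train + cfg$n_healthy_train) > 0L) {
    stop("samples_per_training_subject must be >= 3 (one per vowel)")
  }
  if (!identical(class_stats$name, schema$name)) {
    stop("class_stats rows must match schema order")
  }
  if (any(class_stats$sd_pd <= 0) || any(class_stats$sd_healthy <= 0)) {
    stop("all class standard deviations must be positive")
  }
  if (separation_scale < 0) stop("separation_scale must be non-negative")
  if (gender_ratio < 0 || gender_ratio > 1) {
    stop("gender_ratio must lie in [0, 1]")
  }
  if (subject_effect_sd < 0) stop("subject_effect_sd must be non-negative")
  if (!is.null(cor_matrix)) {
    p <- nrow(schema)
    if (!is.matrix(cor_matrix) || any(dim(cor_matrix) != p)) {
      stop("cor_matrix must be ", p, "x", p)
    }
  }
  class(cfg) <- "generator_config"
  cfg
}

# class moments at the configured separation scale: means interpolate
# linearly about the midpoint (the knob multiplies the PD-healthy mean
# gap); sds interpolate geometrically toward the pooled sd only on
# [0, 1] -- so scale 0 gives identical class distributions, scale 1 the
# stated per-class moments, and scales > 1 widen the gap without
# inflating either class's spread
scaled_class_moments <- function(cfg) {
  st <- cfg$class_stats
  s <- cfg$separation_scale
  s_sd <- min(s, 1)
  mid <- (st$mean_pd + st$mean_healthy) / 2
  pool <- sqrt((st$sd_pd^2 + st$sd_healthy^2) / 2)
  list(
    mean_pd = mid + s * (st$mean_pd - mid),
    mean_healthy = mid + s * (st$mean_healthy - mid),
    sd_pd = pool * (st$sd_pd / pool)^s_sd,
    sd_healthy = pool * (st$sd_healthy / pool)^s_sd
  )
}

# true standardized class contrast per feature under the scaled moments
true_effect_sizes <- function(cfg) {
  m <- scaled_class_moments(cfg)
  d <- (m$mean_pd - m$mean_healthy) / sqrt((m$sd_pd^2 + m$sd_healthy^2) / 2)
  stats::setNames(d, cfg$schema$name)
}

# draw one subject's recording rows; rows correlated through the subject
# random effect
.simulate_subject_rows <- function(cfg, subject_id, label, gender,
                                   sample_types, moments) {
  p <- nrow(cfg$schema)
  n <- length(sample_types)
  mu <- if (label == "PD") moments$mean_pd else moments$mean_healthy
  sd <- if (label == "PD") moments$sd_pd else moments$sd_healthy
  offset <- stats::rnorm(p, 0, cfg$subject_effect_sd * sd)
  if (gender == "F" && cfg$gender_offset != 0) {
    gd <- cfg$schema$gender_dependent
    mu <- mu + ifelse(gd, cfg$gender_offset * sd, 0)
  }
  noise <- matrix(stats::rnorm(n * p), nrow = n)
  if (!is.null(cfg$cor_matrix)) {
    noise <- noise %*% chol(cfg$cor_matrix)
  }
  vals <- sweep(noise, 2L, sd, `*`)
  vals <- sweep(vals, 2L, mu + offset, `+`)
  colnames(vals) <- cfg$schema$name
  cbind(
    data.frame(subject_id = subject_id, label = label, gender = gender,
               sample_type = sample_types, stringsAsFactors = FALSE),
    as.data.frame(vals)
  )
}

.empty_db <- function(cfg, role) {
  cols <- c(.metadata_cols, cfg$schema$name)
  rows <- as.data.frame(stats::setNames(
    c(rep(list(character(0)), 4L), rep(list(numeric(0)), nrow(cfg$schema))),
    cols), stringsAsFactors = FALSE)
  structure(rows, schema = cfg$schema, role = role,
            class = c("phonation_db", "data.frame"))
}

.build_manifest <- function(db, cfg) {
  tallies <- if (nrow(db) > 0L) {
    as.data.frame(table(subject_id = db$subject_id,
                        sample_type = db$sample_type),
                  stringsAsFactors = FALSE)
  } else {
    data.frame(subject_id = character(0), sample_type = character(0),
               Freq = integer(0))
  }
  structure(list(
    n_rows = nrow(db),
    n_subjects = length(unique(db$subject_id)),
    sample_type_counts = if (nrow(db) > 0L) {
      as.list(table(db$sample_type))
    } else list(),
    per_subject_tally = tallies,
    seed = cfg$seed,
    separation_scale = cfg$separation_scale,
    true_effects = true_effect_sizes(cfg)
  ), class = "generation_manifest")
}

#' Generate a synthetic training database
#'
#' One row per (subject, recording slot). Each subject receives exactly
#' one `vowel_a`, one `vowel_o` and one `vowel_u` recording; remaining
#' slots cycle through `word`, `sentence`, `number`. Feature values are
#' class-conditional Gaussians plus the subject and gender effects of
#' the configuration. Deterministic given `cfg$seed`.
#'
#' @param cfg A [generator_config()].
#' @return A list with elements `db` (a `phonation_db`, role
#'   `"training"`) and `manifest` (row counts, per-subject sample-type
#'   tallies, seed and true per-feature effect sizes).
#' @examples
#' gen <- generate_training_database(generator_config(seed = 7))
#' nrow(gen$db)          # 40 * 26 = 1040
#' gen$manifest$n_rows
#' @export
generate_training_database <- function(cfg) {
  stopifnot(inherits(cfg, "generator_config"))
  n_subj <- cfg$n_pd_train + cfg$n_healthy_train
  if (n_subj == 0L) {
    db <- .empty_db(cfg, "training")
    return(list(db = db, manifest = .build_manifest(db, cfg)))
  }
  m <- cfg$samples_per_training_subject
  sample_types <- c("vowel_a", "vowel_o", "vowel_u",
                    rep(c("word", "sentence", "number"),
                        length.out = m - 3L))
  moments <- scaled_class_moments(cfg)
  labels <- rep(c("PD", "healthy"), c(cfg$n_pd_train, cfg$n_healthy_train))
  db <- withr::with_seed(cfg$seed, {
    genders <- ifelse(stats::runif(n_subj) < cfg$gender_ratio, "F", "M")
    parts <- lapply(seq_len(n_subj), function(i) {
      .simulate_subject_rows(
        cfg, sprintf("train_%02d", i), labels[i], genders[i],
        sample_types, moments)
    })
    phonation_database(do.call(rbind, parts), schema = cfg$schema,
                       role = "training")
  })
  list(db = db, manifest = .build_manifest(db, cfg))
}

#' Generate a synthetic testing database
#'
#' All subjects carry the PD label (the independent validation cohort
#' the design emulates contains patients only). Each subject contributes
#' `vowel_a_per_test_subject` phonations of vowel "a" and
#' `vowel_o_per_test_subject` of vowel "o". Deterministic given
#' `cfg$seed` (a fixed offset of the training stream, so training and
#' testing draws are independent but jointly reproducible).
#'
#' @inheritParams generate_training_database
#' @return A list with elements `db` (role `"testing"`) and `manifest`.
#' @examples
#' gen <- generate_testing_database(generator_config(seed = 7))
#' nrow(gen$db)          # 28 * 6 = 168
#' @export
generate_testing_database <- function(cfg) {
  stopifnot(inherits(cfg, "generator_config"))
  if (cfg$n_pd_test == 0L) {
    db <- .empty_db(cfg, "testing")
    return(list(db = db, manifest = .build_manifest(db, cfg)))
  }
  sample_types <- c(rep("vowel_a", cfg$vowel_a_per_test_subject),
                    rep("vowel_o", cfg$vowel_o_per_test_subject))
  if (length(sample_types) == 0L) {
    db <- .empty_db(cfg, "testing")
    return(list(db = db, manifest = .build_manifest(db, cfg)))
  }
  moments <- scaled_class_moments(cfg)
  test_seed <- (cfg$seed + 104729L) %% .Machine$integer.max
  db <- withr::with_seed(test_seed, {
    genders <- ifelse(stats::runif(cfg$n_pd_test) < cfg$gender_ratio,
                      "F", "M")
    parts <- lapply(seq_len(cfg$n_pd_test), function(i) {
      .simulate_subject_rows(
        cfg, sprintf("test_%02d", i), "PD", genders[i],
        sample_types, moments)
    })
    phonation_database(do.call(rbind, parts), schema = cfg$schema,
                       role = "testing")
  })
  list(db = db, manifest = .build_manifest(db, cfg))
}

#' Observed standardized class contrasts of a generated database
#'
#' Computes the per-feature Cohen-style standardized mean difference
#' (PD minus healthy over the pooled sd) observed in a database, for
#' checking the generator against the true effects recorded in its
#' manifest: as the number of rows grows the observed values approach
#' the manifest truth.
#'
#' @param db A `phonation_db` containing both classes.
#' @param manifest Optional `generation_manifest`; when supplied its
#'   true effects are attached for comparison.
#' @return Data frame with columns `feature`, `observed_d` and (when a
#'   manifest is given) `true_d`.
#' @export
empirical_effect_check <- function(db, manifest = NULL) {
  if (!is.null(manifest) &&
      !identical(names(manifest$true_effects), db_schema(db)$name)) {
    stop("manifest schema does not match database schema")
  }
  X <- feature_matrix(db)
  y <- db_labels(db)
  if (length(unique(y)) < 2L) stop("both classes required")
  pd <- X[y == "PD", , drop = FALSE]
  hc <- X[y == "healthy", , drop = FALSE]
  pool <- sqrt((apply(pd, 2L, stats::var) + apply(hc, 2L, stats::var)) / 2)
  d <- (colMeans(pd) - colMeans(hc)) / pool
  out <- data.frame(feature = db_schema(db)$name, observed_d = unname(d),
                    stringsAsFactors = FALSE)
  if (!is.null(manifest)) out$true_d <- unname(manifest$true_effects)
  out
}
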