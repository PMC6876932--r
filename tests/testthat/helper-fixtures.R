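# Small in-code fixtures shared across the suite.

# a tiny hand-built database: 2 subjects, 3 rows, canonical schema
tiny_db <- function() {
  sch <- pd_feature_schema()
  rows <- data.frame(
    subject_id = c("s1", "s1", "s2"),
    label = c("PD", "PD", "healthy"),
    gender = c("M", "M", "F"),
    sample_type = c("vowel_a", "vowel_o", "vowel_a"),
    stringsAsFactors = FALSE)
  set.seed(42)
  for (nm in sch$name) rows[[nm]] <- round(runif(3, 0, 10), 3)
  phonation_database(rows, role = "training")
}

# a small seeded synthetic training database (n subjects per class,
# vowels only by default to keep tests fast)
small_training_db <- function(seed = 1, n = 6L, separation = 1.5,
                              samples = 3L) {
  cfg <- generator_config(n_pd_train = n, n_healthy_train = n,
                          samples_per_training_subject = samples,
                          separation_scale = separation, seed = seed)
  generate_training_database(cfg)$db
}

# class-conditional Gaussian toy matrix with known effect direction
toy_gaussian <- function(n_per_class = 30L, p = 4L, delta = 2,
                         seed = 1) {
  withr::with_seed(seed, {
    y <- rep(c("PD", "healthy"), each = n_per_class)
    X <- matrix(stats::rnorm(2 * n_per_class * p), ncol = p)
    shift <- c(delta, rep(0, p - 1L))
    X[y == "PD", ] <- sweep(X[y == "PD", , drop = FALSE], 2L, shift, `+`)
    list(X = X, y = y)
  })
}
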