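#' Canonical sustained-phonation feature schema
#'
#' The 26 dysphonic measures extracted (with Praat) from each voice
#' recording, grouped into six families: five jitter measures
#' (cycle-to-cycle period perturbation), six shimmer measures
#' (cycle-to-cycle amplitude perturbation), three harmonicity measures,
#' five pitch statistics, four pulse/period counts, and three voicing
#' measures. Column names are a frozen snake_case rendering of the
#' conventional Praat voice-report labels; this ordering is the canonical
#' column order of every phonation database handled by the package.
#'
#' Eleven features are flagged `gender_dependent`: jitter (local),
#' shimmer (local), all four pulse/period measures and all five pitch
#' statistics. These are the features removed by
#' [remove_gender_dependent_features()] when running the gender-unbiased
#' variant of the experiments, since fundamental frequency and its
#' derivatives differ systematically between male and female voices.
#'
#' Units follow Praat conventions (percent for relative jitter/shimmer,
#' dB for shimmer (local, dB) and HNR, Hz for pitch, seconds for
#' periods) but are not recorded in the schema because the source
#' tabulations abbreviate them inconsistently; the schema tracks names,
#' families and gender flags only.
#'
#' @return A data frame of class `phonation_schema` with columns
#'   `name`, `family` and `gender_dependent`, exactly 26 rows.
#' @examples
#' sch <- pd_feature_schema()
#' nrow(sch)                      # 26
#' sum(sch$gender_dependent)      # 11
#' @export
pd_feature_schema <- function() {
  sch <- data.frame(
    name = c(
      "jitter_local", "jitter_local_abs", "jitter_rap", "jitter_ppq5",
      "jitter_ddp",
      "shimmer_local", "shimmer_local_db", "shimmer_apq3", "shimmer_apq5",
      "shimmer_apq11", "shimmer_dda",
      "autocorr", "nhr", "hnr",
      "pitch_median", "pitch_mean", "pitch_sd", "pitch_min", "pitch_max",
      "n_pulses", "n_periods", "period_mean", "period_sd",
      "frac_unvoiced", "n_voice_breaks", "degree_voice_breaks"
    ),
    family = c(
      rep("jitter", 5L),
      rep("shimmer", 6L),
      rep("harmonicity", 3L),
      rep("pitch", 5L),
      rep("pulse", 4L),
      rep("voicing", 3L)
    ),
    stringsAsFactors = FALSE
  )
  sch$gender_dependent <- sch$name %in% c(
    "jitter_local", "shimmer_local",
    "pitch_median", "pitch_mean", "pitch_sd", "pitch_min", "pitch_max",
    "n_pulses", "n_periods", "period_mean", "period_sd"
  )
  class(sch) <- c("phonation_schema", "data.frame")
  sch
}

#' Representative class-conditional feature statistics (synthetic defaults)
#'
#' Per-feature mean and standard deviation for the Parkinson's disease
#' (PD) and healthy classes used as default parameters of the synthetic
#' cohort generator. The original clinical tabulation is not
#' redistributable, so these are *synthetic* representative values chosen
#' from the typical ranges of Praat sustained-phonation measures in
#' dysphonia studies (elevated jitter/shimmer/NHR and reduced HNR,
#' autocorrelation and voiced fraction in the PD group). They reproduce
#' the qualitative class contrasts of such data, not any specific
#' clinical cohort.
#'
#' @param schema A [pd_feature_schema()]; statistics are returned in
#'   schema order.
#' @return Data frame with columns `name`, `mean_pd`, `sd_pd`,
#'   `mean_healthy`, `sd_healthy`, one row per schema feature.
#' @seealso [generator_config()]
#' @export
synthetic_class_stats <- function(schema = pd_feature_schema()) {
  stats <- data.frame(
    name = c(
      "jitter_local", "jitter_local_abs", "jitter_rap", "jitter_ppq5",
      "jitter_ddp",
      "shimmer_local", "shimmer_local_db", "shimmer_apq3", "shimmer_apq5",
      "shimmer_apq11", "shimmer_dda",
      "autocorr", "nhr", "hnr",
      "pitch_median", "pitch_mean", "pitch_sd", "pitch_min", "pitch_max",
      "n_pulses", "n_periods", "period_mean", "period_sd",
      "frac_unvoiced", "n_voice_breaks", "degree_voice_breaks"
    ),
    mean_pd = c(
      2.80, 2.1e-4, 1.40, 1.50, 4.20,
      14.0, 1.30, 6.80, 8.60, 11.0, 20.3,
      0.85, 0.21, 9.80,
      152, 154, 25.0, 110, 230,
      95, 92, 6.8e-3, 6.0e-4,
      28.0, 3.2, 11.5
    ),
    sd_pd = c(
      1.90, 1.5e-4, 1.10, 1.20, 3.30,
      6.00, 0.50, 3.50, 4.40, 5.50, 10.4,
      0.09, 0.15, 3.50,
      42, 43, 22.0, 35, 95,
      65, 64, 1.8e-3, 5.0e-4,
      23.0, 4.1, 13.0
    ),
    mean_healthy = c(
      1.70, 1.2e-4, 0.80, 0.85, 2.40,
      10.0, 0.95, 4.70, 6.00, 7.90, 14.0,
      0.91, 0.12, 13.5,
      145, 147, 18.0, 108, 215,
      140, 136, 7.0e-3, 4.0e-4,
      15.0, 1.4, 5.50
    ),
    sd_healthy = c(
      1.00, 0.8e-4, 0.55, 0.60, 1.65,
      4.50, 0.40, 2.50, 3.10, 3.80, 7.50,
      0.06, 0.09, 3.90,
      38, 39, 17.0, 32, 85,
      85, 84, 1.9e-3, 3.0e-4,
      16.0, 2.4, 8.50
    ),
    stringsAsFactors = FALSE
  )
  idx <- match(schema$name, stats$name)
  if (anyNA(idx)) {
    stop("no default statistics for feature(s): ",
         paste(schema$name[is.na(idx)], collapse = ", "))
  }
  stats[idx, , drop = FALSE]
}

# metadata columns preceding the feature block in the CSV dialect
.metadata_cols <- c("subject_id", "label", "gender", "sample_type")

.sample_types <- c("vowel_a", "vowel_o", "vowel_u", "word", "sentence",
                   "number")
.vowel_types <- c("vowel_a", "vowel_o", "vowel_u")
.labels <- c("PD", "healthy")
.genders <- c("M", "F", "unknown")
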