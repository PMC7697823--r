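# Shared fixtures built in code.

# a sequence_db straight from element lists, bypassing the builder
make_db <- function(..., unit = "admission", vocabulary = NULL) {
  seqs <- list(...)
  if (is.null(names(seqs)) || any(names(seqs) == ""))
    names(seqs) <- paste0("s", seq_along(seqs))
  sequences <- lapply(seqs, function(elements) {
    elements <- lapply(elements, function(e) sort(as.integer(e)))
    list(elements = elements, times = seq_along(elements))
  })
  structure(list(sequences = sequences, vocabulary = vocabulary,
                 unit = unit, n = length(sequences)),
            class = "sequence_db")
}

# random small database for miner/oracle comparisons
random_db <- function(seed, max_seqs = 8L, max_len = 6L, alphabet = 5L,
                      itemsets = FALSE) {
  set.seed(seed)
  n <- sample(2:max_seqs, 1L)
  seqs <- lapply(seq_len(n), function(i) {
    len <- sample(1:max_len, 1L)
    if (itemsets)
      lapply(seq_len(len), function(j)
        sort(sample(seq_len(alphabet), sample(1:2, 1L))))
    else
      as.list(sample(seq_len(alphabet), len, replace = TRUE))
  })
  do.call(make_db, seqs)
}

# canonical key of a mining result, for set comparisons
result_keys <- function(res) {
  vapply(res$patterns, function(p)
    paste(vapply(p$elements, paste, character(1), collapse = ","),
          collapse = "|"), character(1))
}

result_supports <- function(res) {
  vapply(res$patterns, `[[`, integer(1), "support_count")
}

# the printed three-row example sequence table
table1_records <- function() {
  data.frame(
    subject_id = 18803L,
    hadm_id = c(233L, 233L, 254L),
    timestamp = "2189-12-24 07:15:00",
    event_id = c(2L, 6185L, 30L),
    event_value = 1,
    stringsAsFactors = FALSE)
}

# 20-feature vocabulary for predictor experiments
small_vocab <- function(F_ = 20L) {
  v <- data.frame(
    event_id = seq_len(F_), label = sprintf("E%02d", seq_len(F_)),
    category = rep_len(c("admission", "lab", "procedure", "prescription",
                         "comorbidity"), F_),
    stringsAsFactors = FALSE)
  v$hierarchy <- paste(v$category, v$label, sep = "/")
  v
}

# strong-signal study conditions: 2000 admissions, <= 10 days, 20 features,
# one causal count-valued feature (id 10) with log-odds weight 2.5 per
# occurrence at 0.7 expected occurrences/day; intercept balances prevalence
strong_signal_config <- function(seed, n_patients = 2000L) {
  synthetic_config(
    n_patients = n_patients, vocab = small_vocab(),
    planted_pathways = list(),
    outcome_model = list(
      intercept = -2.5 * 0.7 * 7,
      effects = list(list(event_id = 10L, window = c(1L, 10L),
                          weight = 2.5, rate = 0.7))),
    noise_events_per_day = 2, stay_length = c(4L, 10L),
    multi_admission_prob = 0, seed = seed)
}

# tensor + splits for the strong-signal task
strong_signal_data <- function(seed, n_patients = 2000L) {
  co <- generate_cohort(strong_signal_config(seed, n_patients))
  rec <- bucket_time(clean_records(co$events, co$admissions), "day")
  tensor <- build_tensor(rec, co$admissions, labels = co$labels,
                         max_len = 10L, vocabulary = co$vocabulary)
  list(cohort = co, tensor = tensor,
       splits = split_dataset(tensor, seed = seed + 1L))
}

# a tiny trained model reused across attention-invariant tests
tiny_trained_model <- function(seed = 5L, epochs = 3L) {
  dat <- strong_signal_data(seed, n_patients = 200L)
  cfg <- model_config(lstm_units = 8L, max_len = 10L, epochs = epochs,
                      batch_size = 32L, seed = seed + 2L)
  list(model = train_model(dat$splits$train, dat$splits$val, cfg),
       data = dat)
}

# 99% binomial confidence interval for a proportion
binom_ci99 <- function(p, n) {
  se <- sqrt(p * (1 - p) / n)
  c(p - stats::qnorm(0.995) * se, p + stats::qnorm(0.995) * se)
}
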