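#' Default synthetic event vocabulary
#'
#' A compact vocabulary spanning the six event categories the generator
#' emulates (admission type, laboratory test, procedure, prescription,
#' comorbidity, diagnosis), with labels drawn from cardiology practice
#' (troponin testing, CABG/PCI, aspirin, ischemic heart disease, ...).
#' Hierarchy paths are slash-separated, category-rooted, so laboratory
#' events can be rolled up to their panel (chemistry vs. hematology).
#'
#' @return A data.frame with columns `event_id`, `label`, `category`,
#'   `hierarchy`.
#' @export
#' @examples
#' head(default_vocabulary())
default_vocabulary <- function() {
  v <- rbind(
    data.frame(event_id = 1:3,
               label = c("Emergency", "Urgent", "Elective"),
               category = "admission",
               stringsAsFactors = FALSE),
    data.frame(event_id = 101:110,
               label = c("Troponin T", "Glucose", "Urea nitrogen",
                         "Cholesterol", "Creatinine", "Sodium", "Potassium",
                         "Fibrinogen", "Hemoglobin", "Platelet count"),
               category = "lab",
               stringsAsFactors = FALSE),
    data.frame(event_id = 201:204,
               label = c("CABG", "PCI", "ECG", "Echocardiography"),
               category = "procedure",
               stringsAsFactors = FALSE),
    data.frame(event_id = 301:304,
               label = c("Aspirin", "Heparin", "Metoprolol", "Furosemide"),
               category = "prescription",
               stringsAsFactors = FALSE),
    data.frame(event_id = 401:403,
               label = c("Ischemic_hd", "Solid_tumor", "Diabetes"),
               category = "comorbidity",
               stringsAsFactors = FALSE),
    data.frame(event_id = 501:502,
               label = c("Congestive_hf", "Myocardial_infarction"),
               category = "diagnosis",
               stringsAsFactors = FALSE)
  )
  panel <- ifelse(v$label %in% c("Fibrinogen", "Hemoglobin", "Platelet count"),
                  "hematology", "chemistry")
  v$hierarchy <- ifelse(v$category == "lab",
                        paste("lab", panel, v$label, sep = "/"),
                        paste(v$category, v$label, sep = "/"))
  v
}

#' Configuration for the synthetic EHR generator
#'
#' @param n_patients Number of patients to simulate.
#' @param vocab Event vocabulary (`event_id`, `label`, `category`, and
#'   optionally `hierarchy`); defaults to [default_vocabulary()].
#' @param planted_pathways List of pathways to plant; each is a list with
#'   `events` (ordered vector of event ids) and `rate` (fraction of patients,
#'   in `[0, 1]`, whose first admission receives the pathway).
#' @param outcome_model List with `intercept` (log-odds) and `effects`, a list
#'   of per-event effects, each a list with `event_id`, `window` (inclusive
#'   hospital-day range `c(from, to)`), `weight` (log-odds contribution per
#'   occurrence), and `rate` (mean spontaneous occurrences per day inside the
#'   window; 0 means the event only occurs if planted via a pathway).
#' @param noise_events_per_day Mean of the Poisson count of uninformative
#'   events per hospital day, drawn uniformly from vocabulary entries that are
#'   neither causal nor part of a planted pathway.
#' @param stay_length Inclusive integer range `c(min, max)` of hospital days
#'   per admission; the minimum must be at least 1.
#' @param multi_admission_prob Probability that a patient has a second,
#'   later admission.
#' @param seed Integer seed; generation is byte-identical for a fixed seed.
#' @return An object of class `synthetic_config`.
#' @export
synthetic_config <- function(n_patients = 200L,
                             vocab = default_vocabulary(),
                             planted_pathways = list(
                               list(events = c(1L, 101L, 201L), rate = 0.3)
                             ),
                             outcome_model = list(
                               intercept = -2,
                               effects = list(
                                 list(event_id = 101L, window = c(1L, 15L),
                                      weight = 1.0, rate = 0.5)
                               )
                             ),
                             noise_events_per_day = 1.5,
                             stay_length = c(3L, 10L),
                             multi_admission_prob = 0.2,
                             seed = 1L) {
  cfg <- structure(
    list(n_patients = as.integer(n_patients), vocab = vocab,
         planted_pathways = planted_pathways, outcome_model = outcome_model,
         noise_events_per_day = noise_events_per_day,
         stay_length = as.integer(stay_length),
         multi_admission_prob = multi_admission_prob,
         seed = as.integer(seed)),
    class = "synthetic_config")
  validate_synthetic_config(cfg)
}

validate_synthetic_config <- function(cfg) {
  if (!is.numeric(cfg$n_patients) || cfg$n_patients < 1)
    stop("invalid configuration field 'n_patients': must be a positive count",
         call. = FALSE)
  assert_columns(cfg$vocab, c("event_id", "label", "category"), "vocab")
  if (anyDuplicated(cfg$vocab$event_id))
    stop("invalid configuration field 'vocab': duplicate event_id",
         call. = FALSE)
  for (p in cfg$planted_pathways) {
    if (is.null(p$events) || length(p$events) < 1L)
      stop("invalid configuration field 'planted_pathways': empty pathway",
           call. = FALSE)
    if (is.null(p$rate) || p$rate < 0 || p$rate > 1)
      stop("invalid configuration field 'planted_pathways': ",
           "planting rate must lie in [0, 1]", call. = FALSE)
    if (!all(p$events %in% cfg$vocab$event_id))
      stop("invalid configuration field 'planted_pathways': ",
           "pathway references event_id absent from vocab", call. = FALSE)
  }
  om <- cfg$outcome_model
  if (is.null(om$intercept) || !is.numeric(om$intercept))
    stop("invalid configuration field 'outcome_model': missing intercept",
         call. = FALSE)
  for (e in om$effects) {
    if (!e$event_id %in% cfg$vocab$event_id)
      stop("invalid configuration field 'outcome_model': ",
           "effect references event_id absent from vocab", call. = FALSE)
    if (length(e$window) != 2L || e$window[1] > e$window[2] || e$window[1] < 1)
      stop("invalid configuration field 'outcome_model': ",
           "effect window must be an increasing day range starting at >= 1",
           call. = FALSE)
  }
  if (cfg$noise_events_per_day < 0)
    stop("invalid configuration field 'noise_events_per_day': ",
         "must be nonnegative", call. = FALSE)
  if (length(cfg$stay_length) != 2L || cfg$stay_length[1] < 1L ||
      cfg$stay_length[1] > cfg$stay_length[2])
    stop("invalid configuration field 'stay_length': ",
         "must be c(min, max) with min >= 1", call. = FALSE)
  cfg
}

#' Generate a synthetic EHR cohort with planted pathways and known outcomes
#'
#' Simulates admission, event, and vocabulary tables shaped like a
#' de-identified hospital extract. Each patient has one or two contiguous
#' admissions; each planted pathway is inserted (Bernoulli at its planting
#' rate, one draw per patient) into the patient's first admission with its
#' events on distinct, strictly increasing hospital days, so day-level
#' bucketing preserves the planted order. Uninformative noise events are
#' drawn per day from the non-causal, non-pathway part of the vocabulary with
#' a Poisson daily count. Causal events additionally occur spontaneously
#' inside their configured day window at their configured daily rate, and the
#' binary outcome label of each admission is drawn from a logistic model on
#' the causal-event counts in those windows.
#'
#' Because pathway and causal events never enter the noise pool, a planted
#' pathway occurs as an ordered subsequence of a patient's record if and only
#' if it was planted (each pathway is assumed to contain at least one
#' non-causal "marker" event; the default configuration satisfies this), so
#' the returned ground-truth flags are exact.
#'
#' @param config A [synthetic_config()].
#' @return A list of class `synthetic_cohort` with elements
#'   \describe{
#'     \item{events}{event table: `subject_id`, `hadm_id`, `timestamp`,
#'       `event_id`, `event_value`, `category`.}
#'     \item{admissions}{admission table: `hadm_id`, `subject_id`,
#'       `admit_time`, `discharge_time`, `death_time`, `admission_type`.}
#'     \item{vocabulary}{the event vocabulary.}
#'     \item{labels}{per-admission binary outcome: `hadm_id`, `label`.}
#'     \item{truth}{ground truth: `pathway_flags` (patients x pathways logical
#'       matrix), `probability` (named per-admission true outcome
#'       probability), `causal_event_ids`.}
#'   }
#' @export
#' @examples
#' cohort <- generate_cohort(synthetic_config(n_patients = 20, seed = 42))
#' head(cohort$events)
generate_cohort <- function(config) {
  config <- validate_synthetic_config(config)
  with_seed(config$seed, generate_cohort_impl(config))
}

generate_cohort_impl <- function(cfg) {
  vocab <- cfg$vocab
  pathway_events <- unique(unlist(lapply(cfg$planted_pathways, `[[`, "events")))
  effects <- cfg$outcome_model$effects
  causal_ids <- unique(vapply(effects, function(e) as.integer(e$event_id),
                              integer(1)))
  noise_pool <- setdiff(vocab$event_id, union(pathway_events, causal_ids))
  if (length(noise_pool) == 0L && cfg$noise_events_per_day > 0)
    stop("invalid configuration field 'vocab': no events left for the noise ",
         "pool (all are causal or planted)", call. = FALSE)
  adm_type_ids <- vocab$event_id[vocab$category == "admission"]
  free_adm_types <- setdiff(adm_type_ids, union(pathway_events, causal_ids))
  cat_of <- setNames(vocab$category, as.character(vocab$event_id))
  lab_of <- setNames(vocab$label, as.character(vocab$event_id))

  n_path <- length(cfg$planted_pathways)
  flags <- matrix(FALSE, nrow = cfg$n_patients, ncol = max(n_path, 1L))
  if (n_path > 0L)
    for (j in seq_len(n_path))
      flags[, j] <- runif(cfg$n_patients) < cfg$planted_pathways[[j]]$rate

  ev_rows <- vector("list", cfg$n_patients)
  adm_rows <- vector("list", cfg$n_patients)
  lab_rows <- vector("list", cfg$n_patients)
  prob_all <- numeric(0)
  base_date <- as.Date("2120-01-01")
  hadm_next <- 1000L

  for (i in seq_len(cfg$n_patients)) {
    n_adm <- 1L + (runif(1) < cfg$multi_admission_prob)
    admit_date <- base_date
    pe <- list(); pa <- list(); pl <- list()
    for (j in seq_len(n_adm)) {
      hadm <- hadm_next; hadm_next <- hadm_next + 1L
      stay <- sample(cfg$stay_length[1]:cfg$stay_length[2], 1L)
      planted <- list()
      if (j == 1L && n_path > 0L) {
        for (k in seq_len(n_path)) if (flags[i, k]) {
          evs <- as.integer(cfg$planted_pathways[[k]]$events)
          stay <- max(stay, length(evs))
          planted[[length(planted) + 1L]] <- evs
        }
      }
      day <- integer(0); eid <- integer(0)
      # planted pathway events: one per day, strictly increasing days
      for (evs in planted) {
        d <- sort(sample.int(stay, length(evs)))
        day <- c(day, d); eid <- c(eid, evs)
      }
      # admission-type marker on day 1 unless a planted admission event exists
      if (length(free_adm_types) > 0L &&
          !any(cat_of[as.character(eid)] == "admission")) {
        day <- c(day, 1L)
        eid <- c(eid, sample(free_adm_types, 1L))
      }
      # spontaneous causal events inside their windows
      counts <- numeric(length(effects))
      for (k in seq_along(effects)) {
        e <- effects[[k]]
        win <- max(1L, e$window[1]):min(stay, e$window[2])
        if (e$window[1] > stay) win <- integer(0)
        rate <- e$rate %||% 0
        if (length(win) > 0L && rate > 0) {
          kd <- rpois(length(win), rate)
          if (sum(kd) > 0L) {
            day <- c(day, rep(win, kd))
            eid <- c(eid, rep(as.integer(e$event_id), sum(kd)))
          }
        }
      }
      # uninformative noise
      if (cfg$noise_events_per_day > 0 && length(noise_pool) > 0L) {
        nd <- rpois(stay, cfg$noise_events_per_day)
        if (sum(nd) > 0L) {
          day <- c(day, rep(seq_len(stay), nd))
          eid <- c(eid, sample(noise_pool, sum(nd), replace = TRUE))
        }
      }
      # outcome from causal-event counts in-window
      for (k in seq_along(effects)) {
        e <- effects[[k]]
        in_win <- eid == e$event_id & day >= e$window[1] & day <= e$window[2]
        counts[k] <- sum(in_win)
      }
      eta <- cfg$outcome_model$intercept +
        sum(vapply(seq_along(effects),
                   function(k) effects[[k]]$weight * counts[k], numeric(1)))
      p <- plogis(eta)
      y <- rbinom(1L, 1L, p)
      prob_all[as.character(hadm)] <- p

      ord <- order(day, seq_along(day))
      day <- day[ord]; eid <- eid[ord]
      ts <- sprintf("%s 12:00:00", format(admit_date + (day - 1L)))
      pe[[j]] <- data.frame(
        subject_id = i, hadm_id = hadm, timestamp = ts, event_id = eid,
        event_value = 1, category = unname(cat_of[as.character(eid)]),
        stringsAsFactors = FALSE)
      adm_type <- eid[day == 1L & cat_of[as.character(eid)] == "admission"]
      pa[[j]] <- data.frame(
        hadm_id = hadm, subject_id = i,
        admit_time = sprintf("%s 07:00:00", format(admit_date)),
        discharge_time = sprintf("%s 20:00:00",
                                 format(admit_date + (stay - 1L))),
        death_time = NA_character_,
        admission_type = if (length(adm_type) > 0L)
          unname(lab_of[as.character(adm_type[1])]) else "Unknown",
        stringsAsFactors = FALSE)
      pl[[j]] <- data.frame(hadm_id = hadm, label = y)
      admit_date <- admit_date + stay + 29L  # next admission after a 30-day gap
    }
    ev_rows[[i]] <- do.call(rbind, pe)
    adm_rows[[i]] <- do.call(rbind, pa)
    lab_rows[[i]] <- do.call(rbind, pl)
  }

  events <- do.call(rbind, ev_rows); rownames(events) <- NULL
  admissions <- do.call(rbind, adm_rows); rownames(admissions) <- NULL
  labels <- do.call(rbind, lab_rows); rownames(labels) <- NULL
  if (n_path > 0L)
    colnames(flags) <- vapply(cfg$planted_pathways, function(p)
      paste(p$events, collapse = "->"), character(1))
  structure(
    list(events = events, admissions = admissions, vocabulary = vocab,
         labels = labels,
         truth = list(pathway_flags = flags, probability = prob_all,
                      causal_event_ids = causal_ids)),
    class = "synthetic_cohort")
}

#' Write a synthetic cohort to delimited text files
#'
#' Writes `events.csv`, `admissions.csv`, `vocabulary.csv`, `labels.csv`
#' (comma-separated, header row, ISO-8601-style timestamps) and a
#' `truth.json` ground-truth sidecar into `dir`.
#'
#' @param cohort A `synthetic_cohort` from [generate_cohort()].
#' @param dir Output directory (created if missing).
#' @return Invisibly, the named vector of file paths written.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(events = file.path(dir, "events.csv"),
             admissions = file.path(dir, "admissions.csv"),
             vocabulary = file.path(dir, "vocabulary.csv"),
             labels = file.path(dir, "labels.csv"),
             truth = file.path(dir, "truth.json"))
  write.csv(cohort$events, paths["events"], row.names = FALSE)
  write.csv(cohort$admissions, paths["admissions"], row.names = FALSE)
  write.csv(cohort$vocabulary, paths["vocabulary"], row.names = FALSE)
  write.csv(cohort$labels, paths["labels"], row.names = FALSE)
  truth <- cohort$truth
  jsonlite::write_json(
    list(pathway_flags = unclass(as.data.frame(truth$pathway_flags)),
         probability = as.list(truth$probability),
         causal_event_ids = truth$causal_event_ids),
    paths["truth"], auto_unbox = TRUE, digits = NA)
  invisible(paths)
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf(
    "synthetic EHR cohort: %d patients, %d admissions, %d events, %d vocab entries\n",
    length(unique(x$admissions$subject_id)), nrow(x$admissions),
    nrow(x$events), nrow(x$vocabulary)))
  cat(sprintf("outcome prevalence: %.3f\n", mean(x$labels$label)))
  invisible(x)
}
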