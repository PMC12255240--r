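#' Generate a synthetic demonstration cohort on disk
#'
#' Creates one directory per subject containing a subject profile
#' (`subject.json`), trial tables (TSV, one per movement condition: walking,
#' self-selected running, 3.0 m/s set-speed running, and a combined
#' sit-to-stand/stand-to-sit trace) and a ground-truth JSON sidecar per trial
#' (heel strikes or phase boundaries, stride duration, trial speed).
#' Anthropometry is drawn per gender around the cohort means (female 1.628 m,
#' 59.9 kg; male 1.751 m, 71.8 kg).
#'
#' @param dir Output directory.
#' @param n_per_gender Subjects per gender.
#' @param seed Integer seed; all subject and trial randomness derives from it.
#' @param n_trials Trials per movement condition.
#' @param model A `moment_arm_model`.
#' @return The subject directories, invisibly.
#' @export
make_demo_cohort <- function(dir, n_per_gender = 10, seed = 1L, n_trials = 1L,
                             model = load_model_config()) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(seed)
  counter <- 0L
  next_seed <- function() {
    counter <<- counter + 1L
    (abs(seed) %% 100000L) * 10000L + counter
  }
  subject_dirs <- character(0)
  for (gender in c("female", "male")) {
    hm <- model$group_mean_height_m[[gender]]
    mm <- if (gender == "female") 59.9 else 71.8
    hsd <- if (gender == "female") 0.059 else 0.067
    msd <- if (gender == "female") 7.2 else 8.7
    for (i in seq_len(n_per_gender)) {
      id <- sprintf("%s%02d", toupper(substr(gender, 1, 1)), i)
      height <- rnorm(1, hm, hsd)
      mass <- max(40, rnorm(1, mm, msd))
      d_cm <- model$default_dhat_cm[[gender]] / model$condylar_ratio[[gender]] +
        rnorm(1, 0, 0.15)
      sub <- subject_profile(gender, height, mass, d_cm = d_cm, model = model,
                             id = id)
      sdir <- file.path(dir, id)
      dir.create(sdir, showWarnings = FALSE)
      jsonlite::write_json(as.list(sub), file.path(sdir, "subject.json"),
                           auto_unbox = TRUE, digits = NA)
      for (mv in c("walk", "run_selfselect", "run_set")) {
        for (k in seq_len(n_trials)) {
          trial <- generate_gait_trial(
            gait_trial_spec(mv, subject = sub, seed = next_seed()), model)
          gt <- trial_ground_truth(trial)
          base <- file.path(sdir, sprintf("%s_%02d", mv, k))
          write_trial_tsv(trial, paste0(base, ".tsv"))
          jsonlite::write_json(
            list(movement = mv, heel_strikes = gt$heel_strikes,
                 stride_duration_s = gt$stride_duration_s,
                 speed_mps = gt$speed_mps),
            paste0(base, "_truth.json"), auto_unbox = TRUE, digits = NA)
        }
      }
      for (k in seq_len(n_trials)) {
        trial <- generate_sts_trace(
          sts_trial_spec(bodyweight_n = sub$bw_n, height_m = sub$height_m,
                         noise_sd = 0.005 * sub$bw_n, seed = next_seed()))
        gt <- trial_ground_truth(trial)
        base <- file.path(sdir, sprintf("sts_%02d", k))
        write_trial_tsv(trial, paste0(base, ".tsv"))
        jsonlite::write_json(
          list(movement = "sts",
               true_boundaries = as.list(gt$true_boundaries)),
          paste0(base, "_truth.json"), auto_unbox = TRUE, digits = NA)
      }
      subject_dirs <- c(subject_dirs, sdir)
    }
  }
  invisible(subject_dirs)
}

movement_from_filename <- function(path) {
  base <- basename(path)
  for (mv in c("run_selfselect", "run_set", "walk", "sts")) {
    if (startsWith(base, mv)) return(mv)
  }
  NA_character_
}

process_gait_trial <- function(trial, subject, model, movement) {
  cond <- condition_trial(trial, movement)
  events <- detect_heel_strikes(cond$fz, trial_rate(cond))
  strides <- extract_strides(events, cond)
  loads <- compute_joint_loads(cond, subject, model)
  mv_label <- if (movement == "walk") "walk" else movement
  purrr::map_dfr(seq_len(nrow(strides)), function(i) {
    extract_peaks(loads, strides[i, ], mv_label)
  })
}

process_sts_trial <- function(trial, subject, model) {
  cond <- condition_trial(trial, "sts")
  loads <- compute_joint_loads(cond, subject, model)
  out <- list()
  w_up <- detect_sit_to_stand(cond, subject$bw_n)
  if (nrow(w_up)) out$up <- extract_peaks(loads, w_up, "sit_to_stand")
  w_dn <- detect_stand_to_sit(cond, subject$bw_n)
  if (nrow(w_dn)) out$dn <- extract_peaks(loads, w_dn, "stand_to_sit")
  dplyr::bind_rows(out)
}

#' Run the full analysis pipeline over a cohort directory
#'
#' For every trial: condition channels (45 Hz GRF, movement-specific
#' kinematic cutoff), segment (heel-strike strides for gait; formula-defined
#' sit-to-stand/stand-to-sit phases), reduce net moments to muscle forces,
#' evaluate the medial contact force balance, and extract scaled peaks.
#' Per-subject values are means over all clean windows; male and female
#' groups are then compared per movement and variable with the gated
#' two-group test, Bonferroni-corrected over the declared family of tests,
#' and summarised as symmetric percent differences. A failing trial file is
#' logged by name and the remaining trials are still processed.
#'
#' @param cohort_dir Directory layout as produced by [make_demo_cohort()]:
#'   one sub-directory per subject with `subject.json` and trial TSVs.
#' @param out_dir Optional output directory for TSV result tables
#'   (`results.tsv`, `stats.tsv`, `percent_diff.tsv`, `log.tsv`).
#' @param model A `moment_arm_model`.
#' @param n_tests_family Number of tests in the Bonferroni family.
#' @return A list with tibbles `results` (per subject x movement x variable
#'   peaks), `speeds`, `stats`, `percent_diff`, and `log`.
#' @export
run_pipeline <- function(cohort_dir, out_dir = NULL,
                         model = load_model_config(), n_tests_family = 18) {
  subject_files <- list.files(cohort_dir, pattern = "^subject\\.json$",
                              recursive = TRUE, full.names = TRUE)
  if (!length(subject_files)) abort(paste0("no subjects found under ", cohort_dir))
  log <- list()
  note <- function(stage, trial, msg) {
    log[[length(log) + 1]] <<- tibble(stage = stage, trial = trial, message = msg)
  }
  results <- list()
  speeds <- list()
  for (sf in subject_files) {
    sj <- jsonlite::read_json(sf, simplifyVector = TRUE)
    subject <- subject_profile(sj$gender, sj$height_m, sj$mass_kg,
                               d_cm = sj$d_cm, model = model, id = sj$id)
    sdir <- dirname(sf)
    trials <- list.files(sdir, pattern = "\\.tsv$", full.names = TRUE)
    for (tf in trials) {
      mv <- movement_from_filename(tf)
      if (is.na(mv)) next
      peaks <- tryCatch({
        trial <- read_trial_tsv(tf)
        if (mv == "sts") {
          process_sts_trial(trial, subject, model)
        } else {
          process_gait_trial(trial, subject, model, mv)
        }
      }, error = function(e) {
        note("segment/reduce", basename(tf), conditionMessage(e))
        NULL
      })
      if (is.null(peaks) || !nrow(peaks)) next
      sid <- subject$id
      sgender <- subject$gender
      results[[length(results) + 1]] <- dplyr::mutate(
        peaks, subject = sid, gender = sgender, .before = 1)
      truth_file <- sub("\\.tsv$", "_truth.json", tf)
      if (mv != "sts" && file.exists(truth_file)) {
        tj <- jsonlite::read_json(truth_file, simplifyVector = TRUE)
        speeds[[length(speeds) + 1]] <- tibble(
          subject = sid, gender = sgender, movement = mv,
          speed_mps = tj$speed_mps %||% NA_real_)
      }
      note("trial", basename(tf), "ok")
    }
  }
  results <- dplyr::bind_rows(results)
  speeds <- dplyr::bind_rows(speeds)
  if (!nrow(results)) abort("no trial produced results")

  per_subject <- results |>
    dplyr::group_by(.data$subject, .data$gender, .data$movement,
                    .data$variable, .data$peak) |>
    dplyr::summarise(value = mean(.data$value), n_windows = dplyr::n(),
                     .groups = "drop")

  corrected <- bonferroni_alpha(0.05, n_tests_family)
  stats_tbl <- list()
  pct <- list()
  cells <- dplyr::distinct(per_subject, .data$movement, .data$variable, .data$peak)
  for (i in seq_len(nrow(cells))) {
    cell <- cells[i, ]
    vals <- dplyr::filter(per_subject, .data$movement == cell$movement,
                          .data$variable == cell$variable,
                          .data$peak == cell$peak)
    f <- vals$value[vals$gender == "female"]
    m <- vals$value[vals$gender == "male"]
    if (length(f) >= 1 && length(m) >= 1) {
      pct[[i]] <- dplyr::mutate(cell, percent_difference =
                                  percent_difference(mean(m), mean(f)))
    }
    if (length(f) >= 3 && length(m) >= 3) {
      cmp <- choose_and_run_test(f, m, tails = "one", direction = "greater",
                                 alpha = corrected$alpha_reported)
      stats_tbl[[i]] <- dplyr::mutate(
        cell, test = cmp$test, p = cmp$p, cohens_d = cmp$cohens_d,
        alpha = cmp$alpha, significant = cmp$significant)
    } else {
      note("stats", paste(cell$movement, cell$variable, cell$peak),
           "fewer than 3 subjects per gender; comparison skipped")
    }
  }
  speed_stats <- list()
  if (nrow(speeds)) {
    per_speed <- speeds |>
      dplyr::group_by(.data$subject, .data$gender, .data$movement) |>
      dplyr::summarise(speed_mps = mean(.data$speed_mps), .groups = "drop")
    for (mv in unique(per_speed$movement)) {
      f <- per_speed$speed_mps[per_speed$gender == "female" & per_speed$movement == mv]
      m <- per_speed$speed_mps[per_speed$gender == "male" & per_speed$movement == mv]
      if (length(f) >= 3 && length(m) >= 3) {
        tails <- if (mv == "walk") "two" else "one"
        cmp <- choose_and_run_test(m, f, tails = tails, direction = "greater",
                                   alpha = 0.05)
        speed_stats[[mv]] <- tibble(movement = mv, variable = "speed_mps",
                                    peak = "mean", test = cmp$test, p = cmp$p,
                                    cohens_d = cmp$cohens_d, alpha = 0.05,
                                    significant = cmp$significant)
      }
    }
  }
  stats_tbl <- dplyr::bind_rows(c(stats_tbl, speed_stats))
  pct <- dplyr::bind_rows(pct)
  log <- dplyr::bind_rows(log)

  out <- list(results = per_subject, speeds = speeds, stats = stats_tbl,
              percent_diff = pct, log = log,
              alpha_corrected = corrected)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    readr::write_tsv(per_subject, file.path(out_dir, "results.tsv"))
    if (nrow(stats_tbl)) readr::write_tsv(stats_tbl, file.path(out_dir, "stats.tsv"))
    if (nrow(pct)) readr::write_tsv(pct, file.path(out_dir, "percent_diff.tsv"))
    readr::write_tsv(log, file.path(out_dir, "log.tsv"))
  }
  out
}
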