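# CSV/YAML/JSON interchange. Dialect: UTF-8, comma-separated, header
# required, "." decimal; ids are 0-based integers in files and in memory.

#' Read and write trial-record CSV files
#'
#' Trials CSV columns: `participant_id, trial_index, statement_id,
#' true_face_id, chosen_face_id, correct`. On read, face ids are validated
#' against the design and the `correct` flag is recomputed from the ids and
#' cross-checked; any mismatch is an error naming the offending row.
#' Writing then reading reproduces the records exactly.
#'
#' @param path File path.
#' @param design A [wsw_design()] used for validation.
#'
#' @return `read_trials()`: a trial tibble. `write_trials()`: `path`,
#'   invisibly.
#' @export
read_trials <- function(path, design) {
  validate_wsw_design(design)
  header <- strsplit(readLines(path, n = 1L), ",")[[1]]
  required <- c("participant_id", "trial_index", "statement_id",
                "true_face_id", "chosen_face_id", "correct")
  missing <- setdiff(required, header)
  if (length(missing) > 0) {
    abort_wsw(
      paste0("Trial table is missing column(s): ", paste(missing, collapse = ", ")),
      "validation"
    )
  }
  trials <- readr::read_csv(path, col_types = readr::cols(
    participant_id = readr::col_integer(),
    trial_index = readr::col_integer(),
    statement_id = readr::col_integer(),
    true_face_id = readr::col_integer(),
    chosen_face_id = readr::col_integer(),
    correct = readr::col_logical(),
    .default = readr::col_guess()
  ))
  check_trials(trials)
  for (col in c("true_face_id", "chosen_face_id")) {
    bad <- which(!trials[[col]] %in% design$face_id)
    if (length(bad) > 0) {
      abort_wsw(sprintf("Row %d: unknown %s %s.", bad[1], col, trials[[col]][bad[1]]),
                "validation")
    }
  }
  recomputed <- trials$true_face_id == trials$chosen_face_id
  mismatch <- which(recomputed != trials$correct)
  if (length(mismatch) > 0) {
    abort_wsw(
      sprintf("Row %d: `correct` flag (%s) contradicts the face ids.",
              mismatch[1], trials$correct[mismatch[1]]),
      "validation"
    )
  }
  trials
}

#' @rdname read_trials
#' @param trials A trial tibble.
#' @export
write_trials <- function(trials, path) {
  check_trials(trials)
  readr::write_csv(trials, path)
  invisible(path)
}

#' Read and write face-design CSV files
#'
#' Faces CSV columns: `face_id` plus one 0/1 column per cue (optionally a
#' `label` column). The cue level labels (level 0 and level 1 of each cue)
#' are recorded as `# cue:` comment lines in the header so the code mapping
#' travels with the file. Non-factorial (unbalanced) face tables are
#' rejected on read with an explanatory error rather than silently
#' mis-scored.
#'
#' @param path File path.
#'
#' @return `read_faces()`: a [wsw_design()]. `write_faces()`: `path`,
#'   invisibly.
#' @export
read_faces <- function(path) {
  header <- grep("^#", readLines(path, n = 50L), value = TRUE)
  raw <- readr::read_csv(path, comment = "#", col_types = readr::cols())
  if (!"face_id" %in% names(raw)) {
    abort_wsw("Faces CSV must contain a `face_id` column.", "validation")
  }
  cue_cols <- setdiff(names(raw), c("face_id", "label"))
  if (length(cue_cols) == 0) abort_wsw("Faces CSV has no cue columns.", "validation")
  for (col in cue_cols) {
    if (!all(raw[[col]] %in% c(0L, 1L))) {
      abort_wsw(sprintf("Cue column `%s` must contain only 0/1 codes.", col),
                "validation")
    }
  }
  cues <- parse_cue_comments(header, cue_cols)
  design <- new_wsw_design(
    dplyr::mutate(tibble::as_tibble(raw),
                  dplyr::across(dplyr::all_of(c("face_id", cue_cols)), as.integer)),
    cues
  )
  if (anyDuplicated(design$face_id)) {
    abort_wsw("Duplicate face_id values in faces CSV.", "validation")
  }
  if (!is_factorial_design(design)) {
    abort_wsw(
      paste0("Face table is not a balanced full factorial: with ", length(cue_cols),
             " binary cues every attribute combination must appear exactly once."),
      "validation"
    )
  }
  design
}

parse_cue_comments <- function(header, cue_cols) {
  cues <- stats::setNames(
    replicate(length(cue_cols), c("0", "1"), simplify = FALSE),
    cue_cols
  )
  # lines like "# cue: sex levels: female=0,male=1"
  for (line in grep("^# cue:", header, value = TRUE)) {
    m <- regmatches(line, regexec("^# cue: (\\S+) levels: ([^=]+)=0,([^=]+)=1", line))[[1]]
    if (length(m) == 4 && m[2] %in% cue_cols) {
      cues[[m[2]]] <- c(m[3], m[4])
    }
  }
  cues
}

#' @rdname read_faces
#' @param design A [wsw_design()].
#' @export
write_faces <- function(design, path) {
  validate_wsw_design(design)
  cues <- cue_levels(design)
  meta <- vapply(names(cues), function(nm) {
    sprintf("# cue: %s levels: %s=0,%s=1", nm, cues[[nm]][1], cues[[nm]][2])
  }, character(1))
  writeLines(meta, path)
  readr::write_csv(tibble::as_tibble(design), path, append = TRUE, col_names = TRUE)
  invisible(path)
}

#' Read and write categorization-score CSV files
#'
#' Scores CSV: one row per participant with `participant_id`, `n_errors`,
#' and per cue `<cue>_within`, `<cue>_between`, `<cue>_score`. Zero-error
#' participants keep their rows with empty score fields.
#'
#' @param path File path.
#'
#' @return `read_scores()`: a tibble. `write_scores()`: `path`, invisibly.
#' @export
read_scores <- function(path) {
  readr::read_csv(path, col_types = readr::cols(
    participant_id = readr::col_integer(),
    n_errors = readr::col_integer(),
    .default = readr::col_double()
  ))
}

#' @rdname read_scores
#' @param scores A [categorization_scores()] table.
#' @export
write_scores <- function(scores, path) {
  readr::write_csv(tibble::as_tibble(scores), path)
  invisible(path)
}

#' Read participant covariates
#'
#' Covariates CSV: `participant_id` plus arbitrary covariate columns, e.g.
#' `exposure_frequency` (1-5), `acquaintance` (none/family/coworker),
#' `self_scar` (0/1), `age`.
#'
#' @param path File path.
#' @return A tibble keyed by `participant_id`.
#' @export
read_covariates <- function(path) {
  cov <- readr::read_csv(path, col_types = readr::cols(
    participant_id = readr::col_integer(),
    .default = readr::col_guess()
  ))
  if (!"participant_id" %in% names(cov)) {
    abort_wsw("Covariates CSV must contain `participant_id`.", "validation")
  }
  cov
}

#' Read a cohort-generator configuration from YAML or JSON
#'
#' The file mirrors [wsw_config()] field for field
#' (`n_participants`, `trials_per_participant`, `accuracy_shape1`,
#' `accuracy_shape2`, `weight_means`, `weight_cov`, `seed`); absent fields
#' take the defaults.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return A [wsw_config()].
#' @export
read_wsw_config <- function(path) {
  parsed <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  known <- c("n_participants", "trials_per_participant", "accuracy_shape1",
             "accuracy_shape2", "weight_means", "weight_cov", "seed")
  unknown <- setdiff(names(parsed), known)
  if (length(unknown) > 0) {
    abort_wsw(paste0("Unknown config field(s): ", paste(unknown, collapse = ", ")),
              "config")
  }
  if (!is.null(parsed$weight_means)) parsed$weight_means <- unlist(parsed$weight_means)
  if (!is.null(parsed$weight_cov)) {
    parsed$weight_cov <- matrix(unlist(parsed$weight_cov),
                                nrow = length(parsed$weight_means), byrow = TRUE)
  }
  do.call(wsw_config, parsed)
}
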