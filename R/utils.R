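# Internal helpers shared across modules.

abort_wsw <- function(message, class) {
  rlang::abort(message, class = paste0("wsw_error_", class))
}

#' @noRd
cue_names <- function(design) {
  names(attr(design, "cues"))
}

cue_levels <- function(design) {
  attr(design, "cues")
}

# 2^k x k integer matrix of cue codes, rows in design order
cue_code_matrix <- function(design) {
  m <- as.matrix(design[, cue_names(design)])
  storage.mode(m) <- "integer"
  rownames(m) <- design$face_id
  m
}

face_index <- function(design, face_id, arg = "face_id") {
  idx <- match(face_id, design$face_id)
  if (anyNA(idx)) {
    bad <- unique(face_id[is.na(idx)])
    abort_wsw(
      sprintf("Unknown %s: %s", arg, paste(bad, collapse = ", ")),
      "lookup"
    )
  }
  idx
}

# Evaluate `code` under a temporary RNG state seeded with `seed`; the caller's
# stream is restored afterwards. seed = NULL runs on the current stream.
with_seed <- function(seed, code) {
  if (is.null(seed)) {
    return(force(code))
  }
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1L)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  code
}

# Exact rational numbers back combinatorial baselines; stored reduced, with the
# float value as the scalar payload.
new_rational <- function(numerator, denominator) {
  stopifnot(denominator != 0)
  g <- gcd_int(abs(numerator), abs(denominator))
  if (g > 0) {
    numerator <- numerator / g
    denominator <- denominator / g
  }
  if (denominator < 0) {
    numerator <- -numerator
    denominator <- -denominator
  }
  structure(
    numerator / denominator,
    numerator = numerator,
    denominator = denominator,
    class = "wsw_rational"
  )
}

gcd_int <- function(a, b) {
  while (b != 0) {
    tmp <- b
    b <- a %% b
    a <- tmp
  }
  a
}

#' @export
print.wsw_rational <- function(x, ...) {
  cat(
    sprintf(
      "%d/%d = %.6g\n",
      attr(x, "numerator"), attr(x, "denominator"), as.numeric(x)
    )
  )
  invisible(x)
}

#' @export
format.wsw_rational <- function(x, ...) {
  sprintf("%d/%d", attr(x, "numerator"), attr(x, "denominator"))
}

check_trials <- function(trials) {
  required <- c(
    "participant_id", "trial_index", "statement_id",
    "true_face_id", "chosen_face_id", "correct"
  )
  missing <- setdiff(required, names(trials))
  if (length(missing) > 0) {
    abort_wsw(
      paste0("Trial table is missing column(s): ", paste(missing, collapse = ", ")),
      "validation"
    )
  }
  invisible(trials)
}
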