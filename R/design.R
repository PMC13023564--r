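#' Binary cue definitions for a WSW face design
#'
#' A cue is a binary social attribute of a stimulus face (for example sex,
#' race, or the presence of a facial scar). Each cue has exactly two levels;
#' the first level is coded 0 and the second 1 throughout the package.
#'
#' @param ... Named arguments, one per cue. Each value is a character vector
#'   of exactly two level labels, e.g. `sex = c("female", "male")`.
#'
#' @return A named list of two-level character vectors, suitable for
#'   [wsw_design()].
#'
#' @details The default cue set mirrors the classic 2 x 2 x 2 Who-Said-What
#'   design crossing sex (female/male), race (Black/White) and facial scar
#'   (absent/present).
#'
#' @examples
#' wsw_cues()
#' wsw_cues(sex = c("female", "male"))
#' @export
wsw_cues <- function(...) {
  cues <- list(...)
  if (length(cues) == 0) {
    cues <- list(
      sex = c("female", "male"),
      race = c("Black", "White"),
      scar = c("absent", "present")
    )
  }
  validate_cues(cues)
  cues
}

validate_cues <- function(cues) {
  if (length(cues) < 1 || length(cues) > 8) {
    abort_wsw("Between 1 and 8 cues are supported.", "design")
  }
  nms <- names(cues)
  if (is.null(nms) || any(nms == "")) {
    abort_wsw("Every cue must be named.", "design")
  }
  if (anyDuplicated(nms)) {
    abort_wsw("Cue names must be unique.", "design")
  }
  bad <- nms[vapply(cues, function(x) length(x) != 2L || anyDuplicated(x) > 0, logical(1))]
  if (length(bad) > 0) {
    abort_wsw(
      paste0("Each cue needs exactly 2 distinct levels; offending cue(s): ",
             paste(bad, collapse = ", ")),
      "design"
    )
  }
  invisible(cues)
}

#' Build the balanced full-factorial face set
#'
#' Fully crosses `k` binary cues into `2^k` stimulus faces, one face per
#' attribute combination. Face ids are 0-based integers assigned by binary
#' counting over the cue order (the first cue is the most significant bit),
#' which makes ids deterministic and format-independent.
#'
#' @param cues A named list of binary cues, as returned by [wsw_cues()].
#'
#' @return A tibble of class `wsw_design` with one row per face: `face_id`
#'   plus one 0/1 column per cue. The cue level labels are kept in the
#'   `cues` attribute.
#'
#' @examples
#' design <- wsw_design()
#' design
#' @export
wsw_design <- function(cues = wsw_cues()) {
  validate_cues(cues)
  k <- length(cues)
  # expand.grid varies its first factor fastest; reverse so the LAST cue is
  # the least significant bit (binary counting over cue order).
  grid <- expand.grid(rev(replicate(k, 0:1, simplify = FALSE)),
                      KEEP.OUT.ATTRS = FALSE)
  grid <- grid[, rev(seq_len(k)), drop = FALSE]
  names(grid) <- names(cues)
  out <- tibble::as_tibble(grid)
  out <- dplyr::mutate(out, dplyr::across(dplyr::everything(), as.integer))
  out <- dplyr::bind_cols(
    tibble::tibble(face_id = 0:(2^k - 1L)),
    out
  )
  new_wsw_design(out, cues)
}

new_wsw_design <- function(faces, cues) {
  structure(
    faces,
    cues = cues,
    class = c("wsw_design", class(tibble::tibble()))
  )
}

validate_wsw_design <- function(design) {
  if (!inherits(design, "wsw_design")) {
    abort_wsw("`design` must be a `wsw_design` object (see `wsw_design()`).", "design")
  }
  if (anyDuplicated(design$face_id)) {
    abort_wsw("Face ids must be unique.", "design")
  }
  invisible(design)
}

# TRUE iff the design is the complete crossing of its cues (each combination
# exactly once)
is_factorial_design <- function(design) {
  codes <- cue_code_matrix(design)
  k <- ncol(codes)
  if (nrow(codes) != 2^k) return(FALSE)
  key <- as.vector(codes %*% 2^((k - 1):0))
  length(unique(key)) == 2^k
}

#' Per-cue match vector between two faces
#'
#' For each cue, reports whether two faces carry the same code. A memory
#' error whose chosen face matches the true speaker on a cue is a
#' within-category error for that cue.
#'
#' @param design A [wsw_design()].
#' @param face_a,face_b Face ids present in `design`.
#'
#' @return A named logical vector, one element per cue.
#'
#' @examples
#' design <- wsw_design()
#' match_vector(design, 0, 1)
#' @export
match_vector <- function(design, face_a, face_b) {
  validate_wsw_design(design)
  codes <- cue_code_matrix(design)
  ia <- face_index(design, face_a, "face_a")
  ib <- face_index(design, face_b, "face_b")
  out <- codes[ia, ] == codes[ib, ]
  names(out) <- cue_names(design)
  out
}

#' Probability that two random faces share at least one cue
#'
#' Under uniform random confusion, the chance that two distinct faces drawn
#' from the design share at least one binary attribute. For a balanced full
#' factorial on `k` binary cues the closed form is `1 - 1/(2^k - 1)`: the
#' only face sharing nothing with a given face is its full complement. For
#' the 2 x 2 x 2 design this baseline is 6/7 (about 85.7%).
#'
#' @param design A [wsw_design()].
#' @param method `"closed_form"` (full-factorial designs only),
#'   `"enumerate"` (exhaustive unordered-pair count, any design), or
#'   `"auto"` (closed form when available, with both routes agreeing
#'   exactly by construction).
#'
#' @return A `wsw_rational`: a numeric probability carrying exact
#'   `numerator`/`denominator` attributes.
#'
#' @examples
#' feature_overlap_probability(wsw_design())
#' @export
feature_overlap_probability <- function(design,
                                        method = c("auto", "closed_form", "enumerate")) {
  validate_wsw_design(design)
  method <- match.arg(method)
  factorial <- is_factorial_design(design)
  if (method == "closed_form" && !factorial) {
    abort_wsw(
      "Closed form requires a balanced full-factorial design; use method = \"enumerate\".",
      "design"
    )
  }
  if (method == "auto") method <- if (factorial) "closed_form" else "enumerate"
  if (method == "closed_form") {
    k <- length(cue_names(design))
    n_alt <- 2^k - 1L
    return(new_rational(n_alt - 1L, n_alt))
  }
  codes <- cue_code_matrix(design)
  n <- nrow(codes)
  if (n < 2) abort_wsw("Need at least two faces.", "design")
  pairs <- utils::combn(n, 2)
  share <- vapply(
    seq_len(ncol(pairs)),
    function(j) any(codes[pairs[1, j], ] == codes[pairs[2, j], ]),
    logical(1)
  )
  new_rational(sum(share), ncol(pairs))
}

#' Expected categorization score under uniform random guessing
#'
#' The proportional categorization score `(within - between) / total` has a
#' negative chance expectation in a balanced factorial design: among the
#' `2^k - 1` error alternatives, `2^(k-1) - 1` share a given cue with the
#' true face while `2^(k-1)` do not. For `k = 3` the expectation is `-1/7`
#' (about -0.143) for every cue. No base-rate correction is applied to
#' observed scores; this baseline is reported alongside them.
#'
#' @param design A balanced full-factorial [wsw_design()].
#' @param cue Optional cue name; the value is identical for every cue of a
#'   balanced design, so this argument only validates the name.
#'
#' @return A `wsw_rational` (exact fraction with float payload).
#'
#' @examples
#' expected_random_score(wsw_design())
#' @export
expected_random_score <- function(design, cue = NULL) {
  validate_wsw_design(design)
  if (!is_factorial_design(design)) {
    abort_wsw("Analytic chance score requires a balanced full-factorial design.", "design")
  }
  if (!is.null(cue) && !cue %in% cue_names(design)) {
    abort_wsw(sprintf("Unknown cue: %s", cue), "lookup")
  }
  k <- length(cue_names(design))
  same <- 2^(k - 1L) - 1L
  diff <- 2^(k - 1L)
  new_rational(same - diff, same + diff)
}

#' Default first-person statement texts
#'
#' Twenty-four short, everyday, present-tense first-person statements used as
#' default verbal stimuli for simulated cohorts (three per face in the
#' 2 x 2 x 2 design). They are synthetic package fixtures in the style of
#' WSW verbal material, not a published stimulus set.
#'
#' @return A character vector of length 24.
#' @export
wsw_statements <- function() {
  c(
    "I read poetry.", "I have a pet dog.", "I jog every morning.",
    "I bake bread on weekends.", "I collect old postcards.", "I ride my bike to work.",
    "I grow tomatoes in my garden.", "I play chess online.", "I drink tea with breakfast.",
    "I paint with watercolors.", "I listen to jazz records.", "I do the crossword daily.",
    "I swim at the local pool.", "I cook dinner most nights.", "I keep a journal.",
    "I birdwatch in the park.", "I knit scarves in winter.", "I play the guitar.",
    "I volunteer at the library.", "I take photos of sunsets.", "I build model trains.",
    "I go hiking on Saturdays.", "I make my own coffee.", "I read the newspaper daily."
  )
}

#' Randomized face-statement encoding plan
#'
#' Assigns statements to faces for the encoding phase, each face receiving
#' the same number of statements (`per_face`). The assignment is randomized;
#' a fixed `seed` gives a reproducible plan.
#'
#' @param design A [wsw_design()].
#' @param statements Character vector of statement texts, of length
#'   `nrow(design) * per_face`. Defaults to [wsw_statements()] when that
#'   length is 24.
#' @param per_face Number of statements paired with each face (3 in the
#'   classic design, giving 24 pairings over 8 faces).
#' @param seed Optional integer seed for the assignment. The caller's RNG
#'   stream is left untouched.
#'
#' @return A tibble with columns `statement_id` (0-based), `face_id`, `text`.
#'
#' @examples
#' plan <- encoding_plan(wsw_design(), seed = 1)
#' dplyr::count(plan, face_id)
#' @export
encoding_plan <- function(design, statements = NULL, per_face = 3L, seed = NULL) {
  validate_wsw_design(design)
  n_needed <- nrow(design) * per_face
  if (is.null(statements)) {
    if (n_needed == 24L) {
      statements <- wsw_statements()
    } else {
      statements <- sprintf("Statement %d.", seq_len(n_needed))
    }
  }
  if (length(statements) != n_needed) {
    abort_wsw(
      sprintf(
        "Need exactly %d statements (%d faces x %d per face), got %d.",
        n_needed, nrow(design), per_face, length(statements)
      ),
      "design"
    )
  }
  faces <- with_seed(seed, sample(rep(design$face_id, each = per_face)))
  tibble::tibble(
    statement_id = 0:(n_needed - 1L),
    face_id = faces,
    text = statements
  )
}
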