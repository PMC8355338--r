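# The mental-state-attribution task: a 3 x 3 scene of discrete locations.
#
# Location 1 is the central fixation. Locations 2 (eyes) and 3 (mouth)
# belong to the target face (top-left quadrant); locations 4/5 are the eyes
# and mouth of the first context face (top-right) and 6/7 of the second
# (bottom-left). Locations 8 and 9 report "happy" and "sad" respectively.
#
# Hidden-state factors: social context (happy, sad, two incoherent
# arrangements), target face (emotion x ambiguity, joined into one factor
# because a single target feature carries joint evidence about both), and
# fixated location. Outcome modalities: facial expression (5 levels),
# fixated location (9), feedback (null/correct/incorrect).

context_levels <- function() c("happy", "sad", "incoherent_a", "incoherent_b")
target_levels <- function() {
  c("happy_unambiguous", "sad_unambiguous", "happy_ambiguous", "sad_ambiguous")
}
expression_levels <- function() {
  c("narrow_eyelids", "pulled_eyebrows", "exposed_teeth", "covered_teeth", "null")
}
feedback_levels <- function() c("null", "correct", "incorrect")

TARGET_LOCS <- 2:3
CONTEXT_LOCS <- 4:7
REPORT_LOCS <- c(happy = 8L, sad = 9L)

# expression shown by a face of a given kind at a given part
# happy: narrow eyelids + exposed teeth; sad: pulled-together eyebrows +
# covered teeth; ambiguous: pulled-together eyebrows + exposed teeth.
face_expression <- function(kind, part) {
  switch(kind,
    happy = if (part == "eyes") 1L else 3L,
    sad = if (part == "eyes") 2L else 4L,
    ambiguous = if (part == "eyes") 2L else 3L,
    stop_config("unknown face kind: ", kind))
}

target_face_kind <- function(target_level) {
  switch(target_level,
    happy_unambiguous = "happy",
    sad_unambiguous = "sad",
    happy_ambiguous = "ambiguous",
    sad_ambiguous = "ambiguous")
}

target_emotion <- function(target_level) {
  if (target_level %in% c("happy_unambiguous", "happy_ambiguous")) "happy" else "sad"
}

# emotions of the two context faces (first = top-right, second = bottom-left)
context_face_kinds <- function(context_level) {
  switch(context_level,
    happy = c("happy", "happy"),
    sad = c("sad", "sad"),
    incoherent_a = c("happy", "sad"),
    incoherent_b = c("sad", "happy"),
    stop_config("unknown context level: ", context_level))
}

# Ground-truth likelihood and transition arrays shared by the generative
# process and (as the base, precision-1 case) the generative model.
build_task_arrays <- function() {
  ctx <- context_levels()
  tgt <- target_levels()
  ns <- c(length(ctx), length(tgt), 9L)
  A_fe <- array(0, dim = c(5L, ns),
                dimnames = list(expression_levels(), ctx, tgt, NULL))
  A_wh <- array(0, dim = c(9L, ns), dimnames = list(NULL, ctx, tgt, NULL))
  A_fb <- array(0, dim = c(3L, ns),
                dimnames = list(feedback_levels(), ctx, tgt, NULL))

  for (i in seq_along(ctx)) {
    faces <- context_face_kinds(ctx[i])
    for (j in seq_along(tgt)) {
      kind <- target_face_kind(tgt[j])
      emo <- target_emotion(tgt[j])
      for (l in 1:9) {
        expr <- if (l == 2L) face_expression(kind, "eyes")
          else if (l == 3L) face_expression(kind, "mouth")
          else if (l == 4L) face_expression(faces[1L], "eyes")
          else if (l == 5L) face_expression(faces[1L], "mouth")
          else if (l == 6L) face_expression(faces[2L], "eyes")
          else if (l == 7L) face_expression(faces[2L], "mouth")
          else 5L  # central fixation and report locations show no face
        A_fe[expr, i, j, l] <- 1
        A_wh[l, i, j, l] <- 1
        fb <- if (l == REPORT_LOCS[["happy"]]) {
          if (emo == "happy") 2L else 3L
        } else if (l == REPORT_LOCS[["sad"]]) {
          if (emo == "sad") 2L else 3L
        } else 1L
        A_fb[fb, i, j, l] <- 1
      }
    }
  }

  ident <- function(k) {
    arr <- array(0, dim = c(k, k, 9L))
    for (a in 1:9) arr[, , a] <- diag(k)
    arr
  }
  B_wh <- array(0, dim = c(9L, 9L, 9L))
  for (a in 1:9) B_wh[a, , a] <- 1  # saccade to `a` from anywhere

  list(A = list(facial = A_fe, where = A_wh, feedback = A_fb),
       B = list(context = ident(4L), target = ident(4L), where = B_wh),
       n_states = ns, n_out = c(5L, 9L, 3L))
}

#' Construct the ground-truth generative process of a trial
#'
#' Fixes the true social context, target-face emotion and target-face type,
#' and carries the deterministic likelihood mappings that emit observations:
#' facial expressions at face locations (null at the centre and at the
#' report locations), the fixated location itself, and feedback that is
#' correct when the reported emotion (location 8 = happy, 9 = sad) matches
#' the true target-face emotion and incorrect otherwise; all other locations
#' return null feedback.
#'
#' @param context `"happy"`, `"sad"`, `"incoherent_a"` or `"incoherent_b"`
#'   (the incoherent arrangements differ only by which context face is the
#'   happy one).
#' @param emotion true target-face emotion, `"happy"` or `"sad"`.
#' @param type `"unambiguous"` or `"ambiguous"` (ambiguous faces show
#'   pulled-together eyebrows with exposed teeth whatever their emotion).
#' @return an object of class `generative_process`.
#' @export
build_generative_process <- function(context = "happy", emotion = "happy",
                                     type = "ambiguous") {
  if (!context %in% context_levels()) {
    stop("invalid context level: ", context, call. = FALSE)
  }
  if (!emotion %in% c("happy", "sad")) {
    stop("invalid emotion: ", emotion, call. = FALSE)
  }
  if (!type %in% c("unambiguous", "ambiguous")) {
    stop("invalid target-face type: ", type, call. = FALSE)
  }
  arr <- build_task_arrays()
  target <- paste(emotion, type, sep = "_")
  structure(list(
    A = arr$A, B = arr$B,
    context = context, emotion = emotion, type = type,
    colour = condition_colour(context, emotion, type),
    context_index = match(context, context_levels()),
    target_index = match(target, target_levels()),
    start_where = 1L,
    feedback_modality = 3L, feedback_null = 1L, feedback_correct = 2L,
    report_locations = REPORT_LOCS,
    n_states = arr$n_states, n_out = arr$n_out
  ), class = "generative_process")
}

# Observation emitted by the process at a fixated location. Columns are
# one-hot, so the draw is deterministic; sampling is kept for generality.
emit_observation <- function(process, where) {
  i <- process$context_index
  j <- process$target_index
  vapply(seq_along(process$A), function(m) {
    col <- process$A[[m]][, i, j, where]
    if (max(col) > 1 - 1e-12) which.max(col)
    else sample.int(length(col), 1L, prob = col)
  }, integer(1))
}

#' @export
print.generative_process <- function(x, ...) {
  cat("<generative_process> ", x$context, " context, ", x$emotion, " ",
      x$type, " target (", x$colour, " trial)\n", sep = "")
  invisible(x)
}

#' Construct the agent's generative model of the task
#'
#' The base model mirrors the generative process exactly: identical
#' likelihood arrays, identity transitions for context and target face, a
#' fully controllable fixation state (one depth-one policy per location),
#' uniform priors over context and target face (so the two incoherent
#' arrangements jointly carry probability 0.5), a delta prior on the central
#' fixation, zero preferences everywhere except the feedback modality
#' (null 0, correct +0.5, incorrect -10), and pass-through precision
#' (exponent 1) on every likelihood column. Agent variants are derived from
#' it with [make_agent_variant()].
#'
#' @param horizon trial length in time steps.
#' @param learning_rate,max_iters,tol,epsilon numerical settings of the
#'   variational scheme; see [generative_model()].
#' @return a `generative_model` with 4 x 4 x 9 = 144 hidden-state
#'   combinations and outcome modalities of 5, 9 and 3 levels.
#' @export
build_generative_model <- function(horizon = 8L, learning_rate = 0.25,
                                   max_iters = 64L, tol = 1e-4,
                                   epsilon = 1e-16) {
  arr <- build_task_arrays()
  D <- list(context = rep(0.25, 4L), target = rep(0.25, 4L),
            where = c(1, rep(0, 8L)))
  C <- list(facial = rep(0, 5L), where = rep(0, 9L),
            feedback = c(0, 0.5, -10))
  m <- generative_model(A = arr$A, B = arr$B, C = C, D = D,
                        policies = matrix(1:9, ncol = 1L),
                        horizon = horizon, learning_rate = learning_rate,
                        max_iters = max_iters, tol = tol, epsilon = epsilon)
  m$variant <- list(name = "base", z = NULL, z_tf = NULL, z_sc = NULL)
  m
}

#' Derive an agent variant by reshaping likelihood precisions
#'
#' All variants share the base likelihoods and differ only in the precision
#' exponents on the facial-expression modality (the fixated-location and
#' feedback mappings always keep precision 1):
#'
#' * `"contextualising"`: the mapping from an ambiguously *sad* target face
#'   to facial expressions gets precision `z` (default 0) under the happy
#'   context, and the ambiguously *happy* face gets `z` under the sad
#'   context, at all face locations (2-7). With `z = 0` those expressions
#'   become uninformative, so an ambiguous face can only be attributed the
#'   context-consistent emotion — contextual perception.
#' * `"non_contextualising"`: every precision is 1, the pass-through
#'   encoding of an arbitrarily high precision on one-hot columns; the
#'   model equals the base model exactly.
#' * `"local_viewer"`: the context-face locations 4-7 get precision `z_sc`
#'   (default 0) for every state combination and the target-face locations
#'   2-3 get `z_tf` (default 1). The imbalance makes social cues
#'   uninformative, producing the localised scan paths used to model
#'   schizophrenia-like viewing.
#' * `"global_viewer"`: `z_sc = z_tf = 1`; identical to the base model.
#'
#' Supplying `z_tf`/`z_sc` together with the contextualising scheme
#' multiplies the exponents entry-wise.
#'
#' @param model the base task model from [build_generative_model()].
#' @param variant one of `"contextualising"`, `"non_contextualising"`,
#'   `"local_viewer"`, `"global_viewer"`.
#' @param z,z_tf,z_sc optional non-negative numeric overrides of the
#'   variant's precisions.
#' @return the model with the variant's precision scheme applied.
#' @export
make_agent_variant <- function(model, variant = c("contextualising",
                                                  "non_contextualising",
                                                  "local_viewer",
                                                  "global_viewer"),
                               z = NULL, z_tf = NULL, z_sc = NULL) {
  variant <- match.arg(variant)
  for (val in c(z, z_tf, z_sc)) {
    if (!is.null(val) && (!is.numeric(val) || val < 0)) {
      stop("precision values must be non-negative numbers", call. = FALSE)
    }
  }
  zeta_fe <- array(1, dim = model$n_states)
  if (variant == "contextualising") {
    z <- z %||% 0
    i_happy <- match("happy", context_levels())
    i_sad <- match("sad", context_levels())
    j_sa <- match("sad_ambiguous", target_levels())
    j_ha <- match("happy_ambiguous", target_levels())
    face_locs <- c(TARGET_LOCS, CONTEXT_LOCS)
    zeta_fe[i_happy, j_sa, face_locs] <- z
    zeta_fe[i_sad, j_ha, face_locs] <- z
  }
  if (variant == "local_viewer" || !is.null(z_tf) || !is.null(z_sc)) {
    if (variant %in% c("local_viewer")) {
      z_sc <- z_sc %||% 0
      z_tf <- z_tf %||% 1
    } else {
      z_sc <- z_sc %||% 1
      z_tf <- z_tf %||% 1
    }
    loc_scale <- rep(1, 9L)
    loc_scale[CONTEXT_LOCS] <- z_sc
    loc_scale[TARGET_LOCS] <- z_tf
    for (l in 1:9) zeta_fe[, , l] <- zeta_fe[, , l] * loc_scale[l]
  }
  zeta <- list(zeta_fe,
               array(1, dim = model$n_states),
               array(1, dim = model$n_states))
  model <- set_precision(model, zeta)
  model$variant <- list(name = variant, z = z, z_tf = z_tf, z_sc = z_sc)
  model
}

#' Classify a trial cell by context congruence and feature coherence
#'
#' @param context,emotion,type condition levels as in
#'   [build_generative_process()].
#' @return `"green"` (unambiguous face, affectively congruent coherent
#'   context), `"red"` (unambiguous, incongruent), `"blue"` (ambiguous face
#'   in a coherent context) or `"grey"` (any face in an incoherent context).
#' @export
condition_colour <- function(context, emotion, type) {
  if (context %in% c("incoherent_a", "incoherent_b")) return("grey")
  if (type == "ambiguous") return("blue")
  if (context == emotion) "green" else "red"
}

#' Enumerate the 16 task conditions
#'
#' Crosses the four context levels with target-face emotion and type and
#' labels each cell by its congruence/coherence class.
#'
#' @return a data frame with columns `context`, `emotion`, `type`, `colour`.
#' @export
enumerate_conditions <- function() {
  grid <- expand.grid(context = context_levels(),
                      emotion = c("happy", "sad"),
                      type = c("unambiguous", "ambiguous"),
                      stringsAsFactors = FALSE)
  grid$colour <- mapply(condition_colour, grid$context, grid$emotion, grid$type)
  grid[order(match(grid$colour, c("green", "red", "blue", "grey"))), ,
       drop = FALSE] -> grid
  rownames(grid) <- NULL
  grid
}
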