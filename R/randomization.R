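#' Default minimization factors
#'
#' The trial balances age, biological sex, and NYHA functional class.
#' Age must be discretized to act as a minimization factor; the default
#' splits at 60 years (about the middle of a 41-72 year cohort) and is
#' configurable.
#'
#' @param age_cut Age (years) at which the two age strata split.
#' @return Named list of factor levels, with the cut point attached as
#'   attribute `age_cut`.
#' @export
default_allocation_factors <- function(age_cut = 60) {
  f <- list(
    age = c(sprintf("<%d", age_cut), sprintf(">=%d", age_cut)),
    sex = c("male", "female"),
    nyha = c("I", "II", "III")
  )
  attr(f, "age_cut") <- age_cut
  f
}

#' Initialize a minimization allocation state
#'
#' Holds the running per-(factor, level, arm) enrollment counts used by
#' the Pocock-Simon biased-coin minimization rule, together with the base
#' probability with which the imbalance-minimizing arm is chosen (0.7 in
#' this trial; 0.5 < p <= 1).
#'
#' @param arms Character vector of two arm labels.
#' @param factors Named list of level vectors, e.g.
#'   [default_allocation_factors()].
#' @param base_probability Probability of assigning the arm that
#'   minimizes imbalance when the two candidate scores differ.
#' @return An `allocation_state` object.
#' @export
allocation_state <- function(arms = c("intervention", "control"),
                             factors = default_allocation_factors(),
                             base_probability = 0.7) {
  stopifnot(length(arms) == 2L, !anyDuplicated(arms))
  if (base_probability <= 0.5 || base_probability > 1) {
    stop("base_probability must lie in (0.5, 1]")
  }
  counts <- lapply(factors, function(levels) {
    matrix(0L, nrow = length(levels), ncol = 2L,
           dimnames = list(levels, arms))
  })
  structure(
    list(arms = arms, factors = factors, counts = counts,
         base_probability = base_probability, n_assigned = 0L,
         log = list()),
    class = "allocation_state"
  )
}

check_levels <- function(state, patient_levels) {
  patient_levels <- as.list(patient_levels)
  for (f in names(state$factors)) {
    lev <- patient_levels[[f]]
    if (is.null(lev)) stop("missing level for factor ", f)
    if (!lev %in% state$factors[[f]]) {
      stop(sprintf("unknown level '%s' for factor %s", lev, f))
    }
  }
  patient_levels
}

#' Marginal imbalance score after a hypothetical assignment
#'
#' Implements the Pocock-Simon "range" imbalance with equal factor
#' weights: for each factor, add the patient to `candidate_arm` at their
#' level and take the range (max minus min) of that level's counts across
#' arms; the score is the sum over factors. Smaller is better balanced.
#'
#' @param state An [allocation_state()].
#' @param patient_levels Named list/vector giving one level per factor.
#' @param candidate_arm Arm label to evaluate.
#' @return Numeric imbalance score.
#' @export
imbalance_if_assigned <- function(state, patient_levels, candidate_arm) {
  stopifnot(inherits(state, "allocation_state"))
  if (!candidate_arm %in% state$arms) stop("unknown arm: ", candidate_arm)
  patient_levels <- check_levels(state, patient_levels)
  score <- 0
  for (f in names(state$factors)) {
    row <- state$counts[[f]][patient_levels[[f]], ]
    row[candidate_arm] <- row[candidate_arm] + 1L
    score <- score + (max(row) - min(row))
  }
  score
}

#' Assign one patient by biased-coin minimization
#'
#' Computes the imbalance score for each candidate arm; when the scores
#' differ, the score-minimizing arm is drawn with the state's base
#' probability (0.7 by default), otherwise a fair coin decides. The state
#' counts are updated and the decision - both scores and the uniform draw
#' - is appended to the state's audit log. Randomness comes from R's
#' global RNG stream, so seed the session (or pipeline) for
#' reproducibility.
#'
#' @param state An [allocation_state()].
#' @param patient_levels Named list/vector of one level per factor.
#' @param patient_id Optional identifier recorded in the audit log.
#' @return List with `arm` (chosen label) and `state` (updated).
#' @export
minimize_assign <- function(state, patient_levels, patient_id = NA) {
  patient_levels <- check_levels(state, patient_levels)
  scores <- vapply(state$arms, function(a) {
    imbalance_if_assigned(state, patient_levels, a)
  }, numeric(1))
  u <- stats::runif(1)
  if (scores[1L] == scores[2L]) {
    arm <- state$arms[if (u < 0.5) 1L else 2L]
  } else {
    best <- state$arms[which.min(scores)]
    other <- setdiff(state$arms, best)
    arm <- if (u < state$base_probability) best else other
  }
  for (f in names(state$factors)) {
    lev <- patient_levels[[f]]
    state$counts[[f]][lev, arm] <- state$counts[[f]][lev, arm] + 1L
  }
  state$n_assigned <- state$n_assigned + 1L
  state$log[[length(state$log) + 1L]] <- data.frame(
    patient_id = patient_id, arm = arm,
    score_1 = unname(scores[1L]), score_2 = unname(scores[2L]),
    u = u, stringsAsFactors = FALSE
  )
  list(arm = arm, state = state)
}

#' Randomize an enrollment table sequentially
#'
#' Applies [minimize_assign()] to each row of an enrollment table in
#' order, discretizing age at the factor set's cut point.
#'
#' @param enrollment Data frame with columns `patient_id`, `age`, `sex`,
#'   `nyha`.
#' @param state An [allocation_state()]; its factors must include `age`,
#'   `sex`, `nyha`.
#' @return List with `assignments` (data frame `patient_id`, `arm`),
#'   `state` (final), and `audit` (one row per decision).
#' @export
randomize_cohort <- function(enrollment, state = allocation_state()) {
  enrollment <- as.data.frame(enrollment)
  age_cut <- attr(state$factors, "age_cut")
  if (is.null(age_cut)) age_cut <- 60
  arms <- character(nrow(enrollment))
  for (i in seq_len(nrow(enrollment))) {
    levels <- list(
      age = state$factors$age[if (enrollment$age[i] < age_cut) 1L else 2L],
      sex = enrollment$sex[i],
      nyha = enrollment$nyha[i]
    )
    res <- minimize_assign(state, levels, enrollment$patient_id[i])
    arms[i] <- res$arm
    state <- res$state
  }
  list(
    assignments = data.frame(patient_id = enrollment$patient_id,
                             arm = arms, stringsAsFactors = FALSE),
    state = state,
    audit = do.call(rbind, state$log)
  )
}
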