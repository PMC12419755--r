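#' Extract step-`step` rolling windows from one recording
#'
#' Emits every full-length window of `w` consecutive R-R intervals. With the
#' default stride of 1, a recording of length `L` yields `max(0, L - w + 1)`
#' windows and consecutive windows overlap in `w - 1` elements. Truncated
#' tail windows are never emitted: every downstream classifier requires
#' fixed-dimension inputs. Start indices are 0-based.
#'
#' @param recording An [rr_recording()].
#' @param w Window length in beats (>= 1); the pipeline's standard lengths
#'   are 60 and 300.
#' @param step Stride between consecutive window starts (>= 1, default 1).
#' @return An object of class `rr_windows`: list with `values` (matrix,
#'   one window per row), `person_id`, `group`, `start` (0-based), `label`
#'   (0 = control, 1 = treatment) and `w`. Zero windows (L < w) gives a
#'   0-row result, not an error.
#' @examples
#' r <- rr_recording("p", "control", seq(700, 799))
#' nrow(rr_extract_windows(r, w = 60)$values)  # 41
#' @export
rr_extract_windows <- function(recording, w, step = 1L) {
  stopifnot(inherits(recording, "rr_recording"), w >= 1, step >= 1)
  L <- length(recording$rr_ms)
  w <- as.integer(w); step <- as.integer(step)
  if (L < w) {
    rr_log("recording ", recording$person_id, " shorter than w = ", w,
           "; 0 windows emitted")
    starts0 <- integer(0)
  } else {
    starts0 <- seq.int(0L, L - w, by = step)
  }
  n <- length(starts0)
  values <- if (n > 0) {
    idx <- outer(starts0, seq_len(w), `+`)   # 0-based start + 1..w -> 1-based
    matrix(recording$rr_ms[idx], nrow = n, ncol = w)
  } else matrix(numeric(0), nrow = 0, ncol = w)
  new_rr_windows(values,
                 person_id = rep(recording$person_id, n),
                 group = rep(recording$group, n),
                 start = starts0, w = w)
}

new_rr_windows <- function(values, person_id, group, start, w) {
  structure(list(values = values,
                 person_id = as.character(person_id),
                 group = as.character(group),
                 start = as.integer(start),
                 label = as.integer(group == "treatment"),
                 w = as.integer(w)),
            class = "rr_windows")
}

#' Extract windows for a whole cohort
#'
#' Window order is person-major (manifest order) and start-minor; this global
#' ordering is the one used by ordinal subsampling in the explanation layer.
#'
#' @param cohort An `rr_cohort`.
#' @param w,step As in [rr_extract_windows()].
#' @param persons Optional character vector restricting to a subset of
#'   person ids.
#' @return An `rr_windows` object pooling all persons.
#' @export
rr_cohort_windows <- function(cohort, w, step = 1L, persons = NULL) {
  stopifnot(inherits(cohort, "rr_cohort"))
  ids <- persons %||% cohort$manifest$person_id
  parts <- lapply(ids, function(id)
    rr_extract_windows(cohort$recordings[[id]], w, step))
  values <- do.call(rbind, lapply(parts, `[[`, "values"))
  new_rr_windows(values,
                 person_id = unlist(lapply(parts, `[[`, "person_id")),
                 group = unlist(lapply(parts, `[[`, "group")),
                 start = unlist(lapply(parts, `[[`, "start")),
                 w = as.integer(w))
}

#' @export
print.rr_windows <- function(x, ...) {
  cat(sprintf("%d rolling windows of length %d from %d person(s)\n",
              nrow(x$values), x$w, length(unique(x$person_id))))
  invisible(x)
}

## Row-subset an rr_windows object.
windows_subset <- function(x, i) {
  new_rr_windows(x$values[i, , drop = FALSE], x$person_id[i], x$group[i],
                 x$start[i], x$w)
}

windows_for_persons <- function(x, persons) {
  windows_subset(x, x$person_id %in% persons)
}

#' Assign persons to cross-validation folds
#'
#' Builds a person-confined fold plan: every person (and therefore all of
#' their windows) belongs to exactly one fold. Assignment is stratified by
#' group — each group is shuffled under the seed and dealt round-robin — so
#' per-fold group counts are balanced within one person whenever the group
#' sizes allow, with no manual adjustment. At the pipeline's reference scale
#' (30 + 30 persons, k = 5) every fold holds 6 patients and 6 controls.
#'
#' @param cohort An `rr_cohort`.
#' @param k Number of folds (>= 1); must not exceed the smaller group size.
#' @param seed Integer RNG seed; the plan is deterministic given the seed.
#' @return An object of class `rr_fold_plan`: list with `k`, `assignment`
#'   (named integer vector, person_id -> fold in 1..k), and `mode`
#'   (`"kfold"`).
#' @examples
#' co <- rr_generate_cohort(rr_cohort_spec(4, 4, beats_per_person = 400, seed = 1))
#' table(rr_assign_folds(co, k = 2, seed = 9)$assignment)
#' @export
rr_assign_folds <- function(cohort, k, seed) {
  stopifnot(inherits(cohort, "rr_cohort"), k >= 1)
  man <- cohort$manifest
  counts <- table(man$group)
  if (k > min(counts))
    stop2("k = ", k, " exceeds the smaller group size (", min(counts), ")")
  if (any(counts %% k != 0))
    rr_log("group sizes not divisible by k; using nearest-balanced split")
  assignment <- integer(nrow(man))
  names(assignment) <- man$person_id
  with_seed(seed, {
    for (g in names(counts)) {
      ids <- man$person_id[man$group == g]
      ids <- sample(ids)
      assignment[ids] <- rep_len(seq_len(k), length(ids))
    }
  })
  structure(list(k = as.integer(k), assignment = assignment, mode = "kfold"),
            class = "rr_fold_plan")
}

#' Leave-one-person-out fold plan
#'
#' One fold per person: in each cross-validation step a single person is the
#' entire test set and all remaining persons form training/validation.
#'
#' @param cohort An `rr_cohort` with at least 2 persons.
#' @return An `rr_fold_plan` with `mode = "loo"` and `k` = number of persons.
#' @export
rr_loo_plan <- function(cohort) {
  stopifnot(inherits(cohort, "rr_cohort"))
  ids <- cohort$manifest$person_id
  if (length(ids) < 2) stop2("leave-one-out needs at least 2 persons")
  assignment <- seq_along(ids)
  names(assignment) <- ids
  structure(list(k = length(ids), assignment = assignment, mode = "loo"),
            class = "rr_fold_plan")
}

#' @export
print.rr_fold_plan <- function(x, ...) {
  cat(sprintf("%s fold plan: %d fold(s), %d person(s)\n",
              x$mode, x$k, length(x$assignment)))
  invisible(x)
}

fold_persons <- function(plan, fold) names(plan$assignment)[plan$assignment == fold]

## Stable digest of fold membership, used to assert that the test folds are
## identical across methods within one experiment.
fold_hash <- function(plan) {
  parts <- vapply(seq_len(plan$k), function(f)
    paste(sort(fold_persons(plan, f)), collapse = ","), character(1))
  paste(parts, collapse = "|")
}

## Leakage guard: training/validation persons must be disjoint from test
## persons. Called by every fit/evaluate path; a violation aborts.
assert_no_leakage <- function(train_persons, test_persons, context = "fit") {
  bad <- intersect(unique(train_persons), unique(test_persons))
  if (length(bad) > 0)
    stop2("data leakage detected in ", context, ": person(s) ",
          paste(bad, collapse = ", "), " appear on both sides of the split")
  invisible(TRUE)
}
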