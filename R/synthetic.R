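#' Group-level generative profile for synthetic R-R recordings
#'
#' A profile parameterizes the autoregressive generator used to emulate one
#' diagnostic group: a mean R-R interval, a Gaussian innovation scale, AR
#' coefficients that shape the lag structure of the autocorrelation function,
#' and a model of brief activity episodes (e.g. short walks) that transiently
#' depress R-R values.
#'
#' @param group_label `"control"` or `"treatment"`.
#' @param mu_rr Mean R-R interval in milliseconds (> 0).
#' @param sigma_innov Innovation standard deviation in milliseconds (>= 0).
#' @param ar_coeffs Numeric vector of autoregressive coefficients
#'   \eqn{\phi_1..\phi_p} (p <= 6). The AR polynomial must be stationary:
#'   all roots of \eqn{1 - \sum_k \phi_k z^k} strictly outside the unit circle.
#' @param activity_rate Expected activity episodes per 1000 beats (>= 0).
#' @param activity_drop Fractional R-R reduction during an episode, in (0, 1)
#'   (0 allowed, meaning episodes have no effect).
#' @param activity_len Episode length in beats (>= 1).
#' @return An object of class `rr_profile`.
#' @examples
#' p <- rr_profile("control", mu_rr = 850, sigma_innov = 60, ar_coeffs = 0.85)
#' p
#' @export
rr_profile <- function(group_label = c("control", "treatment"),
                       mu_rr, sigma_innov, ar_coeffs = numeric(0),
                       activity_rate = 0, activity_drop = 0.15,
                       activity_len = 60L) {
  group_label <- match.arg(group_label)
  stopifnot(is.numeric(mu_rr), length(mu_rr) == 1, is.finite(mu_rr),
            is.numeric(sigma_innov), length(sigma_innov) == 1,
            is.numeric(ar_coeffs), length(ar_coeffs) <= 6)
  if (mu_rr <= 0) stop2("mu_rr must be positive")
  if (sigma_innov < 0) stop2("sigma_innov must be non-negative")
  if (length(ar_coeffs) > 0 && !ar_stationary(ar_coeffs))
    stop2("ar_coeffs define a non-stationary AR process ",
          "(some root of 1 - sum(phi_k z^k) lies on or inside the unit circle)")
  if (activity_rate < 0) stop2("activity_rate must be non-negative")
  if (activity_drop < 0 || activity_drop >= 1)
    stop2("activity_drop must lie in [0, 1)")
  if (activity_len < 1) stop2("activity_len must be >= 1")
  structure(list(group_label = group_label, mu_rr = mu_rr,
                 sigma_innov = sigma_innov, ar_coeffs = as.numeric(ar_coeffs),
                 activity_rate = activity_rate, activity_drop = activity_drop,
                 activity_len = as.integer(activity_len)),
            class = "rr_profile")
}

#' @export
print.rr_profile <- function(x, ...) {
  cat(sprintf("R-R group profile [%s]: mu = %g ms, sigma = %g ms, AR(%d) = (%s)\n",
              x$group_label, x$mu_rr, x$sigma_innov, length(x$ar_coeffs),
              paste(format(x$ar_coeffs), collapse = ", ")))
  cat(sprintf("  activity: %g episodes/1000 beats, drop %g, length %d beats\n",
              x$activity_rate, x$activity_drop, x$activity_len))
  invisible(x)
}

## Stationarity of an AR(p): all roots of 1 - sum(phi_k z^k) outside the unit
## circle, checked numerically with a small margin for root-finding noise.
ar_stationary <- function(phi, tol = 1e-8) {
  if (all(phi == 0)) return(TRUE)
  all(Mod(polyroot(c(1, -phi))) > 1 + tol)
}

#' Default group profiles
#'
#' The shipped defaults encode the qualitative group structure the pipeline
#' assumes: the control group has longer R-R intervals, larger innovation
#' variance and lag-1-dominant autocorrelation; the treatment group has
#' shorter intervals, lower variance and autocorrelation mass shifted to
#' lags 3-4. Both groups share a mild activity-episode model. Magnitudes are
#' package conventions (see the methods vignette), not measured values.
#'
#' @return Named list with elements `control` and `treatment`, each an
#'   [rr_profile()].
#' @examples
#' rr_default_profiles()$control
#' @export
rr_default_profiles <- function() {
  list(
    control = rr_profile("control", mu_rr = 850, sigma_innov = 60,
                         ar_coeffs = 0.85,
                         activity_rate = 0.3, activity_drop = 0.15,
                         activity_len = 60L),
    treatment = rr_profile("treatment", mu_rr = 700, sigma_innov = 25,
                           ar_coeffs = c(0.30, 0.00, 0.10, 0.50),
                           activity_rate = 0.3, activity_drop = 0.15,
                           activity_len = 60L)
  )
}

#' Construct an R-R recording object
#'
#' @param person_id Person identifier (scalar character).
#' @param group `"control"` or `"treatment"`.
#' @param rr_ms Numeric vector of R-R interval lengths in milliseconds;
#'   all values must be positive and finite.
#' @return An object of class `rr_recording`.
#' @export
rr_recording <- function(person_id, group = c("control", "treatment"), rr_ms) {
  group <- match.arg(group)
  rr_ms <- as.numeric(rr_ms)
  if (length(rr_ms) < 1) stop2("rr_ms must contain at least one beat")
  if (!all(is.finite(rr_ms)) || any(rr_ms <= 0))
    stop2("all R-R intervals must be positive and finite")
  structure(list(person_id = as.character(person_id), group = group,
                 rr_ms = rr_ms),
            class = "rr_recording")
}

#' @export
print.rr_recording <- function(x, ...) {
  cat(sprintf("R-R recording '%s' [%s]: %d beats, mean %.1f ms, sd %.1f ms\n",
              x$person_id, x$group, length(x$rr_ms), mean(x$rr_ms),
              stats::sd(x$rr_ms)))
  invisible(x)
}

#' @export
length.rr_recording <- function(x) length(x$rr_ms)

#' Generate one synthetic R-R recording
#'
#' Simulates a Gaussian AR(p) process around a shifted mean,
#' \deqn{x_t = \mu + \sum_k \phi_k (x_{t-k} - \mu) + \epsilon_t,\qquad
#'       \epsilon_t \sim N(0, \sigma^2),}
#' discards a burn-in prefix so the emitted sequence is approximately
#' stationary, and clips all values to a physiological floor of 200 ms.
#' Identical `(profile, n_beats, seed)` triples give identical output.
#'
#' @param profile An [rr_profile()].
#' @param n_beats Number of beats to emit (>= 1).
#' @param seed Integer RNG seed.
#' @param person_id,group Metadata attached to the recording; `group`
#'   defaults to the profile's label.
#' @param burn_in Number of initial beats discarded (>= 500 by default).
#' @return An [rr_recording()] of exactly `n_beats` values.
#' @examples
#' p <- rr_profile("control", 850, 60, 0.85)
#' r <- rr_generate_person(p, n_beats = 500, seed = 1)
#' length(r$rr_ms)
#' @export
rr_generate_person <- function(profile, n_beats, seed,
                               person_id = "person", group = NULL,
                               burn_in = 500L) {
  stopifnot(inherits(profile, "rr_profile"), n_beats >= 1, burn_in >= 500)
  p <- length(profile$ar_coeffs)
  total <- as.integer(n_beats) + as.integer(burn_in)
  x <- with_seed(seed, {
    eps <- stats::rnorm(total, 0, profile$sigma_innov)
    z <- numeric(total)
    if (p == 0L) {
      z <- eps
    } else {
      phi <- profile$ar_coeffs
      for (t in seq_len(total)) {
        acc <- eps[t]
        for (k in seq_len(min(p, t - 1L)))
          acc <- acc + phi[k] * z[t - k]
        z[t] <- acc
      }
    }
    z
  })
  rr <- profile$mu_rr + x[(burn_in + 1L):total]
  rr <- pmax(rr, 200)
  rr_recording(person_id, group %||% profile$group_label, rr)
}

#' Inject transient activity episodes into a recording
#'
#' Places episodes at Poisson-random locations (expected
#' `activity_rate` episodes per 1000 beats) and multiplies the covered beats
#' by `1 - activity_drop`, emulating brief heart-rate-raising events such as
#' short walks. Values are kept at or above the 200 ms floor and the beat
#' count is unchanged. With `activity_rate = 0` and no forced starts the
#' recording is returned untouched.
#'
#' @param recording An [rr_recording()].
#' @param profile An [rr_profile()] supplying the activity parameters.
#' @param seed Integer RNG seed.
#' @param starts Optional integer vector of forced episode start indices
#'   (1-based); when given, random placement is skipped.
#' @return An [rr_recording()]; attribute `"activity_idx"` holds the indices
#'   of affected beats.
#' @examples
#' r <- rr_recording("p", "control", rep(800, 100))
#' out <- rr_inject_activity(r, rr_profile("control", 800, 0, activity_drop = 0.2,
#'                                         activity_len = 10), seed = 1, starts = 11)
#' unique(out$rr_ms[11:20])
#' @export
rr_inject_activity <- function(recording, profile, seed = NULL, starts = NULL) {
  stopifnot(inherits(recording, "rr_recording"), inherits(profile, "rr_profile"))
  n <- length(recording$rr_ms)
  if (is.null(starts)) {
    if (profile$activity_rate == 0) {
      attr(recording, "activity_idx") <- integer(0)
      return(recording)
    }
    starts <- with_seed(seed, {
      k <- stats::rpois(1, profile$activity_rate * n / 1000)
      if (k > 0) sort(sample.int(n, min(k, n), replace = FALSE)) else integer(0)
    })
  }
  idx <- unique(unlist(lapply(starts, function(s)
    seq.int(s, min(n, s + profile$activity_len - 1L)))))
  idx <- idx[idx >= 1 & idx <= n]
  rr <- recording$rr_ms
  rr[idx] <- pmax(rr[idx] * (1 - profile$activity_drop), 200)
  out <- rr_recording(recording$person_id, recording$group, rr)
  attr(out, "activity_idx") <- as.integer(idx)
  out
}

#' Specify a synthetic cohort
#'
#' @param n_control,n_treatment Persons per group (>= 1).
#' @param beats_per_person Either a single beat count or a length-2 range
#'   from which per-person counts are drawn uniformly. The default range
#'   emulates 1-1.5 hour recordings at typical R-R lengths.
#' @param control_profile,treatment_profile [rr_profile()] objects; default
#'   [rr_default_profiles()].
#' @param seed Integer RNG seed for the whole cohort.
#' @return An object of class `rr_cohort_spec`.
#' @export
rr_cohort_spec <- function(n_control = 30L, n_treatment = 30L,
                           beats_per_person = c(3600L, 5400L),
                           control_profile = rr_default_profiles()$control,
                           treatment_profile = rr_default_profiles()$treatment,
                           seed = 1L) {
  stopifnot(n_control >= 1, n_treatment >= 1,
            length(beats_per_person) %in% 1:2, all(beats_per_person >= 1),
            inherits(control_profile, "rr_profile"),
            inherits(treatment_profile, "rr_profile"))
  structure(list(n_control = as.integer(n_control),
                 n_treatment = as.integer(n_treatment),
                 beats_per_person = as.integer(beats_per_person),
                 control_profile = control_profile,
                 treatment_profile = treatment_profile,
                 seed = as.integer(seed)),
            class = "rr_cohort_spec")
}

#' Generate a synthetic R-R cohort
#'
#' Draws one recording per person from the group profiles (including activity
#' episodes), with deterministic per-person seeds derived from the cohort
#' seed. Person identifiers are `C001..` for controls and `T001..` for the
#' treatment group.
#'
#' @param spec An [rr_cohort_spec()].
#' @return An object of class `rr_cohort`: a list with `recordings` (list of
#'   [rr_recording()]) and `manifest` (data.frame with columns `person_id`,
#'   `group`, `file`; `file` is filled by [rr_write_cohort()]).
#' @examples
#' co <- rr_generate_cohort(rr_cohort_spec(2, 2, beats_per_person = 400, seed = 1))
#' co$manifest
#' @export
rr_generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "rr_cohort_spec"))
  ids <- c(sprintf("C%03d", seq_len(spec$n_control)),
           sprintf("T%03d", seq_len(spec$n_treatment)))
  if (anyDuplicated(ids)) stop2("duplicate person_id in cohort")
  groups <- rep(c("control", "treatment"), c(spec$n_control, spec$n_treatment))
  profiles <- list(control = spec$control_profile,
                   treatment = spec$treatment_profile)
  n_persons <- length(ids)
  beats <- with_seed(spec$seed, {
    if (length(spec$beats_per_person) == 1L)
      rep(spec$beats_per_person, n_persons)
    else
      sample(seq.int(spec$beats_per_person[1], spec$beats_per_person[2]),
             n_persons, replace = TRUE)
  })
  recordings <- vector("list", n_persons)
  for (i in seq_len(n_persons)) {
    prof <- profiles[[groups[i]]]
    rec <- rr_generate_person(prof, beats[i], seed = child_seed(spec$seed, i),
                              person_id = ids[i], group = groups[i])
    recordings[[i]] <- rr_inject_activity(rec, prof,
                                          seed = child_seed(spec$seed, i + n_persons))
  }
  names(recordings) <- ids
  manifest <- data.frame(person_id = ids, group = groups,
                         file = NA_character_, stringsAsFactors = FALSE)
  structure(list(recordings = recordings, manifest = manifest, spec = spec),
            class = "rr_cohort")
}

#' @export
print.rr_cohort <- function(x, ...) {
  tab <- table(x$manifest$group)
  beats <- vapply(x$recordings, length, integer(1))
  cat(sprintf("R-R cohort: %d persons (%s), %d-%d beats each\n",
              nrow(x$manifest),
              paste(names(tab), tab, sep = ": ", collapse = ", "),
              min(beats), max(beats)))
  invisible(x)
}

#' Write a cohort to per-person CSV files plus a manifest
#'
#' Each person is written as `<person_id>.csv` with a single `rr_ms` column,
#' one beat per row; `manifest.csv` has columns `person_id,group,file`.
#'
#' @param cohort An `rr_cohort`.
#' @param dir Output directory (created if missing).
#' @return Invisibly, the manifest path.
#' @export
rr_write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "rr_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(nrow(cohort$manifest))
  for (i in seq_len(nrow(cohort$manifest))) {
    id <- cohort$manifest$person_id[i]
    f <- file.path(dir, paste0(id, ".csv"))
    utils::write.csv(data.frame(rr_ms = cohort$recordings[[id]]$rr_ms),
                     f, row.names = FALSE)
    files[i] <- basename(f)
  }
  manifest <- cohort$manifest
  manifest$file <- files
  mf <- file.path(dir, "manifest.csv")
  utils::write.csv(manifest, mf, row.names = FALSE)
  invisible(mf)
}

#' Read a cohort from a manifest file
#'
#' @param manifest_path Path to a `manifest.csv` with columns
#'   `person_id,group,file`; `file` paths are resolved relative to the
#'   manifest's directory.
#' @return An `rr_cohort`.
#' @export
rr_read_cohort <- function(manifest_path) {
  manifest <- utils::read.csv(manifest_path, stringsAsFactors = FALSE)
  need <- c("person_id", "group", "file")
  if (!all(need %in% names(manifest)))
    stop2("manifest must have columns ", paste(need, collapse = ", "))
  if (anyDuplicated(manifest$person_id)) stop2("duplicate person_id in manifest")
  base <- dirname(manifest_path)
  recordings <- lapply(seq_len(nrow(manifest)), function(i) {
    df <- utils::read.csv(file.path(base, manifest$file[i]))
    rr_recording(manifest$person_id[i], manifest$group[i], df$rr_ms)
  })
  names(recordings) <- manifest$person_id
  structure(list(recordings = recordings, manifest = manifest, spec = NULL),
            class = "rr_cohort")
}
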