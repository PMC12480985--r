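#' Treatment-arm specification for a simulated chronic recording study
#'
#' One arm of a multi-week implant study. Weekly channel activity is
#' Bernoulli with a probability that follows a single linear trend over
#' the study, parameterised by its phase means: the mean over weeks 1-4
#' equals `p_active_phase1` and the mean over weeks 5-8 equals
#' `p_active_phase2` (phase aggregates are what such studies report; the
#' linear ramp is the simplest weekly trajectory consistent with them).
#'
#' @param name arm label.
#' @param n_animals number of implanted animals.
#' @param p_active_phase1 mean weekly probability a viable channel is
#'   active in weeks 1-4.
#' @param p_active_phase2 same for weeks 5-8.
#' @param p_dead_channel probability a channel is malfunctioning from the
#'   outset (never active, flagged).
#' @param units_per_active_channel mean number of isolated units on an
#'   active channel-week (>= 1).
#' @return list of class `arm_spec`.
#' @seealso [default_arm_specs()], [gen_study()]
#' @export
arm_spec <- function(name, n_animals, p_active_phase1, p_active_phase2,
                     p_dead_channel = 0.045, units_per_active_channel = 1.4) {
  stopifnot(is.character(name), length(name) == 1L)
  stop_if_not_scalar_num(n_animals, "n_animals", lower = 1)
  stop_if_not_scalar_num(p_active_phase1, "p_active_phase1", 0, 1)
  stop_if_not_scalar_num(p_active_phase2, "p_active_phase2", 0, 1)
  stop_if_not_scalar_num(p_dead_channel, "p_dead_channel", 0, 1)
  stop_if_not_scalar_num(units_per_active_channel, "units_per_active_channel", 1)
  structure(list(
    name = name, n_animals = as.integer(n_animals),
    p_active_phase1 = p_active_phase1, p_active_phase2 = p_active_phase2,
    p_dead_channel = p_dead_channel,
    units_per_active_channel = units_per_active_channel),
    class = "arm_spec")
}

#' Default four-arm study specification
#'
#' The four treatment arms of the emulated 8-week study: drug-loaded
#' nanoparticles (DEXSPPIN), empty nanoparticles (PIN), vehicle
#' (DILUENT) and free drug (Free DEXSP). Phase activity probabilities
#' are two-point calibrated so the arms reproduce the reported phase
#' declines (17/25/37/54 percent) and the reported relative advantages
#' of the treated arm (36 percent higher in weeks 1-4, 82 percent higher
#' in weeks 5-8, versus vehicle).
#'
#' @return named list of [arm_spec()] objects.
#' @export
default_arm_specs <- function() {
  list(
    DEXSPPIN     = arm_spec("DEXSPPIN", 7, 0.610, 0.5063,
                            units_per_active_channel = 1.6),
    PIN          = arm_spec("PIN", 7, 0.520, 0.390,
                            units_per_active_channel = 1.3),
    DILUENT      = arm_spec("DILUENT", 7, 0.450, 0.2835,
                            units_per_active_channel = 1.2),
    `Free DEXSP` = arm_spec("Free DEXSP", 8, 0.470, 0.2162,
                            units_per_active_channel = 1.1)
  )
}

#' Configuration for a simulated multi-week study
#'
#' @param arms list of [arm_spec()]s (default [default_arm_specs()]).
#' @param weeks number of study weeks (>= 2; default 8).
#' @param channels_per_animal electrode channels per implant (default 16).
#' @param seed integer seed.
#' @return list of class `study_config`.
#' @export
study_config <- function(arms = default_arm_specs(), weeks = 8L,
                         channels_per_animal = 16L, seed = 1L) {
  stopifnot(length(arms) >= 1, all(vapply(arms, inherits, TRUE, "arm_spec")))
  stop_if_not_scalar_num(weeks, "weeks", lower = 2)
  stop_if_not_scalar_num(channels_per_animal, "channels_per_animal", lower = 1)
  structure(list(arms = arms, weeks = as.integer(weeks),
                 channels_per_animal = as.integer(channels_per_animal),
                 seed = as.integer(seed)),
            class = "study_config")
}

#' Weekly activity probabilities implied by an arm specification
#'
#' The unique linear trajectory over `weeks` whose mean over the first
#' half equals `p_active_phase1` and over the second half equals
#' `p_active_phase2`, clamped to `[0, 1]`.
#'
#' @param spec an [arm_spec()].
#' @param weeks total number of weeks.
#' @return numeric vector of length `weeks`.
#' @export
weekly_activity_probs <- function(spec, weeks = 8L) {
  h <- weeks / 2
  m1 <- mean(seq_len(floor(h)))
  m2 <- mean((floor(h) + 1):weeks)
  b <- (spec$p_active_phase2 - spec$p_active_phase1) / (m2 - m1)
  a <- spec$p_active_phase1 - b * m1
  pmin(pmax(a + b * seq_len(weeks), 0), 1)
}

#' Simulate a per-channel activity study table
#'
#' Draws, for every (arm, animal, channel, week), whether the channel is
#' active and how many single units it carries. Channels flagged dead
#' from the outset are inactive every week. Unit counts on active
#' channel-weeks are `1 + Poisson(mu - 1)` so their mean equals the
#' arm's `units_per_active_channel`.
#'
#' @param config a [study_config()].
#' @return data frame (the study table) with columns `arm`, `animal`,
#'   `channel`, `week`, `active`, `n_units`, `dead_from_outset`.
#' @examples
#' tab <- gen_study(study_config(seed = 3))
#' head(tab)
#' @export
gen_study <- function(config) {
  stopifnot(inherits(config, "study_config"))
  with_seed(config$seed, {
    out <- list()
    for (spec in config$arms) {
      p_week <- weekly_activity_probs(spec, config$weeks)
      for (an in seq_len(spec$n_animals)) {
        dead <- stats::rbinom(config$channels_per_animal, 1,
                              spec$p_dead_channel) == 1
        for (ch in seq_len(config$channels_per_animal)) {
          active <- if (dead[ch]) rep(FALSE, config$weeks) else
            stats::rbinom(config$weeks, 1, p_week) == 1
          nu <- ifelse(active,
                       1L + stats::rpois(config$weeks,
                                         spec$units_per_active_channel - 1),
                       0L)
          out[[length(out) + 1L]] <- data.frame(
            arm = spec$name, animal = an, channel = ch,
            week = seq_len(config$weeks), active = active, n_units = nu,
            dead_from_outset = dead[ch])
        }
      }
    }
    tab <- do.call(rbind, out)
    rownames(tab) <- NULL
    tab
  })
}
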