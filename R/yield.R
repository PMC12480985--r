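check_study_table <- function(table) {
  need <- c("arm", "animal", "channel", "week", "active")
  miss <- setdiff(need, names(table))
  if (length(miss))
    stop("study table missing column(s): ", paste(miss, collapse = ", "))
  if (!"dead_from_outset" %in% names(table))
    table$dead_from_outset <- FALSE
  if (anyDuplicated(table[c("arm", "animal", "channel", "week")]))
    stop("study table must have one record per (arm, animal, channel, week)")
  table
}

#' Viable channels of a study
#'
#' A channel is viable unless it was malfunctioning from the outset or
#' was never active in any week of the study; such channels are excluded
#' from every yield denominator. "Never active" is judged over the
#' entire study record, not per phase.
#'
#' @param table study table (see [gen_study()] for the columns).
#' @return data frame of viable channels: `arm`, `animal`, `channel`.
#' @export
viable_channels <- function(table) {
  table <- check_study_table(table)
  key <- interaction(table$arm, table$animal, table$channel, drop = TRUE)
  ever_active <- tapply(table$active, key, any)
  dead <- tapply(table$dead_from_outset, key, any)
  first <- !duplicated(key)
  out <- table[first, c("arm", "animal", "channel")]
  viable <- ever_active[match(key[first], names(ever_active))] &
    !dead[match(key[first], names(dead))]
  out <- out[viable, , drop = FALSE]
  rownames(out) <- NULL
  out
}

viable_key <- function(table, viable) {
  interaction(table$arm, table$animal, table$channel, drop = FALSE) %in%
    interaction(viable$arm, viable$animal, viable$channel, drop = FALSE)
}

#' Weekly active electrode yield
#'
#' AEY for one week: the number of active viable channels divided by the
#' number of viable channels, per arm.
#'
#' @param table study table.
#' @param week the week to evaluate.
#' @return data frame per arm: `arm`, `week`, `n_active`, `n_viable`,
#'   `aey` (`NA` when an arm has no viable channels).
#' @export
weekly_aey <- function(table, week) {
  table <- check_study_table(table)
  viable <- viable_channels(table)
  sub <- table[table$week == week & viable_key(table, viable), , drop = FALSE]
  arms <- unique(table$arm)
  out <- lapply(arms, function(a) {
    nv <- sum(viable$arm == a)
    na_ <- sum(sub$active[sub$arm == a])
    data.frame(arm = a, week = week, n_active = na_, n_viable = nv,
               aey = if (nv > 0) na_ / nv else NA_real_)
  })
  do.call(rbind, out)
}

#' Phase proportion of active electrodes
#'
#' Pools a set of weeks: the numerator is the total number of active
#' viable channel-weeks and the denominator the number of viable
#' channels times the number of weeks in the phase.
#'
#' @param table study table.
#' @param weeks integer vector of weeks forming the phase (non-empty,
#'   all present in the table).
#' @return data frame per arm: `arm`, `n_active`, `n_total`,
#'   `proportion`.
#' @export
phase_proportion <- function(table, weeks) {
  table <- check_study_table(table)
  if (length(weeks) == 0L) stop("empty phase")
  if (!all(weeks %in% table$week))
    stop("phase weeks not present in the study table: ",
         paste(setdiff(weeks, table$week), collapse = ", "))
  viable <- viable_channels(table)
  sub <- table[table$week %in% weeks & viable_key(table, viable), ,
               drop = FALSE]
  arms <- unique(table$arm)
  out <- lapply(arms, function(a) {
    nv <- sum(viable$arm == a)
    n_total <- nv * length(weeks)
    n_active <- sum(sub$active[sub$arm == a])
    data.frame(arm = a, n_active = n_active, n_total = n_total,
               proportion = if (n_total > 0) n_active / n_total else NA_real_)
  })
  do.call(rbind, out)
}

#' Percent decline between two phase proportions
#'
#' `100 * (p1 - p2) / p1`: the relative drop of the late-phase active
#' proportion versus the early phase.
#'
#' @param p1 early-phase proportion (> 0).
#' @param p2 late-phase proportion.
#' @return decline in percent (`NA` with a warning when `p1 <= 0`).
#' @export
phase_decline <- function(p1, p2) {
  if (any(p1 <= 0)) {
    warning("phase decline undefined when the early-phase proportion is 0")
    return(ifelse(p1 > 0, 100 * (p1 - p2) / p1, NA_real_))
  }
  100 * (p1 - p2) / p1
}

#' Two-proportion z-test (pooled, no continuity correction)
#'
#' Tests `H0: p1 == p2` with the pooled-variance z statistic
#' `z = (x1/n1 - x2/n2) / sqrt(p(1-p)(1/n1 + 1/n2))`, `p` the pooled
#' proportion, and a two-sided normal p-value. When both proportions are
#' identical (including the degenerate all-success / all-failure case)
#' z is 0 and p is 1.
#'
#' @param x1,n1 successes and trials of group 1.
#' @param x2,n2 successes and trials of group 2.
#' @return list of class `ztest_result`: `z`, `p`, `p1`, `p2`.
#' @examples
#' two_prop_ztest(93, 428, 51, 428)
#' @export
two_prop_ztest <- function(x1, n1, x2, n2) {
  for (v in list(x1 = x1, n1 = n1, x2 = x2, n2 = n2))
    stopifnot(is.numeric(v), length(v) == 1L, v >= 0)
  if (n1 == 0 || n2 == 0) stop("n1 and n2 must be > 0")
  if (x1 > n1 || x2 > n2) stop("x must not exceed n")
  p1 <- x1 / n1; p2 <- x2 / n2
  pp <- (x1 + x2) / (n1 + n2)
  se <- sqrt(pp * (1 - pp) * (1 / n1 + 1 / n2))
  z <- if (se > 0) (p1 - p2) / se else 0
  structure(list(z = z, p = min(1, 2 * stats::pnorm(-abs(z))),
                 p1 = p1, p2 = p2),
            class = "ztest_result")
}

#' @export
print.ztest_result <- function(x, ...) {
  cat(sprintf("two-proportion z-test: p1 = %.4f, p2 = %.4f, z = %.3f, p = %.3g\n",
              x$p1, x$p2, x$z, x$p))
  invisible(x)
}

#' Units per active channel over a phase
#'
#' For every viable channel active at least once in the phase, the total
#' unit count across the phase divided by the number of weeks in the
#' phase; channels never active in the phase are excluded from the
#' statistic.
#'
#' @param table study table (needs `n_units`).
#' @param weeks integer vector of weeks forming the phase.
#' @return data frame: `arm`, `animal`, `channel`, `units_per_week`.
#' @export
units_per_active_channel <- function(table, weeks) {
  table <- check_study_table(table)
  if (!"n_units" %in% names(table)) stop("study table missing 'n_units'")
  if (length(weeks) == 0L) stop("empty phase")
  viable <- viable_channels(table)
  sub <- table[table$week %in% weeks & viable_key(table, viable), ,
               drop = FALSE]
  key <- interaction(sub$arm, sub$animal, sub$channel, drop = TRUE)
  tot <- tapply(sub$n_units, key, sum)
  act <- tapply(sub$active, key, any)
  first <- !duplicated(key)
  out <- sub[first, c("arm", "animal", "channel")]
  out$units_per_week <- as.numeric(tot[match(key[first], names(tot))]) /
    length(weeks)
  out <- out[act[match(key[first], names(act))], , drop = FALSE]
  rownames(out) <- NULL
  out
}
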