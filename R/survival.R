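# Survival evaluation of hub genes: median-split Kaplan-Meier comparison
# with the log-rank test, the local stand-in for web survival plotters.
# Cohort tables carry one row per patient: sample, time, event (0/1), then
# one numeric column per gene.

check_cohort <- function(cohort) {
  need <- c("sample", "time", "event")
  if (!is.data.frame(cohort) || !all(need %in% names(cohort))) {
    abort("`cohort` needs columns sample, time, event.")
  }
  if (any(cohort$time <= 0)) abort("survival times must be strictly positive.")
  if (!all(cohort$event %in% c(0, 1))) abort("`event` must be 0/1.")
  if (anyDuplicated(cohort$sample)) abort("duplicate sample ids in `cohort`.")
  invisible(cohort)
}

#' Split a cohort at the median expression of one gene
#'
#' Threshold is the cohort median; patients strictly above go to the high
#' group, ties at the median go low. Both groups are guaranteed non-empty
#' unless every value is identical (an error).
#'
#' @param cohort Cohort tibble (see [simulate_survival()] for the layout).
#' @param gene Gene column to split on.
#' @return The cohort with an added factor column `group` (levels
#'   `"high"`, `"low"`).
#' @export
median_split <- function(cohort, gene) {
  check_cohort(cohort)
  if (!gene %in% names(cohort)) {
    abort(sprintf("gene '%s' not measured in the cohort.", gene))
  }
  if (nrow(cohort) < 4) abort("need >= 4 patients for a median split.")
  v <- cohort[[gene]]
  thr <- median(v)
  grp <- factor(ifelse(v > thr, "high", "low"), levels = c("high", "low"))
  if (any(table(grp) == 0)) {
    abort(sprintf("cannot split on '%s': all expression values identical.", gene))
  }
  dplyr::mutate(cohort, group = grp)
}

#' Kaplan-Meier product-limit estimate
#'
#' `S(t)` is the product over event times `t_i <= t` of `(1 - d_i / n_i)`;
#' a patient censored exactly at an event time is counted at risk for that
#' time (the standard right-continuous convention). The Greenwood variance
#' of `S(t)` accompanies each step.
#'
#' @param time Positive follow-up times.
#' @param event 0/1 event indicators (1 = death observed).
#' @return A tibble of class `km_curve`: `time`, `n_risk`, `n_event`,
#'   `n_censor`, `survival`, `greenwood_var`, one row per distinct observed
#'   time.
#' @export
km_estimate <- function(time, event) {
  if (length(time) < 1) abort("need >= 1 patient.")
  if (any(time <= 0)) abort("survival times must be strictly positive.")
  fit <- survival::survfit(survival::Surv(time, event) ~ 1)
  out <- tibble(time = fit$time, n_risk = fit$n.risk, n_event = fit$n.event,
                n_censor = fit$n.censor, survival = fit$surv,
                greenwood_var = (fit$surv * fit$std.err)^2)
  structure(out, class = c("km_curve", class(out)))
}

#' Two-group log-rank test with an O/E hazard-ratio estimate
#'
#' At each distinct event time the observed events in the first group are
#' compared with their hypergeometric expectation given the risk sets;
#' `chi_square = (sum O - sum E)^2 / sum V` with a 1-df chi-square p value.
#' The hazard ratio is the observed/expected ratio estimator
#' `(O_1 / E_1) / (O_2 / E_2)` for the first factor level versus the second,
#' so swapping the groups inverts it.
#'
#' @param time,event Follow-up times and 0/1 indicators.
#' @param group Two-level factor (first level is the numerator of the HR).
#' @return A one-row tibble: `n_1`, `n_2`, `observed_1`, `expected_1`,
#'   `chi_square`, `p_value`, `hazard_ratio`.
#' @export
logrank_test <- function(time, event, group) {
  group <- droplevels(as.factor(group))
  if (nlevels(group) != 2) abort("`group` must have exactly 2 levels.")
  if (any(table(group) == 0)) abort("both groups must be non-empty.")
  if (sum(event) < 1) abort("need >= 1 observed event.")
  sd_fit <- survival::survdiff(survival::Surv(time, event) ~ group)
  v <- if (is.matrix(sd_fit$var)) sd_fit$var[1, 1] else sd_fit$var[1]
  if (!is.finite(v) || v <= 0) {
    abort("log-rank variance is zero: no comparable risk sets.")
  }
  chi <- sd_fit$chisq
  obs <- sd_fit$obs
  expd <- sd_fit$exp
  hr <- (obs[1] / expd[1]) / (obs[2] / expd[2])
  tibble(n_1 = sum(group == levels(group)[1]),
         n_2 = sum(group == levels(group)[2]),
         observed_1 = obs[1], expected_1 = expd[1],
         chi_square = chi,
         p_value = pchisq(chi, df = 1, lower.tail = FALSE),
         hazard_ratio = hr)
}

#' Median-split log-rank evaluation of a hub-gene panel
#'
#' For each hub gene: median-split the cohort, run the log-rank test of the
#' high versus low group, and flag the direction (`"high-worse"` when the
#' high-expression group has the excess hazard, HR > 1). A hub whose split
#' or test fails gets a flagged row instead of aborting the table.
#'
#' @param cohort Cohort tibble.
#' @param hubs Character vector of hub gene ids measured in the cohort.
#' @return A tibble with one row per hub: `gene`, `n_high`, `n_low`,
#'   `chi_square`, `p_value`, `hazard_ratio`, `direction`, `status`.
#' @export
hub_survival_report <- function(cohort, hubs) {
  check_cohort(cohort)
  hubs <- as.character(hubs)
  if (length(hubs) == 0) {
    return(tibble(gene = character(), n_high = integer(), n_low = integer(),
                  chi_square = numeric(), p_value = numeric(),
                  hazard_ratio = numeric(), direction = character(),
                  status = character()))
  }
  rows <- map(hubs, function(g) {
    tryCatch({
      split <- median_split(cohort, g)
      res <- logrank_test(split$time, split$event, split$group)
      tibble(gene = g, n_high = res$n_1, n_low = res$n_2,
             chi_square = res$chi_square, p_value = res$p_value,
             hazard_ratio = res$hazard_ratio,
             direction = if (res$hazard_ratio > 1) "high-worse" else "low-worse",
             status = "ok")
    }, error = function(e) {
      tibble(gene = g, n_high = NA_integer_, n_low = NA_integer_,
             chi_square = NA_real_, p_value = NA_real_,
             hazard_ratio = NA_real_, direction = NA_character_,
             status = conditionMessage(e))
    })
  })
  list_rbind(rows)
}

#' Kaplan-Meier plot for a median-split cohort
#'
#' @param cohort Cohort tibble.
#' @param gene Gene to split on.
#' @return A ggplot object with one step curve per group.
#' @export
plot_km <- function(cohort, gene) {
  split <- median_split(cohort, gene)
  curves <- split |>
    dplyr::group_by(.data$group) |>
    dplyr::group_modify(~{
      km <- km_estimate(.x$time, .x$event)
      dplyr::bind_rows(tibble(time = 0, survival = 1),
                       km[, c("time", "survival")])
    }) |>
    dplyr::ungroup()
  ggplot2::ggplot(curves, ggplot2::aes(x = .data$time, y = .data$survival,
                                       colour = .data$group)) +
    ggplot2::geom_step(linewidth = 0.8) +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(title = sprintf("Kaplan-Meier by %s expression (median split)", gene),
                  x = "time", y = "survival probability") +
    ggplot2::theme_minimal()
}
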