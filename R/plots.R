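#' Plot a simulation's delivery timeline
#'
#' One point per delivered message, time of day against date, coloured by
#' channel and faceted by user; skips are not drawn. The guaranteed daily
#' pattern (morning BCT, midday step feedback, evening BCT) and any
#' geofence prompts are visible at a glance.
#'
#' @param object A `coach_sim` from [run_simulation()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot coach_sim
#' @export
autoplot.coach_sim <- function(object, ...) {
  del <- object$log[object$log$kind == "DELIVERY", ]
  ggplot2::ggplot(del, ggplot2::aes(x = .data$minute / 60, y = .data$date,
                                    colour = .data$channel)) +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::scale_x_continuous(breaks = seq(0, 24, 4), limits = c(0, 24)) +
    ggplot2::facet_wrap(ggplot2::vars(.data$user_id)) +
    ggplot2::labs(x = "hour of day", y = NULL, colour = "channel",
                  title = "Delivered coaching messages") +
    ggplot2::theme_minimal()
}

#' Plot synthetic step trajectories
#'
#' Cumulative step count over the day for one or more user-days, with the
#' stratum bounds (2000 and 6000 by default) and the 7000-step goal marked.
#'
#' @param records A step-record tibble (`user_id, date, time, steps, ...`).
#' @param config An [engine_config()] for the reference lines.
#' @return A ggplot object.
#' @export
plot_step_trajectory <- function(records, config = engine_config()) {
  records <- as_tibble(records)
  records$day <- format(as.Date(records$date))
  ggplot2::ggplot(records, ggplot2::aes(x = .data$time / 60, y = .data$steps,
                                        group = interaction(.data$user_id, .data$day),
                                        colour = .data$user_id)) +
    ggplot2::geom_step() +
    ggplot2::geom_hline(yintercept = c(config$strata_bounds, config$step_goal[1]),
                        linetype = c("dotted", "dotted", "dashed")) +
    ggplot2::labs(x = "hour of day", y = "cumulative steps",
                  title = "Simulated daily step accrual") +
    ggplot2::theme_minimal()
}
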