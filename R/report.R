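# Reporting surfaces: time-course, loop-overlay and maximal-response
# figures, each with a CSV twin holding exactly the plotted values.

sig_stars <- function(p) {
  dplyr::case_when(is.na(p) ~ "", p < 0.001 ~ "***", p < 0.01 ~ "**",
                   p < 0.05 ~ "*", TRUE ~ "")
}

#' Time-course figure data and plot
#'
#' Mean +/- SEM stabilisation-normalised power per arm over the protocol,
#' with the stabilisation window shaded and significance markers from the
#' gated per-timepoint t-tests.
#'
#' @param result A `wl_study_result`.
#' @return List with `data` (the plotted values) and `plot` (ggplot).
#' @export
plot_time_course <- function(result) {
  d <- result$summary
  stars <- dplyr::left_join(
    d[d$arm == "drug", c("time_min", "mean_pct", "sem_pct")],
    result$ttests[, c("time_min", "p")], by = "time_min")
  stars$label <- sig_stars(stars$p)
  stab_end <- result$schedule$stabilisation_end_min
  gp <- ggplot2::ggplot(d, ggplot2::aes(x = .data$time_min,
                                        y = .data$mean_pct,
                                        colour = .data$arm)) +
    ggplot2::annotate("rect", xmin = -Inf, xmax = stab_end, ymin = -Inf,
                      ymax = Inf, alpha = 0.15, fill = "grey40") +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$mean_pct - .data$sem_pct,
                                        ymax = .data$mean_pct + .data$sem_pct),
                           width = 1.2) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::geom_text(data = stars,
                       ggplot2::aes(y = .data$mean_pct + .data$sem_pct + 3,
                                    label = .data$label),
                       colour = "black", na.rm = TRUE) +
    ggplot2::labs(x = "Time (min)",
                  y = "Net power output (% of stabilisation)",
                  colour = NULL,
                  title = sprintf("%s vs vehicle", result$preset)) +
    ggplot2::theme_minimal()
  list(data = dplyr::left_join(d, stars[, c("time_min", "p", "label")],
                               by = "time_min"),
       plot = gp)
}

first_loop_df <- function(trace) {
  loop <- segment_cycles(trace)[[1]]
  data.frame(length_mm = loop$length_mm, force_mN = loop$force_mN)
}

#' Loop-overlay figure data and plot
#'
#' Overlays a representative work-loop from the end of the stabilisation
#' window (dashed) with one from the maximal-response time (solid), for
#' the first included drug-arm preparation.  Requires the dataset to have
#' been simulated with `keep_traces = TRUE`.
#'
#' @param data A `wl_study_data`.
#' @param result The matching `wl_study_result`.
#' @return List with `data` and `plot`.
#' @export
plot_loop_overlay <- function(data, result) {
  included <- unique(result$time_courses$prep_id[result$time_courses$arm == "drug"])
  prep <- NULL
  for (p in data$drug) if (p$prep_id %in% included) { prep <- p; break }
  if (is.null(prep) || is.null(prep$recordings))
    stop("no drug-arm traces available (simulate with keep_traces = TRUE)",
         call. = FALSE)
  stab_end <- result$schedule$stabilisation_end_min
  t_max <- result$effects$time_min[which.max(abs(result$effects$effect_pp))]
  d <- rbind(
    cbind(first_loop_df(prep$recordings[[paste0("t", stab_end)]]),
          loop = sprintf("stabilisation (%d min)", stab_end)),
    cbind(first_loop_df(prep$recordings[[paste0("t", t_max)]]),
          loop = sprintf("maximal response (%g min)", t_max)))
  gp <- ggplot2::ggplot(d, ggplot2::aes(x = .data$length_mm,
                                        y = .data$force_mN,
                                        colour = .data$loop,
                                        linetype = .data$loop)) +
    ggplot2::geom_path() +
    ggplot2::scale_linetype_manual(values = c(2, 1)) +
    ggplot2::scale_colour_manual(values = c("black", "red")) +
    ggplot2::labs(x = "Length (mm)", y = "Force (mN)",
                  title = sprintf("%s: work-loop shape change", result$preset),
                  colour = NULL, linetype = NULL) +
    ggplot2::theme_minimal()
  list(data = d, plot = gp)
}

#' Maximal-response summary across drugs
#'
#' Bar summary of each study's largest-magnitude drug-vs-vehicle effect
#' (mean +/- SEM, percentage points).
#'
#' @param results List of `wl_study_result` objects.
#' @return List with `data` and `plot`.
#' @export
plot_max_response <- function(results) {
  d <- dplyr::bind_rows(lapply(results, function(r) {
    i <- which.max(abs(r$effects$effect_pp))
    tibble::tibble(preset = r$preset, time_min = r$effects$time_min[i],
                   effect_pp = r$effects$effect_pp[i],
                   sem_pp = r$effects$sem_pp[i],
                   p = r$ttests$p[i])
  }))
  gp <- ggplot2::ggplot(d, ggplot2::aes(x = stats::reorder(.data$preset,
                                                           .data$effect_pp),
                                        y = .data$effect_pp)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$effect_pp - .data$sem_pp,
                                        ymax = .data$effect_pp + .data$sem_pp),
                           width = 0.3) +
    ggplot2::labs(x = NULL,
                  y = "Maximal response vs vehicle (percentage points)") +
    ggplot2::theme_minimal()
  list(data = d, plot = gp)
}

#' Write the report artifacts for one analysed study
#'
#' Writes the time-course figure, the loop overlay (when traces are
#' available), the statistics tables and a CSV twin of every figure into
#' `dir`.
#'
#' @param result A `wl_study_result`.
#' @param data The matching `wl_study_data` (optional; enables the loop
#'   overlay).
#' @param dir Output directory (created if needed).
#' @param figures Write PNG figures as well as the CSV twins.
#' @return Invisibly, the paths written.
#' @export
render_report <- function(result, data = NULL, dir, figures = TRUE) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character()
  save_pair <- function(obj, stem, width = 6, height = 4) {
    csv <- file.path(dir, paste0(stem, ".csv"))
    readr::write_csv(obj$data, csv)
    paths <<- c(paths, csv)
    if (figures) {
      png <- file.path(dir, paste0(stem, ".png"))
      ggplot2::ggsave(png, obj$plot, width = width, height = height, dpi = 150)
      paths <<- c(paths, png)
    }
  }
  save_pair(plot_time_course(result), "time_course")
  if (!is.null(data)) {
    ov <- try(plot_loop_overlay(data, result), silent = TRUE)
    if (!inherits(ov, "try-error")) save_pair(ov, "loop_overlay")
  }
  for (nm in c("effects", "rm_anova", "ttests", "exclusions")) {
    f <- file.path(dir, paste0(nm, ".csv"))
    readr::write_csv(result[[nm]], f)
    paths <- c(paths, f)
  }
  invisible(paths)
}
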