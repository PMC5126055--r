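#' @export
print.bg_config <- function(x, ...) {
  cat("Basal ganglia network configuration\n")
  cat(sprintf("  lattice: %d x %d per nucleus, dt = %g ms, trial = %g ms\n",
              x$rows, x$cols, x$dt, x$trial_ms))
  cat(sprintf("  gains (pA): GPe->STN %g, STN->GPe %g, D2->GPe %g, D1->GPi %g, STN->GPi %g\n",
              x$g_gpe_stn, x$g_stn_gpe, x$g_d2_gpe, x$g_d1_gpi, x$g_stn_gpi))
  cat(sprintf("  lateral: STN %g, GPe %g, dopamine coupling k = %g (DA: HC %g, PD %g)\n",
              x$g_lat_stn, x$g_lat_gpe, x$da_coupling, x$da_healthy, x$da_pd))
  cat(sprintf("  striatal rates: [%g, %g] Hz over w in [0, %g]; outcome scale %g\n",
              x$rate_min, x$rate_max, x$w_max, x$outcome_scale))
  invisible(x)
}

#' @export
print.electrode_config <- function(x, ...) {
  cat(sprintf(
    "DBS electrode: centre (%g, %g), %g pA, sigma %g, %g Hz biphasic (%g ms/phase)\n",
    x$center[1], x$center[2], x$amplitude, x$sigma, x$frequency,
    x$phase_width))
  invisible(x)
}

#' @export
print.bg_sim <- function(x, ...) {
  cat(sprintf("Basal ganglia simulation: %s, %g ms, %d x %d lattice\n",
              x$condition, x$duration_ms, x$rows, x$cols))
  if (!is.null(x$electrode)) print(x$electrode) else cat("  stimulation off\n")
  for (nm in names(x$spikes)) {
    r <- nrow(x$spikes[[nm]]) / (x$n_neurons * x$duration_ms / 1000)
    cat(sprintf("  %s: %d spikes recorded (%.1f Hz/neuron)\n",
                nm, nrow(x$spikes[[nm]]), r))
  }
  invisible(x)
}

#' Raster plot of a recorded nucleus
#'
#' @param x a `bg_sim`.
#' @param nucleus which raster to plot.
#' @param max_neurons subsample cap for readability.
#' @param ... passed to [graphics::plot()].
#' @export
plot.bg_sim <- function(x, nucleus = "STN", max_neurons = 200, ...) {
  sp <- raster_from(x, nucleus)
  keep <- sp$neuron <= max_neurons
  graphics::plot(sp$time_ms[keep], sp$neuron[keep], pch = ".", cex = 2,
                 xlab = "time (ms)", ylab = "neuron",
                 main = sprintf("%s raster (%s)", nucleus, x$condition), ...)
  invisible(x)
}

#' @export
print.igt_experiment <- function(x, ...) {
  cat(sprintf("IGT experiment: %s, %d runs%s\n", x$condition[1], nrow(x),
              if (is.null(attr(x, "electrode"))) "" else ", DBS on"))
  print.data.frame(x, row.names = FALSE)
  cat(sprintf("mean total %.2f (sd %.2f)\n", mean(x$total), sd(x$total)))
  invisible(x)
}

#' Summarise an IGT experiment
#'
#' @param object an `igt_experiment`.
#' @param ... unused.
#' @return data frame of mean and sd per bin and for the total score.
#' @export
summary.igt_experiment <- function(object, ...) {
  cols <- c(paste0("bin", 1:5), "total")
  data.frame(score = cols,
             mean = vapply(cols, function(cl) mean(object[[cl]]), numeric(1)),
             sd = vapply(cols, function(cl) sd(object[[cl]]), numeric(1)),
             row.names = NULL)
}

#' Bin-score learning curve of an IGT experiment
#'
#' @param x an `igt_experiment`.
#' @param ... passed to [graphics::plot()].
#' @export
plot.igt_experiment <- function(x, ...) {
  s <- summary(x)
  bins <- s[1:5, ]
  se <- bins$sd / sqrt(nrow(x))
  graphics::plot(1:5, bins$mean, type = "b", pch = 19,
                 ylim = range(c(bins$mean - se, bins$mean + se, 0)),
                 xlab = "bin (20 trials)", ylab = "mean bin score",
                 main = sprintf("IGT learning curve (%s)", x$condition[1]), ...)
  graphics::arrows(1:5, bins$mean - se, 1:5, bins$mean + se,
                   angle = 90, code = 3, length = 0.04)
  graphics::abline(h = 0, lty = 3)
  invisible(x)
}

#' @export
print.igt_sweep <- function(x, ...) {
  cat(sprintf("DBS %s sweep (%s), %d runs per value\n",
              x$param[1], x$condition[1], max(x$run)))
  agg <- stats::aggregate(total ~ value, data = as.data.frame(x), FUN = mean)
  sds <- stats::aggregate(total ~ value, data = as.data.frame(x), FUN = sd)
  agg$sd <- sds$total
  names(agg) <- c(x$param[1], "mean_total", "sd")
  print(agg, row.names = FALSE)
  invisible(x)
}
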