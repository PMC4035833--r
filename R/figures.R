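#' Reproduce the package's reference analyses
#'
#' Runs the configuration behind each headline analysis and writes its plots
#' (PNG) and summary statistics (CSV/JSON) to `out_dir`.  Figures: 2 =
#' delayed-response performance (fixed vs variable delay); 3 = delayed-response
#' representations (selectivity, PSTH before/after learning, PCA trajectories,
#' weight matrix); 4 = delayed categorization; 5 = multitask with disjoint
#' domains; 6 = multitask with overlapping boundaries; 7 = multiplexing
#' summary across the two multitask variants; 8 = ablations (frozen recurrent
#' weights, reward-independent STDP).
#'
#' Trial counts default to a reduced size suitable for interactive use; pass
#' `trials_per_block = 20000` for the full-scale conditions.
#'
#' @param figure Integer in 2..8.
#' @param out_dir Output directory.
#' @param trials_per_block Trials per curriculum block.
#' @param seed Base seed.
#' @param n_repeats Seeds per condition where averages are reported.
#' @return A list of summary statistics, invisibly.
#' @export
reproduce_figure <- function(figure, out_dir = ".", trials_per_block = 5000L,
                             seed = 1L, n_repeats = 2L) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  fun <- switch(as.character(figure),
    "2" = .fig_performance, "3" = .fig_representation,
    "4" = .fig_categorization, "5" = .fig_disjoint, "6" = .fig_overlap,
    "7" = .fig_multiplexing, "8" = .fig_ablation,
    stop("figure must be one of 2..8"))
  stats <- fun(out_dir, trials_per_block, seed, n_repeats)
  jsonlite::write_json(stats, file.path(out_dir, sprintf("figure%s_stats.json", figure)),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(stats)
}

.png_open <- function(path, w = 900, h = 600) {
  grDevices::png(path, width = w, height = h, res = 110)
}

.fig_performance <- function(out_dir, npb, seed, n_repeats) {
  runs <- lapply(c(fixed = "fixed", variable = "variable"), function(md)
    run_experiment(run_config("delayed_response", delay_mode = md,
                              trials_per_block = npb, seed = seed)))
  .png_open(file.path(out_dir, "figure2_performance.png"))
  on.exit(grDevices::dev.off())
  cols <- c(fixed = "steelblue", variable = "firebrick")
  curves <- lapply(runs, performance_curve)
  plot(NA, xlim = c(0, max(curves[[1]]$trial)), ylim = c(0, 1),
       xlab = "trial", ylab = "fraction correct",
       main = "Delayed response: fixed vs variable delay")
  for (nm in names(curves))
    graphics::lines(curves[[nm]]$trial, curves[[nm]]$correct, col = cols[nm])
  graphics::abline(v = npb * seq_along(runs$fixed$config$schedule),
                   lty = 3, col = "grey60")
  graphics::abline(h = 1 / runs$fixed$task$M, lty = 2)
  graphics::legend("bottomleft", legend = names(curves), col = cols, lty = 1)
  list(final_fixed = final_performance(runs$fixed),
       final_variable = final_performance(runs$variable),
       per_delay_variable = per_delay_performance(runs$variable))
}

.fig_representation <- function(out_dir, npb, seed, n_repeats) {
  run <- run_experiment(run_config("delayed_response",
                                   trials_per_block = npb, seed = seed))
  rep_ <- selectivity_report(run, "stimulus")
  labels <- condition_labels(run, "stimulus")
  after <- psth(run$raster, labels, condition = 1L)
  # untrained reference: fresh network settled at its operating point
  set.seed(run$config$seed + 1000L)
  spec0 <- run$task
  net0 <- initialize_network(run$config$network, n_inputs = spec0$n_channels)
  settle <- run_passive(net0, spec0, 20000L, run$config$plasticity,
                        record_trials = 1000L)
  before <- psth(settle$raster, settle$raster_trials$stimulus, condition = 1L)

  .png_open(file.path(out_dir, "figure3_representation.png"), 1200, 900)
  on.exit(grDevices::dev.off())
  graphics::par(mfrow = c(2, 2))
  plot(rep_$S, pch = 16, cex = 0.6, xlab = "excitatory neuron",
       ylab = "depth of selectivity", main = "Stimulus selectivity")
  graphics::image(t(before$p[before$order, ]), main = "PSTH before learning",
                  xlab = "time step", ylab = "neuron (peak-ordered)")
  graphics::image(t(after$p[after$order, ]), main = "PSTH after learning",
                  xlab = "time step", ylab = "neuron (peak-ordered)")
  e <- seq_len(run$network$n_exc)
  ord_e <- after$order[after$order <= run$network$n_exc]
  graphics::image(t(run$network$w_rec[e, e][ord_e, ord_e]),
                  main = "Recurrent weights (peak-ordered)",
                  xlab = "presynaptic", ylab = "postsynaptic")
  wms <- weight_matrix_summary(run$network, order = after$order)
  list(final_performance = final_performance(run),
       mean_S = mean(rep_$S, na.rm = TRUE),
       psth_peakiness_after = psth_peakiness(after$p),
       psth_peakiness_before = psth_peakiness(before$p),
       sparsity = wms$sparsity, feedforwardness = wms$feedforwardness)
}

.fig_categorization <- function(out_dir, npb, seed, n_repeats) {
  run <- run_experiment(run_config("categorization",
                                   trials_per_block = npb, seed = seed))
  rep_ <- selectivity_report(run, "category")
  .png_open(file.path(out_dir, "figure4_categorization.png"))
  on.exit(grDevices::dev.off())
  cols <- c("firebrick", "steelblue")[as.integer(rep_$preferred)]
  plot(rep_$S, col = cols, pch = 16, cex = 0.7, xlab = "excitatory neuron",
       ylab = "category selectivity", main = "Delayed categorization")
  graphics::abline(h = 0.75, lty = 2)
  list(final_performance = final_performance(run),
       selective_fraction_075 = as.numeric(selective_fraction(rep_$S, 0.75)))
}

.multitask_S <- function(run) {
  list(S1 = selectivity_report(run, "category1")$S,
       S2 = selectivity_report(run, "category2")$S)
}

.fig_disjoint <- function(out_dir, npb, seed, n_repeats) {
  run <- run_experiment(run_config("multitask_disjoint",
                                   trials_per_block = npb, seed = seed))
  s <- .multitask_S(run)
  mx <- multiplexing_stats(s$S1, s$S2, 0.75)
  .png_open(file.path(out_dir, "figure5_disjoint.png"))
  on.exit(grDevices::dev.off())
  plot(s$S1, s$S2, pch = 16, cex = 0.7, xlab = "selectivity, task 1",
       ylab = "selectivity, task 2", main = "Disjoint domains")
  graphics::abline(h = 0.75, v = 0.75, lty = 2)
  list(final_performance = final_performance(run),
       both = mx$both, only1 = mx$only1, only2 = mx$only2,
       both_overall = mx$both_overall)
}

.fig_overlap <- function(out_dir, npb, seed, n_repeats) {
  run <- run_experiment(run_config("multitask_overlap",
                                   trials_per_block = npb, seed = seed))
  s <- .multitask_S(run)
  ctx <- selectivity_report(run, "context")
  mx <- multiplexing_stats(s$S1, s$S2, 0.5)
  .png_open(file.path(out_dir, "figure6_overlap.png"))
  on.exit(grDevices::dev.off())
  cols <- ifelse(!is.na(ctx$S) & ctx$S >= 0.5, "firebrick", "grey40")
  plot(s$S1, s$S2, pch = 16, cex = 0.7, col = cols,
       xlab = "selectivity, boundary 1", ylab = "selectivity, boundary 2",
       main = "Overlapping boundaries (red: context-selective)")
  graphics::abline(h = 0.5, v = 0.5, lty = 2)
  list(final_performance = final_performance(run),
       specific_fraction = mean(pmax(s$S1, s$S2, na.rm = TRUE) >= 0.5,
                                na.rm = TRUE),
       both = mx$both, only1 = mx$only1, only2 = mx$only2)
}

.fig_multiplexing <- function(out_dir, npb, seed, n_repeats) {
  res <- lapply(seq_len(n_repeats), function(i) {
    dj <- run_experiment(run_config("multitask_disjoint",
                                    trials_per_block = npb, seed = seed + i - 1L))
    ov <- run_experiment(run_config("multitask_overlap",
                                    trials_per_block = npb, seed = seed + i - 1L))
    sd_ <- .multitask_S(dj); so <- .multitask_S(ov)
    c(disjoint_both = multiplexing_stats(sd_$S1, sd_$S2, 0.75)$both,
      overlap_both = multiplexing_stats(so$S1, so$S2, 0.5)$both)
  })
  m <- colMeans(do.call(rbind, res))
  .png_open(file.path(out_dir, "figure7_multiplexing.png"))
  on.exit(grDevices::dev.off())
  graphics::barplot(c(`disjoint` = m["disjoint_both"],
                      `overlap` = m["overlap_both"]),
                    ylab = "fraction selective to both boundaries",
                    main = "Multiplexing across task variants", ylim = c(0, 1))
  as.list(m)
}

.fig_ablation <- function(out_dir, npb, seed, n_repeats) {
  perf <- function(family, mode, md = "variable")
    vapply(seq_len(n_repeats), function(i)
      final_performance(run_experiment(
        run_config(family, delay_mode = md, trials_per_block = npb,
                   recurrent_mode = mode, seed = seed + i - 1L))),
      numeric(1))
  dr_rstdp <- perf("delayed_response", "rstdp")
  dr_frozen <- perf("delayed_response", "frozen")
  cat_rstdp <- perf("categorization", "rstdp", "fixed")
  cat_stdp <- perf("categorization", "stdp", "fixed")
  .png_open(file.path(out_dir, "figure8_ablation.png"))
  on.exit(grDevices::dev.off())
  graphics::boxplot(list(`DR r-STDP` = dr_rstdp, `DR frozen` = dr_frozen,
                         `Cat r-STDP` = cat_rstdp, `Cat STDP` = cat_stdp),
                    ylab = "final fraction correct", ylim = c(0, 1))
  list(dr_rstdp = mean(dr_rstdp), dr_frozen = mean(dr_frozen),
       cat_rstdp = mean(cat_rstdp), cat_stdp = mean(cat_stdp),
       cat_rstdp_sd = sd(cat_rstdp), cat_stdp_sd = sd(cat_stdp))
}
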