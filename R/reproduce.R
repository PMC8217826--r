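# Regeneration of the data behind the standard diagnostic figure panels.
# Grids are kept modest; every CSV is deterministic.

reproduce_fig3 <- function(dir) {
  grid <- expand.grid(a_E = seq(2, 16, by = 0.5), m = seq(0, 12, by = 0.5))
  grid$region <- mapply(classify_region, grid$a_E, grid$m)
  write_csv12(grid, file.path(dir, "region_map.csv"))
  for (v in c("model1", "model2", "model3")) {
    cfg <- model_preset(v)
    write_csv12(equilibrium_branch(cfg$population, cfg$inputs),
                file.path(dir, paste0("equilibrium_", v, ".csv")))
  }
}

reproduce_fig4 <- function(dir) {
  cfg <- model_preset("model1")
  for (IN in c(0, 1, 8)) {
    write_csv12(equilibrium_branch(cfg$population, cfg$inputs, I_N = IN),
                file.path(dir, sprintf("equilibrium_IN%g.csv", IN)))
  }
  runs <- list(list("tone_only", 0.5, 0), list("tone_only", 1.5, 0),
               list("masking", 0.5, 1), list("masking", 1.5, 1),
               list("continuity", 1.5, 0), list("continuity", 1.5, 8))
  for (r in runs) {
    sim <- simulate_model(cfg, build_scenario(r[[1]], I_T = r[[2]],
                                              I_N = r[[3]]))
    export_simulation(sim, file.path(dir, sprintf("traj_%s_IT%g_IN%g.csv",
                                                  r[[1]], r[[2]], r[[3]])))
  }
  grid <- seq(1.05, 5, by = 0.25)
  write_csv12(threshold_curve(cfg, "masking", I_T = grid),
              file.path(dir, "masking_threshold.csv"))
  write_csv12(threshold_curve(cfg, "continuity", I_T = grid),
              file.path(dir, "continuity_threshold.csv"))
  write_csv12(sweep_aI_alpha(cfg), file.path(dir, "aI_alpha_sweep.csv"))
}

separatrix_csv <- function(cfg, gamma, I_T, I_N, path) {
  lin <- linear_separatrix(cfg, gamma, I_T = I_T, I_N = I_N)
  num <- numeric_separatrix(cfg, gamma, I_T = I_T, I_N = I_N)
  num$s_linear <- separatrix_height(lin, num$x)
  names(num)[names(num) == "s"] <- "s_numeric"
  write_csv12(num[, c("x", "s_linear", "s_numeric", "branch")], path)
}

reproduce_fig5 <- function(dir) {
  cfg <- model_preset("model2")
  separatrix_csv(cfg, cfg$inputs$gamma_on, 0, 0,
                 file.path(dir, "separatrix.csv"))
  runs <- list(list("tone_only", 0.8, 0), list("tone_only", 1.2, 0),
               list("masking", 3, 3.2), list("continuity", 3, 3))
  for (r in runs) {
    sim <- simulate_model(cfg, build_scenario(r[[1]], I_T = r[[2]],
                                              I_N = r[[3]]))
    export_simulation(sim, file.path(dir, sprintf("traj_%s_IT%g_IN%g.csv",
                                                  r[[1]], r[[2]], r[[3]])))
  }
  grid <- seq(1.05, 5, by = 0.25)
  write_csv12(threshold_curve(cfg, "masking", I_T = grid),
              file.path(dir, "masking_threshold.csv"))
  write_csv12(threshold_curve(cfg, "continuity", I_T = grid),
              file.path(dir, "continuity_threshold.csv"))
}

reproduce_fig6 <- function(dir) {
  cfg <- model_preset("model3")
  write_csv12(equilibrium_branch(cfg$population, cfg$inputs),
              file.path(dir, "equilibrium.csv"))
  variants <- list(
    sustained_only = model_config(cfg$population, cfg$inputs,
                                  sustained = TRUE, transient = FALSE,
                                  inhib = TRUE),
    transient_only = model_config(cfg$population, cfg$inputs,
                                  sustained = FALSE, transient = TRUE,
                                  inhib = FALSE),
    combined = cfg)
  for (nm in names(variants)) {
    sim <- simulate_model(variants[[nm]],
                          build_scenario("tone_only", I_T = 1.5))
    export_simulation(sim, file.path(dir, sprintf("traj_%s.csv", nm)))
  }
}

reproduce_fig7 <- function(dir) {
  cfg <- model_preset("model3")
  separatrix_csv(cfg, cfg$inputs$gamma_on, 1.2, 0,
                 file.path(dir, "separatrix_tone_onset.csv"))
  runs <- list(list("tone_only", 1.2, 0), list("masking", 2, 1.5),
               list("continuity", 2, 1.5))
  for (r in runs) {
    sim <- simulate_model(cfg, build_scenario(r[[1]], I_T = r[[2]],
                                              I_N = r[[3]]))
    export_simulation(sim, file.path(dir, sprintf("traj_%s_IT%g_IN%g.csv",
                                                  r[[1]], r[[2]], r[[3]])))
  }
  grid <- seq(1.05, 5, by = 0.25)
  write_csv12(threshold_curve(cfg, "masking", I_T = grid),
              file.path(dir, "masking_threshold.csv"))
  write_csv12(threshold_curve(cfg, "continuity", I_T = grid),
              file.path(dir, "continuity_threshold.csv"))
  write_csv12(sweep_gamma_off(cfg, gamma_off = c(0.2, 0.88, 2),
                              I_T = seq(1.2, 5, length.out = 8)),
              file.path(dir, "gamma_off_sweep.csv"))
}
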