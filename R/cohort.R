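# Cohort-level phantom study: per-animal bouton density from multi-section
# phantoms, mirroring the structure of the innervation group contrasts.

#' Simulate and quantify a two-group bouton-density phantom cohort
#'
#' For each animal, `n_sections` histology phantoms are generated and
#' quantified ([detect_boutons()] on the green channel, [detect_axons()]
#' on the red channel); counts and lengths are summed across sections
#' before forming the per-animal density (boutons per 100 um of axon),
#' the same pooling used for the real innervation metrics. Group B's
#' planted bouton density is reduced by `deficit` (e.g. 0.16 for a 16%
#' deficit); the group contrast is then tested with a two-tailed Student
#' t test.
#'
#' @param n_per_group Animals per group (default 7).
#' @param deficit Fractional reduction of group B's planted density
#'   (default 0.16).
#' @param density Control bouton density, per 100 um (default 12).
#' @param n_sections Sections per animal (default 3).
#' @param spec Template [phantom_spec()] providing image geometry and
#'   rendering parameters; its density and seed fields are overridden.
#' @param seed Integer seed for the whole cohort.
#' @return A list: `animals` (data.frame with group, animal,
#'   bouton_count, axon_length_um, boutons_per_100um), `test`
#'   (`test_result`), `measured_deficit_pct` (percent reduction of the
#'   group-B mean density relative to group A).
#' @export
simulate_bouton_cohort <- function(n_per_group = 7, deficit = 0.16,
                                   density = 12, n_sections = 3,
                                   spec = phantom_spec(), seed = 1) {
  with_seed(seed, {
    seeds <- matrix(sample.int(.Machine$integer.max,
                               2 * n_per_group * n_sections),
                    nrow = 2 * n_per_group)
    rows <- vector("list", 2 * n_per_group)
    for (a in seq_len(2 * n_per_group)) {
      grp <- if (a <= n_per_group) "A" else "B"
      dens <- if (grp == "A") density else density * (1 - deficit)
      cnt <- 0L
      len <- 0
      for (s in seq_len(n_sections)) {
        sp <- spec
        sp$bouton_density_per_100um <- dens
        sp$seed <- seeds[a, s]
        ph <- simulate_histology(sp)
        cnt <- cnt + detect_boutons(ph$green, sp$pixel_size)$count
        len <- len + detect_axons(ph$red, sp$pixel_size)$length_um
      }
      rows[[a]] <- data.frame(group = grp, animal = a, bouton_count = cnt,
                              axon_length_um = len,
                              boutons_per_100um = 100 * cnt / len)
    }
    animals <- do.call(rbind, rows)
    dens_a <- animals$boutons_per_100um[animals$group == "A"]
    dens_b <- animals$boutons_per_100um[animals$group == "B"]
    list(animals = animals,
         test = t_from_samples(dens_a, dens_b),
         measured_deficit_pct = 100 * (1 - mean(dens_b) / mean(dens_a)))
  })
}

#' Simulate and analyze a pooled miniscope imaging cohort
#'
#' Generates `n_mice` full sessions (choice sequence, trajectory, arm
#' entries, 20-bin trials) and a position-tuned ensemble per mouse, then
#' runs the ensemble analyses and pools cells across mice the way the
#' group contrasts pool them: per-neuron peak bins from the
#' trial-averaged position map and the alternation-selectivity map.
#'
#' The tuning structure is configurable so that one call can produce a
#' "coordinated" cohort (peak bins enriched just before the maze center,
#' a sizable alternation-selective subpopulation, high alternation bias)
#' and another a "flattened" cohort (uniform peaks, few selective cells,
#' alternation near chance).
#'
#' @param n_mice Number of mice (default 8).
#' @param neurons_per_mouse Cells contributed per mouse (default 63).
#' @param p_alt Alternation bias of the agents.
#' @param n_entries Arm entries per session (default 30).
#' @param precenter_frac Fraction of neurons whose peak bin is drawn from
#'   `precenter_window` instead of uniformly from all bins (0 = uniform
#'   tuning).
#' @param precenter_window Bin window for the enrichment (default 8:10).
#' @param frac_selective Fraction of neurons given trial-type-dependent
#'   amplitude (gain `selective_gain` on alternating trials).
#' @param selective_weight_precenter Odds weighting with which the
#'   selective subpopulation is drawn from neurons peaking inside
#'   `precenter_window` (default 3, mirroring the concentration of
#'   alternation-selective cells just before the maze center; 1 =
#'   selectivity independent of tuning).
#' @param selective_gain Amplitude gain on alternating trials.
#' @param noise_sd Trace noise SD in dF/F0 units (default 0.1, i.e.
#'   SNR 10 for unit-amplitude transients).
#' @param seed Integer seed.
#' @return A list: `peak_bin` (pooled integer vector), `selectivity`
#'   (pooled `selectivity_map`-like list with `selective` and
#'   `assessable`), `alternation_pct` (per mouse), `ground_truth`
#'   (pooled planted peak bins and selective flags).
#' @export
simulate_imaging_cohort <- function(n_mice = 8, neurons_per_mouse = 63,
                                    p_alt = 0.7, n_entries = 30,
                                    precenter_frac = 0.3,
                                    precenter_window = 8:10,
                                    frac_selective = 0.2,
                                    selective_weight_precenter = 3,
                                    selective_gain = 2, noise_sd = 0.1,
                                    seed = 1) {
  with_seed(seed, {
    seeds <- matrix(sample.int(.Machine$integer.max, 3 * n_mice), n_mice)
    peaks <- integer(0)
    sel_rows <- list()
    assess <- logical(0)
    gt_peaks <- integer(0)
    gt_sel <- logical(0)
    alt_pct <- numeric(n_mice)
    for (m in seq_len(n_mice)) {
      sq <- simulate_choice_sequence(
        agent_spec(p_alt = p_alt, n_entries = n_entries,
                   seed = seeds[m, 1]))
      traj <- simulate_trajectory(sq)
      ent <- detect_arm_entries(traj)
      alt_pct[m] <- alternation_percentage(ent)$alternation_pct
      trials <- segment_trials(traj, ent)
      n_pre <- stats::rbinom(1, neurons_per_mouse, precenter_frac)
      pk <- c(sample(precenter_window, n_pre, replace = TRUE),
              sample.int(trials$n_bins, neurons_per_mouse - n_pre,
                         replace = TRUE))
      pk <- sample(pk)
      n_sel <- stats::rbinom(1, neurons_per_mouse, frac_selective)
      w <- ifelse(pk %in% precenter_window, selective_weight_precenter, 1)
      sel_flag <- logical(neurons_per_mouse)
      if (n_sel > 0)
        sel_flag[sample.int(neurons_per_mouse, n_sel, prob = w)] <- TRUE
      tun <- tuning_spec(neurons_per_mouse, peak_bin = pk,
                         selective = sel_flag,
                         selective_gain = selective_gain,
                         noise_sd = noise_sd, seed = seeds[m, 2])
      sim <- simulate_ensemble(trials, tun)
      pm <- position_activity_map(sim$traces, trials)
      sl <- alternation_selectivity(sim$traces, trials)
      peaks <- c(peaks, pm$peak_bin)
      sel_rows[[m]] <- sl$selective
      assess <- c(assess, sl$assessable)
      gt_peaks <- c(gt_peaks, pk)
      gt_sel <- c(gt_sel, sel_flag)
    }
    list(peak_bin = peaks,
         selectivity = list(selective = do.call(rbind, sel_rows),
                            assessable = assess),
         alternation_pct = alt_pct,
         ground_truth = list(peak_bin = gt_peaks, selective = gt_sel))
  })
}
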