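#' Configuration for the two-arm simulation pipeline
#'
#' Bundles and validates the per-stage parameters for a control versus
#' nanoparticle-loaded simulation comparison. The defaults describe a
#' desk-scale demonstration phantom: a 0.05 um^3 water sphere with four
#' core-shell particles, a 300 bp procedural duplex placed beside the first
#' particle so that it lies inside the near-particle enhancement annulus, an
#' energetic-process-weighted track configuration, and a dose chosen so the
#' nanoparticle arm sits near the DSB-count optimum of the clustering rule
#' (roughly one SSB per 10 bp) while the control stays well below it. Damage
#' rates are normalized per Gy and per Gbp, so arm comparisons
#' (amplification factors) are meaningful at this scale.
#'
#' @param phantom List: `n_particles`, `sphere_volume` (um^3),
#'   `core_diameter`, `shell_thickness` (nm), `shell_material`.
#' @param duplex List: `n_bp`, `capture_radius` (nm), `gap_nm` (distance from
#'   the first particle's surface to the duplex axis).
#' @param track A [track_config()]; the control arm runs it with all
#'   enhancement factors forced to zero.
#' @param damage A [damage_config()].
#' @param target_dose Gy.
#' @param seeds List with integer `phantom`, `control`, `np`.
#' @return A validated list of class `simulation_config`.
#' @export
simulation_config <- function(
    phantom = list(n_particles = 4, sphere_volume = 0.05,
                   core_diameter = 3, shell_thickness = 2,
                   shell_material = "Pt"),
    duplex = list(n_bp = 300, capture_radius = 2, gap_nm = 5),
    track = track_config(
      process_frequencies = c(elastic = 0.2, electronic_excitation = 0.1,
                              vibrational_excitation = 0.2, ionization = 0.45,
                              attachment = 0.05),
      enhancement_factor = c(Au = 2, Pt = 2.5),
      enhancement_radius = 60),
    damage = damage_config(),
    target_dose = 20000,
    seeds = list(phantom = 101L, control = 201L, np = 301L)) {
  stopifnot(inherits(track, "track_config"), inherits(damage, "damage_config"))
  need <- c("n_particles", "sphere_volume", "core_diameter", "shell_thickness",
            "shell_material")
  if (!all(need %in% names(phantom)))
    stop("phantom block must name: ", paste(need, collapse = ", "))
  if (phantom$n_particles < 1)
    stop("simulation arm needs at least 1 particle")
  if (!all(c("n_bp", "capture_radius", "gap_nm") %in% names(duplex)))
    stop("duplex block must name n_bp, capture_radius, gap_nm")
  if (duplex$n_bp < 1 || duplex$capture_radius <= 0 || duplex$gap_nm < 0)
    stop("invalid duplex block")
  if (target_dose <= 0) stop("target_dose must be positive")
  if (!all(c("phantom", "control", "np") %in% names(seeds)))
    stop("seeds must name phantom, control, np")
  structure(list(phantom = phantom, duplex = duplex, track = track,
                 damage = damage, target_dose = target_dose, seeds = seeds),
            class = "simulation_config")
}

# place the duplex beside the first particle: axis along z, centred at the
# particle's z, offset in x by (outer radius + gap)
place_duplex <- function(config, phantom) {
  d <- config$duplex
  dup <- build_bdna(d$n_bp, capture_radius = d$capture_radius)
  p1 <- phantom$particles[1, ]
  half_len <- (d$n_bp - 1) * 0.34 / 2
  transform_duplex(dup, translation = c(
    p1$cx + p1$outer_radius + d$gap_nm, p1$cy, p1$cz - half_len))
}

#' Run the two-arm (control versus nanoparticle) simulation pipeline
#'
#' Builds the phantom, samples a control phase space (enhancement factors
#' forced to zero: particles present but radiologically inert) and a
#' nanoparticle phase space (configured shell-material enhancement), scores
#' SSBs/DSBs on the duplex in both arms, and reports per-dose per-Gbp DSB
#' rates with the amplification factor. A manifest of all seeds and config
#' digests makes the run bit-reproducible.
#'
#' @param config A [simulation_config()].
#' @return List of class `simulation_result` with `control` and `np`
#'   (`damage_record`s), `phantom`, `duplex`, `af` (percent, `NA` when the
#'   control arm scored zero DSBs), and `manifest`.
#' @export
run_simulation_arm <- function(config = simulation_config()) {
  stopifnot(inherits(config, "simulation_config"))
  ph <- tryCatch(
    build_phantom(config$phantom$n_particles, config$phantom$sphere_volume,
                  config$phantom$core_diameter, config$phantom$shell_thickness,
                  config$phantom$shell_material, seed = config$seeds$phantom),
    error = function(e) stop("phantom stage failed: ", conditionMessage(e)))
  dup <- place_duplex(config, ph)

  control_track <- config$track
  control_track$enhancement_factor[] <- 0

  ps_control <- tryCatch(
    sample_events(ph, config$target_dose, control_track,
                  seed = config$seeds$control),
    error = function(e) stop("tracks stage (control) failed: ", conditionMessage(e)))
  ps_np <- tryCatch(
    sample_events(ph, config$target_dose, config$track,
                  seed = config$seeds$np),
    error = function(e) stop("tracks stage (np) failed: ", conditionMessage(e)))

  rec_control <- score_damage(ps_control, dup, config$damage)
  rec_np <- score_damage(ps_np, dup, config$damage)

  af <- if (rec_control$n_dsb > 0)
    amplification_factor(rec_np$rate, rec_control$rate) else NA_real_

  structure(
    list(control = rec_control, np = rec_np, phantom = ph, duplex = dup,
         af = af,
         manifest = list(
           seeds = config$seeds,
           target_dose = config$target_dose,
           control_config_digest = ps_control$config_digest,
           np_config_digest = ps_np$config_digest,
           n_events = c(control = nrow(ps_control$deposits),
                        np = nrow(ps_np$deposits)))),
    class = "simulation_result"
  )
}

#' @export
print.simulation_result <- function(x, ...) {
  cat(sprintf("simulation_result: control %d DSB (%.3g /Gy/Gbp), NP %d DSB (%.3g /Gy/Gbp), AF %s\n",
              x$control$n_dsb, x$control$rate, x$np$n_dsb, x$np$rate,
              if (is.na(x$af)) "NA" else sprintf("%.1f%%", x$af)))
  invisible(x)
}

#' Run the experimental (gel electrophoresis) analysis arm
#'
#' Fits dose-response yields for the control and nanoparticle-loaded samples
#' (each optionally paired with a DMSO radical-scavenger arm), and reports
#' the amplification factors and the hydroxyl-radical effect decomposition
#' with propagated uncertainties.
#'
#' @param control,np Gel lane data.frames (`dose`, `S`, `R`, `L`) for the
#'   nanoparticle-free and nanoparticle-loaded samples.
#' @param control_dmso,np_dmso Optional scavenged-arm lanes; supply both or
#'   neither.
#' @param staining_factor Supercoiled staining correction.
#' @return Object of class `amplification_result`: list with the four
#'   `dose_response` fits (`NULL` where absent), `af`, `af_se`, `af_dmso`,
#'   `af_dmso_se`, `oh_control`, `oh_np` (each a percent with `_se`).
#' @export
run_experimental_arm <- function(control, np, control_dmso = NULL,
                                 np_dmso = NULL, staining_factor = 1.47) {
  if (is.null(control)) stop("missing arm: control")
  if (is.null(np)) stop("missing arm: np")
  if (is.null(control_dmso) != is.null(np_dmso))
    stop("missing arm: supply both control_dmso and np_dmso, or neither")

  dr_control <- fit_dose_response(control, staining_factor)
  dr_np <- fit_dose_response(np, staining_factor)
  af <- amplification(dr_np, dr_control)

  out <- list(dr_control = dr_control, dr_np = dr_np,
              dr_control_dmso = NULL, dr_np_dmso = NULL,
              af = af$af, af_se = af$af_se,
              af_dmso = NA_real_, af_dmso_se = NA_real_,
              oh_control = NA_real_, oh_control_se = NA_real_,
              oh_np = NA_real_, oh_np_se = NA_real_)

  if (!is.null(control_dmso)) {
    dr_cd <- fit_dose_response(control_dmso, staining_factor)
    dr_nd <- fit_dose_response(np_dmso, staining_factor)
    af_d <- amplification(dr_nd, dr_cd)
    oh_c <- oh_effect(dr_control, dr_cd)
    oh_n <- oh_effect(dr_np, dr_nd)
    out$dr_control_dmso <- dr_cd
    out$dr_np_dmso <- dr_nd
    out$af_dmso <- af_d$af; out$af_dmso_se <- af_d$af_se
    out$oh_control <- oh_c$effect; out$oh_control_se <- oh_c$effect_se
    out$oh_np <- oh_n$effect; out$oh_np_se <- oh_n$effect_se
  }
  structure(out, class = "amplification_result")
}

#' @export
print.amplification_result <- function(x, ...) {
  cat("amplification_result\n")
  cat(sprintf("  m_control = %.4g, m_NP = %.4g breaks/plasmid/Gy\n",
              x$dr_control$slope, x$dr_np$slope))
  cat(sprintf("  AF = %.1f%% +/- %.1f\n", x$af, x$af_se))
  if (!is.null(x$dr_control_dmso)) {
    cat(sprintf("  AF (DMSO) = %.1f%% +/- %.1f\n", x$af_dmso, x$af_dmso_se))
    cat(sprintf("  OH effect: control %.1f%%, NP %.1f%%\n",
                x$oh_control, x$oh_np))
  }
  invisible(x)
}

#' Read a pipeline configuration from a YAML file
#'
#' Keys mirror the [simulation_config()] blocks (`phantom`, `duplex`,
#' `track`, `damage`, `target_dose`, `seeds`); any omitted key falls back to
#' the defaults. All stage parameters are validated before any stage runs.
#'
#' @param path YAML file path.
#' @return A `simulation_config`.
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  defaults <- simulation_config()
  merge_block <- function(name) {
    b <- defaults[[name]]
    if (!is.null(raw[[name]])) b[names(raw[[name]])] <- raw[[name]]
    b
  }
  track <- defaults$track
  if (!is.null(raw$track)) {
    tr <- raw$track
    args <- list()
    for (key in c("process_frequencies", "energy_means", "enhancement_factor"))
      if (!is.null(tr[[key]])) args[[key]] <- unlist(tr[[key]])
    for (key in c("background_event_density", "enhancement_radius", "photon_energy"))
      if (!is.null(tr[[key]])) args[[key]] <- tr[[key]]
    full <- list(process_frequencies = track$process_frequencies,
                 energy_means = track$energy_means,
                 background_event_density = track$background_event_density,
                 enhancement_factor = track$enhancement_factor,
                 enhancement_radius = track$enhancement_radius,
                 photon_energy = track$photon_energy)
    full[names(args)] <- args
    track <- do.call(track_config, full)
  }
  damage <- defaults$damage
  if (!is.null(raw$damage)) {
    dm <- list(ssb_energy_threshold = damage$ssb_energy_threshold,
               dsb_bp_threshold = damage$dsb_bp_threshold)
    dm[names(raw$damage)] <- raw$damage
    damage <- do.call(damage_config, dm)
  }
  seeds <- defaults$seeds
  if (!is.null(raw$seeds)) seeds[names(raw$seeds)] <- lapply(raw$seeds, as.integer)
  simulation_config(
    phantom = merge_block("phantom"),
    duplex = merge_block("duplex"),
    track = track,
    damage = damage,
    target_dose = if (!is.null(raw$target_dose)) raw$target_dose else defaults$target_dose,
    seeds = seeds
  )
}
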