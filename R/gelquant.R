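#' Normalize gel densitometry lanes to DSB counts per plasmid
#'
#' Converts raw band intensities of the supercoiled (S), relaxed (R) and
#' linear (L) plasmid conformations into the per-plasmid DSB count. The
#' supercoiled band stains more weakly with ethidium bromide, so the total is
#' `staining_factor * S + R + L` (default 1.47); the linear fraction is
#' `L' = L / total`, and the Poisson inversion gives
#' `DSB per plasmid = L' / (1 - L')` (the mean of a Poisson break count whose
#' zero-and-one classes are not linearized).
#'
#' @param lanes data.frame with columns `S`, `R`, `L` (any other columns such
#'   as `dose` and `replicate` are carried through).
#' @param staining_factor Supercoiled staining correction, dimensionless.
#' @return The input with added columns `total`, `l_prime`,
#'   `dsb_per_plasmid`.
#' @export
#' @examples
#' normalize_lane(data.frame(S = 0, R = 0.5, L = 0.5))  # 1 DSB per plasmid
normalize_lane <- function(lanes, staining_factor = 1.47) {
  stopifnot(all(c("S", "R", "L") %in% names(lanes)))
  if (any(lanes$S < 0 | lanes$R < 0 | lanes$L < 0))
    stop("band intensities must be non-negative")
  total <- staining_factor * lanes$S + lanes$R + lanes$L
  if (any(total <= 0)) stop("lane with all-zero band intensities")
  l_prime <- lanes$L / total
  if (any(l_prime >= 1))
    stop("all-linear lane (L' = 1): Poisson inversion undefined")
  lanes$total <- total
  lanes$l_prime <- l_prime
  lanes$dsb_per_plasmid <- l_prime / (1 - l_prime)
  lanes
}

#' Fit a DSB dose-response line
#'
#' Normalizes the lanes and fits an unweighted least-squares line of
#' per-plasmid DSB count against dose, pooling all replicates. The slope is
#' the damage yield m_DSB in breaks per plasmid per Gy; the intercept is left
#' free (native plasmid preparations can carry background damage). Per-dose
#' standard deviations across replicates are retained for plotting.
#'
#' @param lanes data.frame with `dose`, `S`, `R`, `L` (and optionally
#'   `replicate`).
#' @param staining_factor Supercoiled staining correction.
#' @return Object of class `dose_response`: list with `slope`, `slope_se`,
#'   `intercept`, `doses`, `yield_mean`, `yield_sd`, `n_lanes`, `fit`.
#' @export
fit_dose_response <- function(lanes, staining_factor = 1.47) {
  stopifnot("dose" %in% names(lanes))
  norm <- normalize_lane(lanes, staining_factor)
  doses <- sort(unique(norm$dose))
  if (length(doses) < 3)
    stop("need at least 3 distinct doses for a dose-response fit (got ",
         length(doses), ")")
  fit <- stats::lm(dsb_per_plasmid ~ dose, data = norm)
  # classical slope SE: sqrt(RSS / (n - 2) / Sxx); computed directly so a
  # perfect (zero-residual) fit cleanly reports SE = 0
  rss <- sum(stats::residuals(fit)^2)
  sxx <- sum((norm$dose - mean(norm$dose))^2)
  slope_se <- sqrt(rss / (nrow(norm) - 2) / sxx)
  structure(
    list(slope = unname(stats::coef(fit)[["dose"]]),
         slope_se = slope_se,
         intercept = unname(stats::coef(fit)[["(Intercept)"]]),
         doses = doses,
         yield_mean = as.numeric(tapply(norm$dsb_per_plasmid, norm$dose, mean)[as.character(doses)]),
         yield_sd = as.numeric(tapply(norm$dsb_per_plasmid, norm$dose, stats::sd)[as.character(doses)]),
         n_lanes = nrow(norm),
         fit = fit),
    class = "dose_response"
  )
}

#' @export
print.dose_response <- function(x, ...) {
  cat(sprintf("dose_response: m_DSB = %.4g +/- %.2g breaks/plasmid/Gy (%d lanes, %d doses)\n",
              x$slope, x$slope_se, x$n_lanes, length(x$doses)))
  invisible(x)
}

#' Amplification factor between two fitted dose responses
#'
#' `AF = 100 * (m_NP - m_control) / m_control`, with the uncertainty obtained
#' by first-order propagation of the two slope standard errors.
#'
#' @param dr_np,dr_control `dose_response` fits for the nanoparticle-loaded
#'   and control samples.
#' @return List with `af` (percent) and `af_se`.
#' @export
amplification <- function(dr_np, dr_control) {
  stopifnot(inherits(dr_np, "dose_response"), inherits(dr_control, "dose_response"))
  m0 <- dr_control$slope
  if (m0 <= 0) stop("control slope must be positive")
  m1 <- dr_np$slope
  af <- 100 * (m1 - m0) / m0
  af_se <- 100 * sqrt((dr_np$slope_se / m0)^2 +
                      (m1 * dr_control$slope_se / m0^2)^2)
  list(af = af, af_se = af_se)
}

#' Hydroxyl-radical effect from scavenger suppression
#'
#' Fraction of the damage yield suppressed by a hydroxyl-radical scavenger
#' (DMSO): `100 * (m - m_DMSO) / m`. This estimates the indirect,
#' water-radiolysis-mediated share of the damage.
#'
#' @param dr,dr_dmso `dose_response` fits without and with the scavenger.
#' @return List with `effect` (percent) and `effect_se` (first-order
#'   propagation).
#' @export
oh_effect <- function(dr, dr_dmso) {
  stopifnot(inherits(dr, "dose_response"), inherits(dr_dmso, "dose_response"))
  m <- dr$slope
  if (m <= 0) stop("unscavenged slope must be positive")
  md <- dr_dmso$slope
  effect <- 100 * (m - md) / m
  effect_se <- 100 * sqrt((dr_dmso$slope_se / m)^2 +
                          (md * dr$slope_se / m^2)^2)
  list(effect = effect, effect_se = effect_se)
}

#' Generate synthetic gel lanes from a forward Poisson damage model
#'
#' Forward model of the plasmid relaxation assay. At dose D the true mean DSB
#' count per plasmid is `mu = m_dsb_true * D`; the exact inverse of the
#' Poisson quantification gives the linear fraction `l = mu / (1 + mu)`. The
#' surviving (non-linear) plasmid is split between supercoiled and relaxed by
#' exponential single-strand-break conversion:
#' `s = (1 - l) * exp(-m_ssb_true * D)`, `r = 1 - l - s`. Measured band
#' intensities are `(s / staining_factor, r, l)` plus independent Gaussian
#' noise of standard deviation `noise_sd`, truncated at zero, per replicate
#' (densitometry noise lives on intensities, before normalization).
#'
#' With `noise_sd = 0`, [normalize_lane()] followed by [fit_dose_response()]
#' recovers `m_dsb_true` exactly: the generator is the exact inverse of the
#' quantification chain.
#'
#' @param doses Doses in Gy.
#' @param m_dsb_true True DSB yield, breaks/plasmid/Gy (>= 0).
#' @param m_ssb_true True SSB yield driving supercoiled-to-relaxed
#'   conversion, breaks/plasmid/Gy; defaults to `20 * m_dsb_true`, a typical
#'   SSB:DSB ratio for sparsely ionizing radiation.
#' @param noise_sd Gaussian intensity noise SD, in fraction units.
#' @param replicates Replicates per dose.
#' @param seed Integer seed (lanes are deterministic per seed).
#' @param staining_factor Supercoiled staining correction used to *encode*
#'   the supercoiled intensity; analyze with the same factor.
#' @return data.frame with columns `dose`, `replicate`, `S`, `R`, `L`.
#' @export
synth_gel <- function(doses, m_dsb_true, m_ssb_true = 20 * m_dsb_true,
                      noise_sd = 0.01, replicates = 3, seed = 1L,
                      staining_factor = 1.47) {
  if (m_dsb_true < 0 || m_ssb_true < 0) stop("true yields must be >= 0")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  if (replicates < 1) stop("replicates must be >= 1")
  mu <- m_dsb_true * doses
  l <- mu / (1 + mu)
  if (any(!is.finite(l) | l >= 1))
    stop("parameters produce an all-linear lane (l >= 1)")
  s <- (1 - l) * exp(-m_ssb_true * doses)
  r <- 1 - l - s

  lanes <- data.frame(
    dose = rep(doses, each = replicates),
    replicate = rep(seq_len(replicates), times = length(doses)),
    S = rep(s / staining_factor, each = replicates),
    R = rep(r, each = replicates),
    L = rep(l, each = replicates)
  )
  if (noise_sd > 0) {
    rng <- local_rng(seed)
    n <- nrow(lanes)
    lanes$S <- pmax(0, lanes$S + rng$rnorm(n, 0, noise_sd))
    lanes$R <- pmax(0, lanes$R + rng$rnorm(n, 0, noise_sd))
    lanes$L <- pmax(0, lanes$L + rng$rnorm(n, 0, noise_sd))
  }
  lanes
}

#' Write / read gel lanes as CSV
#'
#' Columns `dose_Gy, replicate, S, R, L`.
#'
#' @param lanes data.frame as produced by [synth_gel()].
#' @param path File path.
#' @return `write_gel_lanes` returns `path` invisibly; `read_gel_lanes` the
#'   lanes data.frame.
#' @export
write_gel_lanes <- function(lanes, path) {
  out <- data.frame(dose_Gy = lanes$dose, replicate = lanes$replicate,
                    S = lanes$S, R = lanes$R, L = lanes$L)
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_gel_lanes
#' @export
read_gel_lanes <- function(path) {
  raw <- utils::read.csv(path)
  need <- c("dose_Gy", "replicate", "S", "R", "L")
  if (!all(need %in% names(raw)))
    stop("gel lane file must have columns: ", paste(need, collapse = ", "))
  data.frame(dose = raw$dose_Gy, replicate = raw$replicate,
             S = raw$S, R = raw$R, L = raw$L)
}
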