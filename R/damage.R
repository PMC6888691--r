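#' Damage-calling configuration
#'
#' An SSB is called at a sugar-phosphate site whose accumulated energy
#' strictly exceeds `ssb_energy_threshold` (default 8.22 eV, the ionization
#' energy scale of the DNA molecule). SSBs on opposite strands within
#' `dsb_bp_threshold` base pairs (default 10, inclusive) cluster into a DSB.
#'
#' @param ssb_energy_threshold eV, > 0.
#' @param dsb_bp_threshold Base pairs, > 0.
#' @return A list of class `damage_config`.
#' @export
damage_config <- function(ssb_energy_threshold = 8.22, dsb_bp_threshold = 10) {
  if (ssb_energy_threshold <= 0) stop("ssb_energy_threshold must be positive")
  if (dsb_bp_threshold <= 0) stop("dsb_bp_threshold must be positive")
  structure(list(ssb_energy_threshold = ssb_energy_threshold,
                 dsb_bp_threshold = dsb_bp_threshold),
            class = "damage_config")
}

#' Accumulate deposit energies onto duplex sensitive sites
#'
#' Each energy deposit is assigned to its nearest sensitive site if it lies
#' within that site's capture radius, and discarded otherwise; a deposit is
#' never counted twice. Site energy is the sum of its assigned deposit
#' energies.
#'
#' @param ps A `phase_space`.
#' @param duplex A `duplex_geometry`.
#' @return Numeric vector of accumulated energies (eV), one per row of
#'   `duplex$sites`.
#' @export
accumulate <- function(ps, duplex) {
  stopifnot(inherits(ps, "phase_space"), inherits(duplex, "duplex_geometry"))
  sites <- duplex$sites
  energies <- numeric(nrow(sites))
  d <- ps$deposits
  if (nrow(d) == 0 || nrow(sites) == 0) return(energies)

  r_max <- max(sites$capture_radius)
  # cheap bounding-box prefilter: the duplex occupies a tiny fraction of the
  # phantom, so nearly all deposits are rejected here
  keep <- d$x >= min(sites$x) - r_max & d$x <= max(sites$x) + r_max &
    d$y >= min(sites$y) - r_max & d$y <= max(sites$y) + r_max &
    d$z >= min(sites$z) - r_max & d$z <= max(sites$z) + r_max
  d <- d[keep, , drop = FALSE]
  if (nrow(d) == 0) return(energies)

  S <- as.matrix(sites[, c("x", "y", "z")])
  s2 <- rowSums(S^2)
  chunk <- max(1L, floor(5e6 / nrow(S)))
  for (start in seq(1L, nrow(d), by = chunk)) {
    idx <- start:min(start + chunk - 1L, nrow(d))
    P <- cbind(d$x[idx], d$y[idx], d$z[idx])
    # squared distances deposit x site
    d2 <- outer(rowSums(P^2), s2, `+`) - 2 * P %*% t(S)
    nearest <- max.col(-d2, ties.method = "first")
    within <- d2[cbind(seq_along(idx), nearest)] <=
      sites$capture_radius[nearest]^2
    if (any(within)) {
      acc <- tapply(d$energy[idx][within], nearest[within], sum)
      ii <- as.integer(names(acc))
      energies[ii] <- energies[ii] + as.numeric(acc)
    }
  }
  energies
}

#' Call single-strand breaks from accumulated site energies
#'
#' @param site_energy Energies (eV) aligned with `duplex$sites`.
#' @param duplex The `duplex_geometry` the energies were accumulated on.
#' @param cfg A [damage_config()].
#' @return data.frame with columns `strand`, `bp_index`, `energy`, one row
#'   per SSB (site energy strictly greater than the threshold).
#' @export
call_ssb <- function(site_energy, duplex, cfg = damage_config()) {
  stopifnot(inherits(duplex, "duplex_geometry"), inherits(cfg, "damage_config"))
  hit <- site_energy > cfg$ssb_energy_threshold
  out <- duplex$sites[hit, c("strand", "bp_index"), drop = FALSE]
  out$energy <- site_energy[hit]
  rownames(out) <- NULL
  out
}

#' Cluster single-strand breaks into double-strand breaks
#'
#' SSBs are sorted by base-pair index and swept left to right; an SSB joins
#' the current cluster when its gap to the cluster's last member is at most
#' `dsb_bp_threshold` base pairs (chain rule; opposite-strand breaks at the
#' same index have gap 0). A cluster is one DSB if and only if it contains
#' breaks on both strands; a cluster never yields more than one DSB, and
#' every SSB belongs to exactly one cluster.
#'
#' @param ssbs data.frame with `strand`, `bp_index` (as from [call_ssb()]).
#' @param cfg A [damage_config()].
#' @return List with `clusters` (list of data.frames of clustered SSBs),
#'   `dsb_clusters` (the subset spanning both strands) and `n_dsb`.
#' @export
call_dsb <- function(ssbs, cfg = damage_config()) {
  stopifnot(inherits(cfg, "damage_config"))
  if (is.null(ssbs) || nrow(ssbs) == 0)
    return(list(clusters = list(), dsb_clusters = list(), n_dsb = 0L))
  ssbs <- ssbs[order(ssbs$bp_index, ssbs$strand), , drop = FALSE]
  gap <- diff(ssbs$bp_index)
  cluster_id <- cumsum(c(1L, as.integer(gap > cfg$dsb_bp_threshold)))
  clusters <- split(ssbs, cluster_id)
  names(clusters) <- NULL
  is_dsb <- vapply(clusters, function(cl)
    nrow(cl) >= 2 && length(unique(cl$strand)) == 2, logical(1))
  list(clusters = clusters,
       dsb_clusters = clusters[is_dsb],
       n_dsb = sum(is_dsb))
}

#' Normalize a DSB count to a rate per gray per gigabase pair
#'
#' @param n_dsb DSB count.
#' @param dose Absorbed dose, Gy (> 0).
#' @param length_bp Scored duplex length, base pairs (> 0).
#' @return Rate in Gy^-1 Gbp^-1: `n_dsb / dose / (length_bp / 1e9)`.
#' @export
dsb_rate <- function(n_dsb, dose, length_bp) {
  if (dose <= 0) stop("dose must be positive")
  if (length_bp <= 0) stop("length_bp must be positive")
  n_dsb / dose / (length_bp / 1e9)
}

#' Amplification factor of a damage rate over a control
#'
#' Percentage increase of the nanoparticle-loaded damage yield relative to
#' the nanoparticle-free control: `100 * (y_np - y_control) / y_control`.
#'
#' @param y_np Damage yield or rate with nanoparticles.
#' @param y_control Control yield or rate (> 0).
#' @return Amplification factor in percent.
#' @export
#' @examples
#' amplification_factor(13.10, 9.32)  # ~40.6%
amplification_factor <- function(y_np, y_control) {
  if (y_control <= 0) stop("control yield must be positive")
  100 * (y_np - y_control) / y_control
}

#' Score a phase space against a duplex geometry
#'
#' Convenience wrapper chaining [accumulate()], [call_ssb()] and
#' [call_dsb()], with per-dose, per-length rate normalization.
#'
#' @param ps A `phase_space`.
#' @param duplex A `duplex_geometry`.
#' @param cfg A [damage_config()].
#' @param dose Dose used for rate normalization, Gy; defaults to the phase
#'   space's target dose.
#' @return An object of class `damage_record`: list with `site_energy`,
#'   `ssbs`, `dsbs` (the [call_dsb()] result), `n_ssb`, `n_dsb`, `dose`,
#'   `duplex_length` and `rate` (Gy^-1 Gbp^-1).
#' @export
score_damage <- function(ps, duplex, cfg = damage_config(), dose = NULL) {
  if (is.null(dose)) dose <- ps$target_dose
  site_energy <- accumulate(ps, duplex)
  ssbs <- call_ssb(site_energy, duplex, cfg)
  dsbs <- call_dsb(ssbs, cfg)
  structure(
    list(site_energy = site_energy, ssbs = ssbs, dsbs = dsbs,
         n_ssb = nrow(ssbs), n_dsb = dsbs$n_dsb, dose = dose,
         duplex_length = duplex$n_bp,
         rate = dsb_rate(dsbs$n_dsb, dose, duplex$n_bp)),
    class = "damage_record"
  )
}

#' @export
print.damage_record <- function(x, ...) {
  cat(sprintf("damage_record: %d SSB(s), %d DSB(s) on %d bp at %.4g Gy -> %.4g DSB/Gy/Gbp\n",
              x$n_ssb, x$n_dsb, x$duplex_length, x$dose, x$rate))
  invisible(x)
}
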