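#' Build a nanoparticle-loaded water phantom
#'
#' Places `n_particles` non-overlapping core-shell nanoparticles uniformly at
#' random inside a spherical water volume. The defaults reproduce the
#' irradiation phantom used throughout this package: 191 particles with 3 nm
#' gold cores and 2 nm shells in a 50 um^3 water sphere.
#'
#' Placement is rejection sampling: centres are drawn uniformly in the sphere
#' interior shrunk by the particle outer radius, and a draw is rejected if it
#' overlaps an already-placed particle (centre distance not exceeding the sum
#' of outer radii). At the dilutions of interest rejections are rare; an
#' error is raised if any particle cannot be placed within `max_retries`
#' attempts, which signals an overcrowded phantom.
#'
#' @param n_particles Number of particles to place (>= 0).
#' @param sphere_volume Water sphere volume in um^3.
#' @param core_diameter Core diameter in nm.
#' @param shell_thickness Shell thickness in nm (>= 0).
#' @param shell_material Shell material label, `"Au"` or `"Pt"`.
#' @param seed Integer seed; the phantom is bit-identical for a fixed seed.
#' @param core_material Core material label (default `"Au"`).
#' @param max_retries Maximum placement attempts per particle.
#'
#' @return An object of class `phantom`: a list with `sphere_volume` (um^3),
#'   `sphere_radius_nm`, `water_density` (kg/m^3), `seed`, and `particles`,
#'   a data.frame with one row per particle (columns `cx`, `cy`, `cz` centre
#'   coordinates in nm, `core_diameter`, `shell_thickness`, `outer_radius`,
#'   `core_material`, `shell_material`).
#' @export
#' @examples
#' ph <- build_phantom(10, 50, 3, 2, "Pt", seed = 1)
#' nrow(ph$particles)
build_phantom <- function(n_particles, sphere_volume = 50,
                          core_diameter = 3, shell_thickness = 2,
                          shell_material = c("Pt", "Au"), seed = 1L,
                          core_material = "Au", max_retries = 1e5) {
  shell_material <- match.arg(shell_material)
  if (!is.finite(sphere_volume) || sphere_volume <= 0)
    stop("sphere_volume must be positive")
  if (n_particles < 0) stop("n_particles must be >= 0")
  if (core_diameter <= 0) stop("core_diameter must be positive")
  if (shell_thickness < 0) stop("shell_thickness must be >= 0")

  radius_nm <- sphere_radius_nm(sphere_volume)
  outer_r <- core_diameter / 2 + shell_thickness
  if (n_particles > 0 && outer_r >= radius_nm)
    stop("particle outer radius exceeds the phantom radius")

  centers <- matrix(numeric(0), ncol = 3)
  if (n_particles > 0) {
    rng <- local_rng(seed)
    placed <- matrix(NA_real_, nrow = n_particles, ncol = 3)
    r_max <- radius_nm - outer_r   # keep particles fully inside the sphere
    for (i in seq_len(n_particles)) {
      ok <- FALSE
      for (try in seq_len(max_retries)) {
        p <- rng$point_in_sphere(r_max)
        if (i == 1L) { ok <- TRUE } else {
          prev <- placed[seq_len(i - 1L), , drop = FALSE]
          d2 <- (prev[, 1] - p[1])^2 + (prev[, 2] - p[2])^2 +
            (prev[, 3] - p[3])^2
          ok <- all(d2 > (2 * outer_r)^2)
        }
        if (ok) { placed[i, ] <- p; break }
      }
      if (!ok)
        stop("failed to place particle ", i, " after ", max_retries,
             " retries: phantom is overcrowded")
    }
    centers <- placed
  }

  particles <- data.frame(
    cx = centers[, 1], cy = centers[, 2], cz = centers[, 3],
    core_diameter = rep(core_diameter, n_particles),
    shell_thickness = rep(shell_thickness, n_particles),
    outer_radius = rep(outer_r, n_particles),
    core_material = rep(core_material, n_particles),
    shell_material = rep(shell_material, n_particles),
    stringsAsFactors = FALSE
  )
  structure(
    list(sphere_volume = sphere_volume, sphere_radius_nm = radius_nm,
         water_density = 1000, seed = as.integer(seed),
         particles = particles),
    class = "phantom"
  )
}

#' @export
print.phantom <- function(x, ...) {
  cat(sprintf(
    "phantom: %d core-shell particle(s) in a %.3g um^3 water sphere (R = %.1f nm)\n",
    nrow(x$particles), x$sphere_volume, x$sphere_radius_nm))
  if (nrow(x$particles) > 0)
    cat(sprintf("  core %.2g nm / shell %.2g nm (%s core, %s shell), seed %d\n",
                x$particles$core_diameter[1], x$particles$shell_thickness[1],
                x$particles$core_material[1], x$particles$shell_material[1],
                x$seed))
  invisible(x)
}

#' Sphere radius from volume
#'
#' @param volume_um3 Sphere volume in um^3.
#' @return Radius in nm, `(3V/4pi)^(1/3)` converted from um.
#' @export
sphere_radius_nm <- function(volume_um3) {
  1000 * (3 * volume_um3 / (4 * pi))^(1 / 3)
}

#' Metal atoms per nanoparticle core
#'
#' Number of atoms in a spherical core of diameter `core_diameter` at bulk
#' atomic density: `(pi/6) d^3 rho`, rounded to the nearest integer. For a
#' 3 nm gold core at 59 atoms/nm^3 this gives 834 atoms, the "about 1000
#' metal atoms" scale of a sub-5 nm particle.
#'
#' @param core_diameter Core diameter, nm.
#' @param atomic_density Bulk atomic density, atoms/nm^3 (Au: 59.0).
#' @return Integer atom count.
#' @export
atoms_per_particle <- function(core_diameter, atomic_density = 59.0) {
  if (core_diameter <= 0) stop("core_diameter must be positive")
  if (atomic_density <= 0) stop("atomic_density must be positive")
  round(pi / 6 * core_diameter^3 * atomic_density)
}

#' Particle count from a metal concentration
#'
#' Converts a molar metal concentration in a given volume to a nanoparticle
#' count: `round(c * N_A * V / atoms_per_particle)`. Note that the pipeline
#' default particle count is a direct configuration input (191); this
#' conversion is provided for bookkeeping and gives ~1274 particles for
#' 4.23e-5 mol/L in 50 um^3 with 1000 atoms per particle.
#'
#' @param metal_concentration mol/L.
#' @param atoms_per_particle Atoms per particle.
#' @param volume Volume in litres.
#' @return Integer particle count (0 for zero volume).
#' @export
particles_from_concentration <- function(metal_concentration,
                                         atoms_per_particle, volume) {
  if (metal_concentration <= 0) stop("metal_concentration must be positive")
  if (atoms_per_particle <= 0) stop("atoms_per_particle must be positive")
  if (volume < 0) stop("volume must be >= 0")
  avogadro <- 6.02214076e23
  round(metal_concentration * avogadro * volume / atoms_per_particle)
}

#' Write / read a phantom as columnar text
#'
#' One particle per row (`cx, cy, cz, core_diameter, shell_thickness,
#' shell_material`, lengths in nm), with `#`-prefixed header lines carrying
#' the seed, sphere volume and core material.
#'
#' @param phantom A `phantom` object.
#' @param path File path.
#' @return `write_phantom` returns `path` invisibly; `read_phantom` returns a
#'   `phantom`.
#' @export
write_phantom <- function(phantom, path) {
  stopifnot(inherits(phantom, "phantom"))
  header <- c(
    sprintf("# seed: %d", phantom$seed),
    sprintf("# sphere_volume_um3: %.17g", phantom$sphere_volume),
    sprintf("# core_material: %s",
            if (nrow(phantom$particles)) phantom$particles$core_material[1] else "Au"),
    "# columns: cx cy cz core_diameter shell_thickness shell_material"
  )
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(header, con)
  p <- phantom$particles
  if (nrow(p) > 0) {
    writeLines(sprintf("%.17g\t%.17g\t%.17g\t%.17g\t%.17g\t%s",
                       p$cx, p$cy, p$cz, p$core_diameter, p$shell_thickness,
                       p$shell_material), con)
  }
  invisible(path)
}

#' @rdname write_phantom
#' @export
read_phantom <- function(path) {
  lines <- readLines(path)
  hdr <- lines[startsWith(lines, "#")]
  body <- lines[!startsWith(lines, "#") & nzchar(lines)]
  get_hdr <- function(key) {
    m <- grep(paste0("^# ", key, ": "), hdr, value = TRUE)
    if (length(m) == 0) stop("missing header field: ", key)
    sub(paste0("^# ", key, ": "), "", m[1])
  }
  seed <- as.integer(get_hdr("seed"))
  vol <- as.numeric(get_hdr("sphere_volume_um3"))
  core_material <- get_hdr("core_material")
  if (length(body) == 0) {
    return(build_phantom(0, vol, seed = seed))
  }
  fields <- strsplit(body, "\t", fixed = TRUE)
  bad <- which(lengths(fields) != 6)
  if (length(bad))
    stop("malformed particle row at line ", bad[1])
  m <- do.call(rbind, fields)
  particles <- data.frame(
    cx = as.numeric(m[, 1]), cy = as.numeric(m[, 2]), cz = as.numeric(m[, 3]),
    core_diameter = as.numeric(m[, 4]), shell_thickness = as.numeric(m[, 5]),
    outer_radius = as.numeric(m[, 4]) / 2 + as.numeric(m[, 5]),
    core_material = core_material, shell_material = m[, 6],
    stringsAsFactors = FALSE
  )
  structure(
    list(sphere_volume = vol, sphere_radius_nm = sphere_radius_nm(vol),
         water_density = 1000, seed = seed, particles = particles),
    class = "phantom"
  )
}

# Seed-scoped RNG helper: runs sampling under a private RNG state so package
# randomness never disturbs the caller's .Random.seed.
local_rng <- function(seed) {
  env <- new.env()
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(as.integer(seed))
  env$state <- get(".Random.seed", globalenv())
  if (is.null(old)) rm(".Random.seed", envir = globalenv())
  else assign(".Random.seed", old, envir = globalenv())

  with_state <- function(f) {
    function(...) {
      old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
      assign(".Random.seed", env$state, envir = globalenv())
      on.exit({
        env$state <- get(".Random.seed", globalenv())
        if (is.null(old)) rm(".Random.seed", envir = globalenv())
        else assign(".Random.seed", old, envir = globalenv())
      })
      f(...)
    }
  }
  env$runif <- with_state(stats::runif)
  env$rnorm <- with_state(stats::rnorm)
  env$rexp <- with_state(stats::rexp)
  env$rpois <- with_state(stats::rpois)
  env$sample_int <- with_state(function(n, size, prob = NULL)
    sample.int(n, size, replace = TRUE, prob = prob))
  # uniform point in a sphere of radius r, via inverse-CDF radius sampling
  env$point_in_sphere <- with_state(function(r) {
    repeat {
      v <- stats::rnorm(3)
      n2 <- sum(v^2)
      if (n2 > 0) break
    }
    u <- stats::runif(1)
    (r * u^(1 / 3) / sqrt(n2)) * v
  })
  # n uniform points in a sphere of radius r (vectorized)
  env$points_in_sphere <- with_state(function(n, r) {
    if (n == 0) return(matrix(numeric(0), ncol = 3))
    v <- matrix(stats::rnorm(3 * n), ncol = 3)
    nv <- sqrt(rowSums(v^2))
    u <- stats::runif(n)
    v * (r * u^(1 / 3) / nv)
  })
  # uniform points in a spherical annulus r1 <= r <= r2 around a centre
  env$points_in_annulus <- with_state(function(n, center, r1, r2) {
    if (n == 0) return(matrix(numeric(0), ncol = 3))
    v <- matrix(stats::rnorm(3 * n), ncol = 3)
    nv <- sqrt(rowSums(v^2))
    u <- stats::runif(n)
    r <- (u * (r2^3 - r1^3) + r1^3)^(1 / 3)
    sweep(v * (r / nv), 2, center, `+`)
  })
  env
}
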