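#' Shell thickness from XPS overlayer attenuation
#'
#' Core-shell particles attenuate core photoelectrons in the shell; the shell
#' thickness follows from the attenuation length of the measured
#' photoelectrons and the overlayer parameter:
#' `T = l_film * cos(theta) * ln(1 + r_overlayer)`.
#'
#' For the Au-core/Pt-shell system measured at normal emission
#' (`theta = 0`), with the gold 4f attenuation length `l_film = 1.02` nm and
#' overlayer parameter `r_overlayer = 3` (the mean core diameter value), the
#' shell thickness is 1.4 nm to one decimal. The platinum attenuation length
#' (1.05 nm) is available by argument.
#'
#' @param l_film Electron attenuation length in the film, nm (> 0). 1.02 for
#'   Au-4f photoelectrons, 1.05 for Pt.
#' @param theta Scattering (take-off) angle in degrees, `0 <= theta < 90`.
#' @param r_overlayer Dimensionless overlayer parameter (>= 0).
#' @return Shell thickness in nm.
#' @export
#' @examples
#' shell_thickness(1.02, 0, 3)  # 1.414 -> 1.4 nm
shell_thickness <- function(l_film = 1.02, theta = 0, r_overlayer = 3) {
  if (!is.finite(l_film) || l_film <= 0) stop("l_film must be positive")
  if (theta < 0 || theta >= 90)
    stop("theta must be in [0, 90) degrees")
  if (r_overlayer < 0) stop("r_overlayer must be >= 0")
  l_film * cos(theta * pi / 180) * log(1 + r_overlayer)
}
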