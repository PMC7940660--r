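# Physical constants and unit conversions.
# Internally every quantity is SI: wavenumbers in 1/m, angular frequencies in
# rad/s, densities in kg/m^3.  Data files and the printed literature values
# use nm^-1 and ps^-1; conversion happens only at the I/O boundary.

#' Boltzmann constant (J/K), CODATA 2018 exact value
#' @export
k_boltzmann <- 1.380649e-23

#' Unit conversions between SI and terahertz-spectroscopy units
#'
#' Dispersion data in this field are tabulated with wavenumbers in inverse
#' nanometres and angular excitation frequencies in inverse picoseconds.
#' These helpers convert to and from the SI units (1/m, rad/s) used
#' internally.
#'
#' @param x numeric vector to convert.
#' @return numeric vector in the target unit.
#' @examples
#' invnm_to_si(2.0)   # 2.0 nm^-1 -> 2e9 m^-1
#' si_to_invps(4.9e12)
#' @export
invnm_to_si <- function(x) x * 1e9

#' @rdname invnm_to_si
#' @export
si_to_invnm <- function(x) x / 1e9

#' @rdname invnm_to_si
#' @export
invps_to_si <- function(x) x * 1e12

#' @rdname invnm_to_si
#' @export
si_to_invps <- function(x) x / 1e12

# Evaluate `code` under a temporary R RNG state seeded with `seed`; the
# caller's RNG state is untouched.  With seed = NULL the code runs on the
# current stream.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else if (exists(".Random.seed", envir = genv, inherits = FALSE))
      rm(".Random.seed", envir = genv)
  })
  set.seed(seed)
  force(code)
}

stopifnot_scalar <- function(x, name, positive = TRUE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    abort(sprintf("`%s` must be a single finite number", name),
          class = "aquasoliton_error_input")
  if (positive && x <= 0)
    abort(sprintf("`%s` must be strictly positive", name),
          class = "aquasoliton_error_input")
  invisible(x)
}
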