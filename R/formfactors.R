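# Cromer-Mann four-Gaussian X-ray scattering factors (International Tables
# for Crystallography Vol. C, Table 6.1.1.4): f(s) = sum a_i exp(-b_i s^2) + c
# with s = sin(theta)/lambda in 1/Angstrom.  Atomic masses in amu alongside,
# used as default per-atom weights for map coupling and as dynamical masses.
.cm_table <- local({
  tab <- list(
    #        mass        a1..a4                                   b1..b4                                  c
    H  = list(1.008,  c(0.493002, 0.322912, 0.140191, 0.040810), c(10.5109, 26.1257, 3.14236, 57.7997),  0.003038),
    C  = list(12.011, c(2.310,    1.020,    1.5886,   0.865),    c(20.8439, 10.2075, 0.5687,  51.6512),  0.21560),
    N  = list(14.007, c(12.2126,  3.1322,   2.0125,   1.1663),   c(0.0057,  9.8933,  28.9975, 0.5826), -11.529),
    O  = list(15.999, c(3.0485,   2.2868,   1.5463,   0.867),    c(13.2771, 5.7011,  0.3239,  32.9089),  0.2508),
    S  = list(32.06,  c(6.9053,   5.2034,   1.4379,   1.5863),   c(1.4679,  22.2151, 0.2536,  56.172),   0.8669),
    P  = list(30.974, c(6.4345,   4.1791,   1.780,    1.4908),   c(1.9067,  27.157,  0.526,   68.1645),  1.1149),
    MG = list(24.305, c(5.4204,   2.1735,   1.2269,   2.3073),   c(2.8275,  79.2611, 0.3808,  7.1937),   0.8584),
    `NA` = list(22.990, c(4.7626,   3.1736,   1.2674,   1.1128),   c(3.285,   8.8422,  0.3136,  129.424),  0.676),
    K  = list(39.098, c(8.2186,   7.4398,   1.0519,   0.8659),   c(12.7949, 0.7748,  213.187, 41.6841),  1.4228),
    CL = list(35.45,  c(11.4604,  7.1964,   6.2556,   1.6455),   c(0.0104,  1.1662,  18.5194, 47.7784), -9.5574),
    CA = list(40.078, c(8.6266,   7.3873,   1.5899,   1.0211),   c(10.4421, 0.6599,  85.7484, 178.437),  1.3751),
    MN = list(54.938, c(11.2819,  7.3573,   3.0193,   2.2441),   c(5.3409,  0.3432,  17.8674, 83.7543),  1.0896),
    FE = list(55.845, c(11.7695,  7.3573,   3.5222,   2.3045),   c(4.7611,  0.3072,  15.3535, 76.8805),  1.0369),
    ZN = list(65.38,  c(14.0743,  7.0318,   5.1652,   2.410),    c(3.2655,  0.2333,  10.3163, 58.7097),  1.3041),
    CU = list(63.546, c(13.338,   7.1676,   5.6158,   1.6735),   c(3.5828,  0.247,   11.3966, 64.8126),  1.191),
    SE = list(78.971, c(17.0006,  5.8196,   3.9731,   4.3543),   c(2.4098,  0.2726,  15.2372, 43.8163),  2.8409)
  )
  tab
})

norm_element <- function(element) {
  el <- toupper(trimws(element))
  bad <- !(el %in% names(.cm_table))
  if (any(bad))
    stop("no scattering coefficients for element(s): ",
         paste(unique(el[bad]), collapse = ", "))
  el
}

#' Atomic X-ray form factor
#'
#' Cromer-Mann four-Gaussian approximation
#' `f(s) = sum_{i=1..4} a_i exp(-b_i s^2) + c`, with `s = sin(theta)/lambda`
#' in 1/Angstrom.  At `s = 0` the value approximates the electron count.
#'
#' @param element element symbol (case-insensitive); see
#'   [known_elements()] for the supported set.
#' @param s `sin(theta)/lambda` in 1/Angstrom, any non-negative vector.
#' @return scattering amplitude in electrons, same length as `s`.
#' @examples
#' form_factor("C", 0)      # ~6 electrons
#' form_factor("O", c(0, 0.2, 0.4))
#' @export
form_factor <- function(element, s) {
  if (any(s < 0)) stop("s = sin(theta)/lambda must be >= 0")
  el <- norm_element(element)
  if (length(el) != 1L) stop("one element at a time; vectorize over s")
  cf <- .cm_table[[el]]
  a <- cf[[2]]; b <- cf[[3]]; cc <- cf[[4]]
  s2 <- s^2
  out <- rep(cc, length(s))
  for (i in 1:4) out <- out + a[i] * exp(-b[i] * s2)
  out
}

#' @rdname form_factor
#' @export
known_elements <- function() names(.cm_table)

#' Atomic mass lookup
#' @param element vector of element symbols.
#' @return atomic masses in amu.
#' @export
atomic_mass <- function(element) {
  el <- norm_element(element)
  vapply(el, function(e) .cm_table[[e]][[1]], numeric(1), USE.NAMES = FALSE)
}
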