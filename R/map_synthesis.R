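#' Estimate sigma-A weighting parameters per resolution shell
#'
#' Reflections are binned into resolution shells of roughly equal working
#' counts.  Within each shell amplitudes are normalized
#' (`E = F / sqrt(<F^2>)`) and a moment estimator based on the correlation
#' of `|E_o|` with `|E_c|` supplies `sigmaA`, clamped to `[0, 0.999]`; the
#' model-quality scale is `D = sigmaA * sqrt(<|F_obs|^2> / <|F_calc|^2>)`
#' (which also absorbs the overall observed-to-calculated scale).  The
#' figure of merit per reflection is `m = I1(X)/I0(X)` for acentric and
#' `tanh(X/2)` for centric reflections, with
#' `X = 2 sigmaA |E_o||E_c| / (1 - sigmaA^2)`.  Free reflections never enter
#' the shell estimates.
#'
#' @param refl a [reflection_set()].
#' @param fc paired `structure_factor_set`.
#' @param n_shells requested number of shells; shells thinner than 30
#'   working reflections are merged with a warning.
#' @return a `sigmaa_model`: data frame `shells` (s2 range, sigmaA, D) plus
#'   per-reflection vectors `shell`, `m`, `D`, `e_obs`, `e_calc`.
#' @export
estimate_sigmaA <- function(refl, fc, n_shells = 10L) {
  work <- !refl$free & !is.na(refl$fobs)
  if (sum(work) < 50) stop("need >= 50 working reflections for sigma-A estimation")
  n_shells <- max(1L, min(as.integer(n_shells), sum(work) %/% 30L))
  if (n_shells < 1L) {
    warning("too few reflections for shelling; using a single shell")
    n_shells <- 1L
  }
  st2 <- stol(refl$hkl, refl$cell)^2
  br <- stats::quantile(st2[work], probs = seq(0, 1, length.out = n_shells + 1))
  br[1] <- -Inf; br[length(br)] <- Inf
  shell <- cut(st2, breaks = unique(br), labels = FALSE, include.lowest = TRUE)
  ns <- max(shell)

  fo <- refl$fobs; fa <- Mod(fc$f)
  sigA <- numeric(ns); Dsh <- numeric(ns)
  e_obs <- numeric(length(fo)); e_calc <- numeric(length(fo))
  for (s in seq_len(ns)) {
    i <- shell == s
    iw <- i & work
    mo2 <- mean(fo[iw]^2); mc2 <- mean(fa[iw]^2)
    e_obs[i] <- fo[i] / sqrt(mo2)
    e_calc[i] <- fa[i] / sqrt(mc2)
    # moment estimator: for correlated complex-Gaussian structure factors
    # corr(|E_o|^2, |E_c|^2) = sigmaA^2
    r <- suppressWarnings(stats::cor(e_obs[iw]^2, e_calc[iw]^2))
    if (is.na(r)) r <- if (max(abs(e_obs[iw] - e_calc[iw])) < 1e-8) 1 else 0
    sigA[s] <- min(sqrt(max(r, 0)), 0.999)
    Dsh[s] <- sigA[s] * sqrt(mo2 / mc2)
  }
  sa <- sigA[shell]
  X <- 2 * sa * abs(e_obs * e_calc) / (1 - sa^2)
  cen <- centric_flags(refl$hkl, NULL)
  m <- ifelse(cen, tanh(X / 2),
              besselI(X, 1, expon.scaled = TRUE) /
                besselI(X, 0, expon.scaled = TRUE))
  m[is.na(refl$fobs)] <- 0
  structure(list(
    shells = data.frame(shell = seq_len(ns), sigmaA = sigA, D = Dsh),
    shell = shell, m = m, D = Dsh[shell],
    e_obs = e_obs, e_calc = e_calc), class = "sigmaa_model")
}

# centric when a symmetry operator maps h to -h; in P1 (no operators given)
# every reflection is acentric
centric_flags <- function(hkl, symmetry = NULL) {
  if (is.null(symmetry) || length(symmetry) <= 1L)
    return(rep(FALSE, nrow(hkl)))
  cen <- rep(FALSE, nrow(hkl))
  for (op in symmetry) {
    Rt <- t(op$R)
    cen <- cen | apply(hkl, 1, function(h) all(abs(h %*% Rt + h) < 1e-8))
  }
  cen
}

#' Sigma-A weighted 2mFo-DFc map coefficients
#'
#' Per working reflection the coefficient is
#' `(2 m |F_obs| - D |F_calc|) exp(i phi_calc)`; free reflections are zeroed
#' when `exclude_free` (the default) so that the cross-validation set never
#' shapes the density the model is fitted into.  Unmeasured reflections fall
#' back to `D |F_calc| exp(i phi_calc)`.
#'
#' @param refl a [reflection_set()].
#' @param fc paired `structure_factor_set` (source of `phi_calc`).
#' @param sa an [estimate_sigmaA()] result.
#' @param exclude_free zero the free-set coefficients.
#' @return a `structure_factor_set` of map coefficients.
#' @export
map_coefficients <- function(refl, fc, sa, exclude_free = TRUE) {
  amp <- Mod(fc$f)
  ph <- fc$f / ifelse(amp > 0, amp, 1)        # unit phase factors
  fo <- refl$fobs
  coef_amp <- 2 * sa$m * fo - sa$D * amp
  fill <- is.na(fo)
  coef_amp[fill] <- (sa$D * amp)[fill]
  cf <- coef_amp * ph
  if (exclude_free) cf[refl$free] <- 0
  structure(list(hkl = fc$hkl, f = cf, d = fc$d, cell = fc$cell),
            class = "structure_factor_set")
}

#' Sharpen map coefficients
#'
#' Scales amplitudes by `exp(+B_sharp s^2)` (`s = sin theta / lambda`),
#' boosting high-resolution terms; phases are untouched.  Negative values
#' blur.
#'
#' @param coeffs a `structure_factor_set`.
#' @param b_sharp sharpening B in A^2.
#' @return the sharpened `structure_factor_set`.
#' @export
sharpen <- function(coeffs, b_sharp) {
  st2 <- stol(coeffs$hkl, coeffs$cell)^2
  coeffs$f <- coeffs$f * exp(b_sharp * st2)
  coeffs
}

#' Synthesize a real-space map from coefficients
#'
#' `Phi(x) = (1/V) sum_h coeff(h) exp(-2 pi i h.x)`, realized by placing
#' each coefficient and its Friedel mate on a reciprocal grid and applying
#' one FFT; the result is real up to rounding.
#'
#' @param coeffs a `structure_factor_set` (one Friedel hemisphere).
#' @param grid_spacing target spacing in Angstrom; must be at most
#'   `d_min / 2` for alias-free synthesis (default `d_min / 3`).
#' @return a [map_grid()] in electrons per cubic Angstrom (times the
#'   amplitude units of the coefficients).
#' @export
synthesize_map <- function(coeffs, grid_spacing = min(coeffs$d) / 3) {
  d_min <- min(coeffs$d)
  if (grid_spacing > d_min / 2 + 1e-9)
    stop("grid spacing must be <= d_min/2 (have ", signif(grid_spacing, 3),
         " A for d_min ", signif(d_min, 3), " A)")
  cell <- coeffs$cell
  dims <- vapply(cell[1:3] / grid_spacing, next_fast_size, integer(1))
  hmax <- apply(abs(coeffs$hkl), 2, max)
  if (any(dims < 2 * hmax + 1)) dims <- pmax(dims, 2L * as.integer(hmax) + 1L)
  G <- array(0 + 0i, dim = dims)
  put <- function(h, v) {
    idx <- (h %% matrix(dims, nrow(h), 3, byrow = TRUE)) + 1L
    lin <- idx[, 1] + (idx[, 2] - 1L) * dims[1] + (idx[, 3] - 1L) * dims[1] * dims[2]
    G[lin] <<- v
  }
  put(coeffs$hkl, coeffs$f)
  put(-coeffs$hkl, Conj(coeffs$f))
  vals <- Re(stats::fft(G)) / cell_volume(cell)
  map_grid(vals, cell)
}

#' Model-phased 2mFo-DFc map in one call
#'
#' Convenience wrapper chaining structure-factor calculation, sigma-A
#' estimation, coefficient construction, optional sharpening and map
#' synthesis.  This is the map the refinement loop regenerates at every
#' iteration.
#'
#' @param model phasing [atomic_model()].
#' @param refl observed [reflection_set()].
#' @param exclude_free omit free reflections from the synthesis (default).
#' @param b_sharp sharpening B factor (A^2), 0 to disable.
#' @param grid_spacing map spacing (default `d_min/3`).
#' @param n_shells sigma-A shells.
#' @return a [map_grid()].
#' @export
model_phased_map <- function(model, refl, exclude_free = TRUE, b_sharp = 0,
                             grid_spacing = min(refl$d) / 3, n_shells = 10L) {
  fc <- calc_structure_factors(model, refl)
  sa <- estimate_sigmaA(refl, fc, n_shells)
  cf <- map_coefficients(refl, fc, sa, exclude_free = exclude_free)
  if (b_sharp != 0) cf <- sharpen(cf, b_sharp)
  synthesize_map(cf, grid_spacing)
}

#' Kick-averaged model-phased map
#'
#' Suppresses model bias by perturbing all atoms with zero-mean Gaussian
#' noise of the stated r.m.s. magnitude, regenerating the full model-phased
#' map with each perturbed copy (new phases, same amplitudes) and averaging
#' the maps voxel-wise.
#'
#' @param model phasing [atomic_model()].
#' @param refl observed [reflection_set()].
#' @param kick_rms r.m.s. displacement per atom in Angstrom (> 0).
#' @param n_kicks number of perturbed copies (>= 2).
#' @param seed integer seed.
#' @param ... forwarded to [model_phased_map()].
#' @return a [map_grid()] (the voxel-wise mean map).
#' @export
kicked_map <- function(model, refl, kick_rms = 0.3, n_kicks = 5L, seed = 1L, ...) {
  if (kick_rms <= 0) stop("kick_rms must be > 0")
  if (n_kicks < 2) stop("need at least 2 kicks")
  xyz <- model_xyz(model)
  kicks <- with_seed(seed, lapply(seq_len(n_kicks), function(i)
    matrix(stats::rnorm(length(xyz), sd = kick_rms / sqrt(3)), ncol = 3)))
  acc <- NULL
  for (k in kicks) {
    m <- model_phased_map(set_model_xyz(model, xyz + k), refl, ...)
    acc <- if (is.null(acc)) m$values else acc + m$values
  }
  map_grid(acc / n_kicks, model$cell)
}

#' Convert density to the steering grid potential
#'
#' `V(r) = xi * (1 - (Phi'(r) - Phi_thr) / (Phi_max - Phi_thr))` with
#' `Phi' = max(Phi, Phi_thr)`: zero at the density maximum, rising to the
#' flat plateau `xi` wherever density falls to or below the threshold, so
#' atoms feel no force in solvent/noise regions and are pulled toward high
#' density elsewhere.  The default threshold of 0 treats negative and zero
#' density in the (signed) 2mFo-DFc map as featureless.
#'
#' @param map a [map_grid()] of density.
#' @param xi global scale in kcal/mol per unit coupling weight.
#' @param phi_thr threshold in map units, or a quantile when
#'   `thr_quantile = TRUE`.
#' @param thr_quantile interpret `phi_thr` as a voxel-value quantile.
#' @return a `grid_potential`: a [map_grid()] of energies with fields
#'   `xi`, `phi_thr`, `phi_max`.
#' @export
density_to_potential <- function(map, xi = 0.3, phi_thr = 0,
                                 thr_quantile = FALSE) {
  if (xi < 0) stop("xi must be >= 0")
  thr <- if (thr_quantile) stats::quantile(map$values, phi_thr) else phi_thr
  phi_max <- max(map$values)
  if (phi_max <= thr) stop("map maximum must exceed the threshold")
  phi <- pmax(map$values, thr)
  v <- xi * (1 - (phi - thr) / (phi_max - thr))
  out <- map_grid(array(v, dim = dim(map$values)), map$cell, map$origin)
  out$xi <- xi; out$phi_thr <- thr; out$phi_max <- phi_max
  class(out) <- c("grid_potential", class(out))
  out
}
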