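#' Ion species in an electrolyte
#'
#' An ionic species that shifts the antiambipolar peak position `V_P`
#' log-linearly (Nernst-like) with its concentration: the contribution is
#' `-(slope / z) * log10(conc / c_ref)` volts. Divalent ions produce half
#' the shift of a monovalent ion with the same slope.
#'
#' @param name Species name (e.g. `"Na"`, `"Ca"`).
#' @param z Valence, 1 or 2.
#' @param conc_mM Concentration in mM (`> 0` when used in [effective_vp()]).
#' @param slope_V_per_decade Peak shift per decade of concentration (V);
#'   the default 0.059 V/decade is the Nernstian slope at room temperature.
#' @param c_ref_mM Reference concentration (mM) at which the shift is zero.
#' @return An object of class `"ion_species"`.
#' @export
ion_species <- function(name, z = 1L, conc_mM = 100,
                        slope_V_per_decade = 0.059, c_ref_mM = 100) {
  stopifnot(z %in% c(1L, 2L), conc_mM >= 0, c_ref_mM > 0)
  structure(list(name = name, z = as.integer(z), conc_mM = conc_mM,
                 slope_V_per_decade = slope_V_per_decade,
                 c_ref_mM = c_ref_mM),
            class = "ion_species")
}

#' Neurotransmitter / amino-acid modulator
#'
#' A dissolved modulator molecule with linear-in-concentration effects on the
#' device parameters: `dVP_coeff` shifts the Na-OECT peak voltage (V/mM,
#' negative for GABA and glutamine), `peak_atten` reduces the peak current
#' fractionally per mM (saturating at full suppression) and `dVK_coeff`
#' shifts the K-OECT threshold (V/mM, used for Ca2+ routed to the potassium
#' device). Acetylcholine defaults to all-zero coefficients: it does not
#' shift `V_P`.
#'
#' @param name One of `"GABA"`, `"glutamine"`, `"dopamine"`,
#'   `"acetylcholine"` or a custom name.
#' @param conc_mM Concentration in mM.
#' @param dVP_coeff Peak-voltage shift coefficient (V/mM).
#' @param peak_atten Fractional peak-current attenuation per mM (1/mM).
#' @param dVK_coeff K-threshold shift coefficient (V/mM).
#' @return An object of class `"modulator"`.
#' @export
modulator <- function(name, conc_mM = 0, dVP_coeff = 0, peak_atten = 0,
                      dVK_coeff = 0) {
  stopifnot(conc_mM >= 0, peak_atten >= 0)
  structure(list(name = name, conc_mM = conc_mM, dVP_coeff = dVP_coeff,
                 peak_atten = peak_atten, dVK_coeff = dVK_coeff),
            class = "modulator")
}

#' Electrolyte composition for one device
#'
#' Bundles ion species and modulator molecules with a routing tag naming the
#' device whose electrolyte this is (`"Na_OECT"` or `"K_OECT"`).
#' Concentrations are piecewise-constant per simulation segment; there is no
#' diffusion or depletion model.
#'
#' @param ions List of [ion_species()] objects.
#' @param modulators List of [modulator()] objects.
#' @param target `"Na_OECT"` or `"K_OECT"`.
#' @return An object of class `"electrolyte"`.
#' @export
electrolyte <- function(ions = list(), modulators = list(),
                        target = c("Na_OECT", "K_OECT")) {
  target <- match.arg(target)
  stopifnot(all(vapply(ions, inherits, TRUE, "ion_species")),
            all(vapply(modulators, inherits, TRUE, "modulator")))
  nm <- c(vapply(ions, `[[`, "", "name"), vapply(modulators, `[[`, "", "name"))
  if (anyDuplicated(nm))
    stop("duplicate species name in electrolyte: ",
         nm[duplicated(nm)][1])
  structure(list(ions = ions, modulators = modulators, target = target),
            class = "electrolyte")
}

#' @export
print.electrolyte <- function(x, ...) {
  cat("Electrolyte (target:", x$target, ")\n")
  for (i in x$ions)
    cat(sprintf("  ion %s (z=%d): %.4g mM (ref %.4g mM, slope %.3g V/dec)\n",
                i$name, i$z, i$conc_mM, i$c_ref_mM, i$slope_V_per_decade))
  for (m in x$modulators)
    cat(sprintf("  modulator %s: %.4g mM (dVP %.3g V/mM, atten %.3g /mM, dVK %.3g V/mM)\n",
                m$name, m$conc_mM, m$dVP_coeff, m$peak_atten, m$dVK_coeff))
  invisible(x)
}

#' Effective antiambipolar peak voltage under an electrolyte
#'
#' Composes the base peak voltage with the Nernst-like ionic shifts and the
#' linear modulator shifts:
#' \deqn{V_P = V_{P0} - \sum_i \frac{s_i}{z_i}\log_{10}(c_i/c_{ref,i})
#'            + \sum_j \beta_j c_j}
#'
#' @param base An [antiambipolar_params()] object.
#' @param e An [electrolyte()] with `target = "Na_OECT"`.
#' @return Effective peak voltage (V).
#' @export
effective_vp <- function(base, e) {
  stopifnot(inherits(base, "aap_params"), inherits(e, "electrolyte"))
  if (e$target != "Na_OECT")
    stop("effective_vp applies to the Na-OECT electrolyte")
  ion_shift <- 0
  for (i in e$ions) {
    if (i$conc_mM <= 0)
      stop("ion concentration must be > 0 for species ", i$name,
           " (log shift undefined)")
    ion_shift <- ion_shift +
      (i$slope_V_per_decade / i$z) * log10(i$conc_mM / i$c_ref_mM)
  }
  mod_shift <- sum(vapply(e$modulators,
                          function(m) m$dVP_coeff * m$conc_mM, 0))
  base$V_P0 - ion_shift + mod_shift
}

#' Effective antiambipolar peak current under an electrolyte
#'
#' Multiplicative saturating attenuation by modulators:
#' `I_peak0 * prod(max(0, 1 - atten_j * conc_j))`, bounded in
#' `[0, I_peak0]`.
#'
#' @inheritParams effective_vp
#' @return Effective peak current (A).
#' @export
effective_peak_current <- function(base, e) {
  stopifnot(inherits(base, "aap_params"), inherits(e, "electrolyte"))
  if (e$target != "Na_OECT")
    stop("effective_peak_current applies to the Na-OECT electrolyte")
  fac <- prod(vapply(e$modulators,
                     function(m) max(0, 1 - m$peak_atten * m$conc_mM), 0.0))
  base$I_peak0 * fac
}

#' Effective K-OECT threshold voltage under an electrolyte
#'
#' Linear threshold shift by modulator species routed to the potassium
#' device: `V_K + sum(dVK_coeff_j * conc_j)`. Calcium carries a negative
#' coefficient, so increasing Ca2+ lowers the threshold and makes the
#' potassium branch turn on earlier.
#'
#' @param base An [oect_params()] object.
#' @param e An [electrolyte()] with `target = "K_OECT"`.
#' @return Effective threshold voltage (V).
#' @export
effective_vk <- function(base, e) {
  stopifnot(inherits(base, "oect_params"), inherits(e, "electrolyte"))
  if (e$target != "K_OECT")
    stop("effective_vk applies to the K-OECT electrolyte")
  base$V_T + sum(vapply(e$modulators,
                        function(m) m$dVK_coeff * m$conc_mM, 0))
}

#' Apply an electrolyte to Na-OECT parameters
#'
#' Returns a copy of `base` with `V_P0` and `I_peak0` replaced by their
#' electrolyte-modulated effective values (and `k_peak` rescaled in
#' proportion to the peak-current attenuation, so the relative drain-bias
#' dependence is preserved).
#'
#' @inheritParams effective_vp
#' @return A modulated [antiambipolar_params()] object.
#' @export
modulated_na_params <- function(base, e = NULL) {
  if (is.null(e)) return(base)
  ipk <- effective_peak_current(base, e)
  scale <- if (base$I_peak0 > 0) ipk / base$I_peak0 else 0
  base$V_P0 <- effective_vp(base, e)
  base$I_peak0 <- ipk
  base$k_peak <- base$k_peak * scale
  if (base$I_peak0 <= 0) base$I_peak0 <- .Machine$double.xmin
  base
}

#' Apply an electrolyte to K-OECT parameters
#'
#' Returns a copy of `base` with the threshold replaced by [effective_vk()].
#'
#' @inheritParams effective_vk
#' @return A modulated [oect_params()] object.
#' @export
modulated_k_params <- function(base, e = NULL) {
  if (is.null(e)) return(base)
  base$V_T <- effective_vk(base, e)
  base
}
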