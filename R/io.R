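## YAML/JSON experiment configs with unit-suffixed keys, plus run manifests.

`%||%` <- function(a, b) if (is.null(a)) b else a

parse_electrolyte <- function(x, target) {
  if (is.null(x)) return(NULL)
  ions <- lapply(x$ions %||% list(), function(i)
    ion_species(i$name, as.integer(i$z %||% 1L), i$conc_mM %||% 100,
                i$slope_V_per_decade %||% 0.059, i$c_ref_mM %||% 100))
  mods <- lapply(x$modulators %||% list(), function(m)
    modulator(m$name, m$conc_mM %||% 0, m$dVP_coeff_V_per_mM %||% 0,
              m$peak_atten_per_mM %||% 0, m$dVK_coeff_V_per_mM %||% 0))
  electrolyte(ions = ions, modulators = mods, target = target)
}

#' Read an experiment configuration file
#'
#' Reads a YAML (or JSON) experiment configuration with unit-suffixed keys
#' and returns the circuit parameters, stimulus program and simulation
#' settings. A top-level `preset:` key (`config_A`, `config_B`, `config_C`)
#' loads the corresponding reference configuration; any further keys
#' override individual fields. Unknown keys are an error, listing the
#' offending names.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return List with `params` ([circuit_params()]), `stim`
#'   ([stimulus_program()] or `NULL`) and `sim` (list of `t_span`,
#'   `dt_out`, `method`).
#' @export
read_experiment_config <- function(path) {
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::fromJSON(path, simplifyVector = FALSE)
  } else {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("reading YAML configs requires the 'yaml' package")
    yaml::read_yaml(path)
  }
  known_top <- c("preset", "circuit", "amplifier", "na_oect", "k_oect",
                 "electrolytes", "stimulus", "simulation")
  bad <- setdiff(names(cfg), known_top)
  if (length(bad))
    stop("unknown config keys: ", paste(bad, collapse = ", "))

  p <- if (!is.null(cfg$preset)) {
    switch(cfg$preset, config_A = config_A(), config_B = config_B(),
           config_C = config_C(),
           stop("unknown preset: ", cfg$preset))
  } else NULL

  cc <- cfg$circuit %||% list()
  known_cc <- c("E_Na_V", "E_K_V", "C_mem_F", "C_int_F", "R_dk_Ohm",
                "C_gK_F", "G_L_S", "E_L_V", "C_g_Na_F")
  bad <- setdiff(names(cc), known_cc)
  if (length(bad))
    stop("unknown circuit keys: ", paste(bad, collapse = ", "))
  amp <- cfg$amplifier
  na <- cfg$na_oect
  ko <- cfg$k_oect
  if (is.null(p)) {
    p <- circuit_params(
      E_Na = cc$E_Na_V %||% 0.5, E_K = cc$E_K_V %||% -0.05,
      C_mem = cc$C_mem_F %||% 1e-6, C_int = cc$C_int_F %||% 1e-8,
      R_dk = cc$R_dk_Ohm %||% 4.7e5, C_gK = cc$C_gK_F %||% 6e-8,
      G_L = cc$G_L_S %||% 2e-5, E_L = cc$E_L_V %||% 0.16,
      C_g_Na = cc$C_g_Na_F %||% 1e-7,
      amplifier = if (is.null(amp)) amplifier_params() else
        amplifier_params(amp$gain, amp$offset_V, amp$rail_low_V,
                         amp$rail_high_V),
      na_params = if (is.null(na)) antiambipolar_params() else
        antiambipolar_params(
          I_peak0 = na$I_peak0_A, V_P0 = na$V_P0_V,
          sigma_rise = na$sigma_rise_V, sigma_fall = na$sigma_fall_V,
          V_DS_ref = na$V_DS_ref_V %||% 0.3,
          k_peak = na$k_peak_A_per_V %||% 0, k_VP = na$k_VP %||% 0,
          k_sigma = na$k_sigma_per_V %||% 0,
          form = na$form %||% "gaussian"),
      k_params = if (is.null(ko)) oect_params() else
        oect_params(V_T = ko$V_T_V, K_g = ko$K_g_A_per_V2,
                    C_g = ko$C_g_F %||% 1e-7,
                    R_g_intrinsic = ko$R_g_Ohm %||% 2.5e3))
  } else {
    for (k in names(cc)) {
      field <- c(E_Na_V = "E_Na", E_K_V = "E_K", C_mem_F = "C_mem",
                 C_int_F = "C_int", R_dk_Ohm = "R_dk", C_gK_F = "C_gK",
                 G_L_S = "G_L", E_L_V = "E_L", C_g_Na_F = "C_g_Na")[[k]]
      p[[field]] <- cc[[k]]
    }
  }
  if (!is.null(cfg$electrolytes)) {
    p$na_electrolyte <- parse_electrolyte(cfg$electrolytes$na, "Na_OECT")
    p$k_electrolyte <- parse_electrolyte(cfg$electrolytes$k, "K_OECT")
  }

  stim <- NULL
  if (!is.null(cfg$stimulus)) {
    ss <- cfg$stimulus
    segs <- lapply(ss$segments %||% list(), function(s) {
      if ((s$kind %||% "constant") == "ramp")
        list(t_start = s$t_start_s, duration = s$duration_s, kind = "ramp",
             start = s$start_A, end = s$end_A)
      else
        list(t_start = s$t_start_s, duration = s$duration_s,
             kind = "constant", amplitude = s$amplitude_A)
    })
    noise <- if (!is.null(ss$noise))
      list(model = ss$noise$model %||% "OU", sigma = ss$noise$sigma_A,
           tau = ss$noise$tau_s %||% 0.01,
           seed = as.integer(ss$noise$seed %||% 1L))
    else NULL
    t_max <- (cfg$simulation$t_span_s %||% 5)
    stim <- stimulus_program(segments = segs,
                             baseline = ss$baseline_A %||% 0,
                             noise = noise, t_max = t_max)
  }
  sim <- list(t_span = cfg$simulation$t_span_s %||% 5,
              dt_out = cfg$simulation$dt_out_s %||% 1e-4,
              method = cfg$simulation$method %||% "lsoda")
  list(params = p, stim = stim, sim = sim)
}

#' Write a run manifest
#'
#' Writes a JSON manifest (config digest, solver settings, seed, package
#' version, timestamp) next to a run's outputs so the run can be reproduced
#' exactly.
#'
#' @param path Output file path (JSON).
#' @param p The [circuit_params()] used.
#' @param sim List of solver settings.
#' @param seed Integer seed (or `NA`).
#' @param extra Optional named list merged into the manifest.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(path, p, sim = list(), seed = NA_integer_,
                           extra = list()) {
  m <- c(list(config_digest = config_digest(p),
              package_version = as.character(utils::packageVersion("coecn")),
              r_version = R.version.string,
              seed = seed, solver = sim,
              timestamp = format(Sys.time(), tz = "UTC")),
         extra)
  jsonlite::write_json(m, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}
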