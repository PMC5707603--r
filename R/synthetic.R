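#' Spectrum template: a sum of Lorentzian bands
#'
#' Describes a synthetic Raman spectrum as a list of Lorentzian peaks
#' (center, half-width at half-maximum, amplitude) sampled on a shift grid
#' with additive Gaussian noise. Lorentzian line shapes are the standard
#' model for Raman bands.
#'
#' @param peaks data.frame with columns `center` (cm^-1, in `[0, 1800)`),
#'   `width` (HWHM, cm^-1, > 0) and `amplitude` (a.u., >= 0).
#' @param noise_sd standard deviation of the additive noise (a.u.).
#' @param grid numeric vector of Raman shifts to sample (default every 5 cm^-1
#'   over 0-1795).
#' @return Object of class `spectrum_template`.
#' @export
spectrum_template <- function(peaks, noise_sd = 0,
                              grid = seq(0, 1795, by = 5)) {
  stopifnot(is.data.frame(peaks),
            all(c("center", "width", "amplitude") %in% names(peaks)))
  if (nrow(peaks) > 0L) {
    stopifnot(all(peaks$center >= 0), all(peaks$center < 1800),
              all(peaks$width > 0), all(peaks$amplitude >= 0))
  }
  stopifnot(noise_sd >= 0, length(grid) >= 1L, !is.unsorted(grid, strictly = TRUE))
  structure(list(peaks = peaks, noise_sd = noise_sd, grid = grid),
            class = "spectrum_template")
}

#' CNT-like spectrum templates by type and functionalization
#'
#' Builds a template with the characteristic carbon-nanotube bands: the G
#' band near 1580 cm^-1 (graphitic mode), the D band near 1350 cm^-1 (defects
#' — functionalized CNTs get a larger D amplitude), and, for single- and
#' double-walled types, a radial-breathing mode below 300 cm^-1. Peak
#' positions and amplitudes are jittered so distinct CNTs of the same class
#' still differ.
#'
#' @param cnt_type one of `"MWCNT"`, `"SW+DWCNT"`, `"SWCNT"`.
#' @param func_type one of `"0"` (pristine), `"COOH"`, `"OH"`.
#' @param noise_sd additive noise level (default 2 a.u.).
#' @param jitter_sd sd of the random jitter on centers (cm^-1) and relative
#'   jitter on amplitudes (default 5).
#' @return A [spectrum_template()].
#' @export
cnt_template <- function(cnt_type = c("MWCNT", "SW+DWCNT", "SWCNT"),
                         func_type = c("0", "COOH", "OH"),
                         noise_sd = 2, jitter_sd = 5) {
  cnt_type <- match.arg(cnt_type)
  func_type <- match.arg(func_type)
  d_amp <- if (func_type == "0") 30 else if (func_type == "COOH") 75 else 60
  peaks <- data.frame(
    center = c(1350, 1580),
    width = c(40, 30),
    amplitude = c(d_amp, 100)
  )
  if (cnt_type %in% c("SWCNT", "SW+DWCNT")) {
    peaks <- rbind(peaks, data.frame(center = 180, width = 15, amplitude = 25))
  }
  if (cnt_type != "SWCNT") {  # G' overtone region, stronger for multi-walled
    peaks <- rbind(peaks, data.frame(center = 1620, width = 25, amplitude = 20))
  }
  peaks$center <- pmin(pmax(peaks$center + stats::rnorm(nrow(peaks), 0, jitter_sd), 0), 1799)
  peaks$amplitude <- peaks$amplitude * exp(stats::rnorm(nrow(peaks), 0, jitter_sd / 50))
  spectrum_template(peaks, noise_sd = noise_sd)
}

#' Simulate a Raman spectrum from a template
#'
#' Intensity at each grid point is the sum of the template's Lorentzians plus
#' Gaussian noise, clipped at zero. Deterministic under a fixed seed.
#'
#' @param template a [spectrum_template()].
#' @param seed optional integer seed.
#' @param label spectrum label.
#' @return A [raman_spectrum()].
#' @export
simulate_spectrum <- function(template, seed = NULL, label = "synthetic") {
  stopifnot(inherits(template, "spectrum_template"))
  if (nrow(template$peaks) == 0L && template$noise_sd == 0) {
    stop("degenerate template: no peaks and no noise")
  }
  if (!is.null(seed)) set.seed(seed)
  x <- template$grid
  y <- rep(0, length(x))
  for (p in seq_len(nrow(template$peaks))) {
    c0 <- template$peaks$center[p]
    w <- template$peaks$width[p]
    a <- template$peaks$amplitude[p]
    y <- y + a * w^2 / ((x - c0)^2 + w^2)
  }
  if (template$noise_sd > 0) y <- y + stats::rnorm(length(x), 0, template$noise_sd)
  raman_spectrum(x, pmax(y, 0), label = label)
}

#' Respirometry flux-profile parameters
#'
#' Parameters of a synthetic high-resolution-respirometry oxygen-flux trace:
#' a basal (state V2) flux, transient ADP pulses (state V3) as exponentially
#' decaying steps, and an uncoupler window (state V4) during which the flux
#' is raised by a multiplicative gain, echoing the uncoupled respiration
#' observed between 750 and 1250 s in the assays the generator emulates.
#'
#' @param basal basal flux, pmol/s (> 0).
#' @param adp_pulses data.frame with columns `time` (s, increasing),
#'   `amplitude` (pmol/s) and `tau` (decay constant, s).
#' @param uncoupler_window length-2 numeric, seconds (default `c(750, 1250)`).
#' @param uncoupler_gain extra flux inside the window as a multiple of basal
#'   (default 0.6).
#' @param noise_sd additive noise sd, pmol/s.
#' @return Object of class `flux_profile_params`.
#' @export
flux_profile_params <- function(basal = 40,
                                adp_pulses = data.frame(time = c(200, 400, 600),
                                                        amplitude = 25, tau = 60),
                                uncoupler_window = c(750, 1250),
                                uncoupler_gain = 0.6, noise_sd = 0) {
  if (!(basal > 0)) stop("basal flux must be positive")
  stopifnot(is.data.frame(adp_pulses),
            all(c("time", "amplitude", "tau") %in% names(adp_pulses)))
  if (nrow(adp_pulses) > 1L && is.unsorted(adp_pulses$time, strictly = TRUE)) {
    stop("pulse times must be increasing")
  }
  stopifnot(length(uncoupler_window) == 2L, uncoupler_window[2L] >= uncoupler_window[1L],
            noise_sd >= 0)
  structure(list(basal = basal, adp_pulses = adp_pulses,
                 uncoupler_window = uncoupler_window,
                 uncoupler_gain = uncoupler_gain, noise_sd = noise_sd),
            class = "flux_profile_params")
}

#' Simulate an oxygen-flux time series
#'
#' Flux at time t is basal + the sum of pulse transients
#' (`amplitude * exp(-(t - t0)/tau)` for `t >= t0`) + `uncoupler_gain * basal`
#' inside the uncoupler window, plus optional Gaussian noise. The companion
#' oxygen-concentration series is the negative cumulative integral of the
#' flux (flux is measured as the negative time derivative of the oxygen
#' concentration).
#'
#' @param params a [flux_profile_params()].
#' @param times numeric vector of increasing times (s).
#' @param seed optional integer seed.
#' @param o2_init initial oxygen concentration (arbitrary units, default 0:
#'   the concentration series is then minus the cumulative oxygen consumed).
#' @return List with `times`, `flux` (pmol/s) and `oxygen`.
#' @export
simulate_flux_profile <- function(params, times, seed = NULL, o2_init = 0) {
  stopifnot(inherits(params, "flux_profile_params"))
  if (is.unsorted(times, strictly = TRUE)) stop("times must be strictly increasing")
  if (!is.null(seed)) set.seed(seed)
  flux <- rep(params$basal, length(times))
  for (p in seq_len(nrow(params$adp_pulses))) {
    t0 <- params$adp_pulses$time[p]
    amp <- params$adp_pulses$amplitude[p]
    tau <- params$adp_pulses$tau[p]
    on <- times >= t0
    flux[on] <- flux[on] + amp * exp(-(times[on] - t0) / tau)
  }
  w <- params$uncoupler_window
  inside <- times >= w[1L] & times <= w[2L]
  flux[inside] <- flux[inside] + params$uncoupler_gain * params$basal
  if (params$noise_sd > 0) flux <- flux + stats::rnorm(length(times), 0, params$noise_sd)
  dt <- diff(times)
  consumed <- cumsum(c(0, (flux[-1L] + flux[-length(flux)]) / 2 * dt))
  list(times = times, flux = flux, oxygen = o2_init - consumed)
}

#' Default generative PTML coefficients of the synthetic study
#'
#' Six MA terms (one or two per experimental condition, over a spread of
#' moment orders), a unit-scale dependence on the expected flux and a slow
#' linear drift in time. Coefficient magnitudes are matched to the typical
#' scale of each MA column so every term contributes order-1 pmol/s.
#'
#' @return A [ptml_coefficients()] object.
#' @export
default_study_coefficients <- function() {
  ptml_coefficients(
    a0 = 10, a1 = 0.8, a2 = 0.002,
    beta = c(dTr0_rep = 0.3, dTre3_rep = 0.005, dTre2_CNTtype = 0.01,
             dTre4_FuncType = 5e-4, dTre0_Solvent = 0.3, dTre5_Solvent = 1e-5)
  )
}

.study_conditions <- function(n_cnts) {
  types <- c("MWCNT", "SW+DWCNT", "SWCNT")
  funcs <- c("0", "COOH", "OH")
  combos <- expand.grid(func_type = funcs, cnt_type = types,
                        stringsAsFactors = FALSE)[seq_len(n_cnts) %% 9 + 1, ]
  data.frame(
    cnt_id = paste0("CNT", seq_len(n_cnts)),
    cnt_type = combos$cnt_type,
    func_type = combos$func_type,
    solvent = rep_len(c("H2O", "DMSO"), n_cnts),
    stringsAsFactors = FALSE
  )
}

#' Simulate a complete star-graph/PTML study
#'
#' Generates a desk-scale analogue of a full CNT respirometry study with a
#' known generative truth: per-CNT Raman spectra (templates drawn by CNT type
#' and functionalization, functionalized CNTs getting a larger D band), their
#' true trace invariants, a case table over CNT x replicate x time, and
#' measured fluxes.
#'
#' Two flux models are available. `"ptml"` draws, for every experimental
#' group, a basal respirometry profile and defines the group's true expected
#' flux as its time average; the case flux is then the linear PTML
#' combination of that truth, time and the MA operators, plus iid Gaussian
#' noise whose sd is `noise_frac` times the sd of the noise-free signal.
#' `"respirometry"` instead uses the time-resolved profile itself (ADP pulses
#' and an uncoupler step — strongly nonlinear in time) plus a small linear MA
#' contribution; this is the nonlinear link used to contrast flexible and
#' linear regressors.
#'
#' @param n_cnts number of CNTs (>= 2, default 9).
#' @param n_times time points per series (default 1830, seconds 0..1829; the
#'   full-scale default gives `n_cnts * 2 * n_times` cases).
#' @param coefficients generative [ptml_coefficients()] (default
#'   [default_study_coefficients()]).
#' @param flux_model `"ptml"` (default) or `"respirometry"`.
#' @param noise_frac noise sd as a fraction of the signal sd (default 0.1);
#'   set 0 for noiseless data.
#' @param include_controls add a control series (cnt_id `"0"`, blank solution,
#'   zero invariants) per solvent (default `FALSE`).
#' @param seed integer seed.
#' @param encode_params list of [encode_sequence()] parameters used to
#'   transform the spectra (default: intensity threshold 1 a.u., so sequence
#'   lengths vary with the band structure).
#' @return List with `spectra` (named list of [raman_spectrum()]), `cases`
#'   (case table), `invariants` ([invariant_table()] data.frame) and `truth`
#'   (list: `coefficients`, `design` — the generative design matrix,
#'   `jm_expected`, `signal`, `noise_sd`).
#' @export
simulate_study <- function(n_cnts = 9L, n_times = 1830L,
                           coefficients = default_study_coefficients(),
                           flux_model = c("ptml", "respirometry"),
                           noise_frac = 0.1, include_controls = FALSE,
                           seed = 1L, encode_params = list(threshold = 1)) {
  if (n_cnts < 2L) stop("need at least two CNTs")
  flux_model <- match.arg(flux_model)
  stopifnot(inherits(coefficients, "ptml_coefficients"))
  set.seed(seed)
  cnts <- .study_conditions(n_cnts)

  spectra <- list()
  invs <- list()
  for (i in seq_len(n_cnts)) {
    tpl <- cnt_template(cnts$cnt_type[i], cnts$func_type[i])
    sp <- simulate_spectrum(tpl, label = cnts$cnt_id[i])
    spectra[[cnts$cnt_id[i]]] <- sp
    invs[[cnts$cnt_id[i]]] <- do.call(transform_spectrum, c(list(sp), encode_params))
  }
  inv_tab <- invariant_table(invs)

  times <- seq(0, 1829, length.out = n_times)
  series <- merge(cnts, data.frame(rep = c("0", "1")), by = NULL)
  if (include_controls) {
    ctrl <- data.frame(cnt_id = "0", cnt_type = "0", func_type = "0",
                       solvent = c("H2O", "DMSO"), rep = "0",
                       stringsAsFactors = FALSE)
    series <- rbind(series, ctrl[names(series)])
  }
  cases <- series[rep(seq_len(nrow(series)), each = n_times), ]
  cases$time <- rep(times, nrow(series))
  rownames(cases) <- NULL

  # one respirometry profile per experimental group, with a random basal level
  gkey <- interaction(series[c("rep", "cnt_type", "func_type", "solvent")],
                      drop = TRUE, sep = "|")
  basal <- stats::setNames(stats::runif(nlevels(gkey), 30, 60), levels(gkey))
  profiles <- lapply(levels(gkey), function(g) {
    simulate_flux_profile(flux_profile_params(basal = basal[[g]]), times)$flux
  })
  names(profiles) <- levels(gkey)
  case_key <- as.character(interaction(cases[c("rep", "cnt_type", "func_type", "solvent")],
                                       drop = TRUE, sep = "|"))
  jm_true <- vapply(profiles, mean, numeric(1))[case_key]

  X <- do.call(cbind, lapply(names(.condition_fields), function(cond) {
    ma_operators(inv_tab, cases, cond)
  }))
  design <- cbind(data.frame(Jm_expected = as.numeric(jm_true), t = cases$time), X)

  beta_cols <- names(coefficients$beta)
  missing <- setdiff(beta_cols, names(design))
  if (length(missing) > 0L) stop("coefficients name unknown column(s): ",
                                 paste(missing, collapse = ", "))
  linear_part <- predict_linear_ptml(coefficients, design)
  signal <- switch(flux_model,
    ptml = linear_part,
    respirometry = {
      profile_flux <- mapply(function(g, t) profiles[[g]][match(t, times)],
                             case_key, cases$time)
      profile_flux + (linear_part - coefficients$a0 -
                        coefficients$a1 * design$Jm_expected -
                        coefficients$a2 * design$t)
    }
  )
  noise_sd <- noise_frac * stats::sd(signal)
  cases$flux <- signal + if (noise_sd > 0) stats::rnorm(length(signal), 0, noise_sd) else 0
  cases <- cases[c("flux", "cnt_id", "rep", "cnt_type", "func_type", "solvent", "time")]

  list(
    spectra = spectra,
    cases = cases,
    invariants = inv_tab,
    truth = list(coefficients = coefficients, design = design,
                 jm_expected = as.numeric(jm_true), signal = signal,
                 noise_sd = noise_sd, flux_model = flux_model, basal = basal)
  )
}

#' Write a simulated study to disk in the package's input formats
#'
#' Emits one two-column CSV per spectrum, the case-table CSV (headers per
#' [default_case_columns()]) and a JSON file with the generative truth, so
#' the written files can be read back with [read_spectrum()] and
#' [read_case_table()].
#'
#' @param study list from [simulate_study()].
#' @param dir output directory (created if needed).
#' @return Invisibly, the directory.
#' @export
write_study <- function(study, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (id in names(study$spectra)) {
    sp <- study$spectra[[id]]
    utils::write.csv(data.frame(shift = sp$shifts, intensity = sp$intensities),
                     file.path(dir, paste0(id, ".csv")), row.names = FALSE)
  }
  out <- stats::setNames(study$cases, unname(default_case_columns()[names(study$cases)]))
  utils::write.csv(out, file.path(dir, "cases.csv"), row.names = FALSE)
  truth <- study$truth
  truth$coefficients <- list(a0 = truth$coefficients$a0, a1 = truth$coefficients$a1,
                             a2 = truth$coefficients$a2,
                             beta = as.list(truth$coefficients$beta))
  truth$design <- NULL
  truth$signal <- NULL
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
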