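# Synthetic µXRF spectrum generator.
#
# Physics caricature sufficient to exercise the pipeline: Gaussian emission
# peaks at tabulated line energies on an exponential-plus-constant
# continuum, a scatter feature near the 18 keV excitation energy, Si escape
# peaks at (line - 1.742) keV, a session-specific additive offset curve and
# multiplicative sensitivity curve, a per-acquisition energy-axis jitter,
# and Poisson counting noise. Intensities are "concentrations" in peak-area
# units; no attempt at fundamental-parameter realism.

baseline_conc <- c(Cr = 150, Cu = 150, Se = 120, Br = 120, Ge = 60, Kr = 40,
                   V = 80, Ni = 60, Co = 50, Ce = 40, Nd = 40, Th = 30,
                   U = 25)

conc_profile <- function(...) {
  extra <- c(...)
  out <- baseline_conc
  for (el in names(extra)) out[el] <- extra[[el]]
  out[is.na(out)] <- 0
  out
}

#' Default simulation scenario
#'
#' Emulates the study design the pipeline targets: 38 specimens across 8
#' clades and 7 sites, 6 analysed zones each (3 fossil, 3 sediment), three
#' acquisition sessions with distinct spectral offsets, two control
#' specimens measured in every session, a calcitic-to-ferruginous sediment
#' composition gradient with Fe-correlated trace elements, and
#' clade-specific element profiles. The non-discriminant control elements
#' (Cr, Cu, Se, Br) have identical expected concentrations everywhere.
#'
#' @param seed Integer seed stored in the scenario (mandatory for
#'   reproducibility of [simulate_dataset()]).
#' @return An `xrf_scenario` object (a validated list).
#' @export
default_scenario <- function(seed = 20260925L) {
  sc <- list(
    channels = seq(0.2, 20.6, by = 0.01),
    excitation_kev = 18,
    detector = list(fwhm_a = 0.06, fwhm_b = 0.028, escape_fraction = 0.02,
                    escape_shift = 1.742, kb_ka_ratio = 0.135),
    background = list(amp = 2000, scale = 4, const = 100,
                      scatter_energy = 17.8, scatter_sd = 0.25,
                      scatter_amp = 1500),
    exposure = 20,   # zone-mean spectra integrate many pixels: high counts
    sessions = list(
      "DiffAbs-2018" = list(offset_amp = 0, offset_scale = 5,
                            scatter_add = 0, sens_amp = 0, sens_phase = 0),
      "PUMA-2021" = list(offset_amp = 400, offset_scale = 5,
                         scatter_add = 900, sens_amp = 0.10,
                         sens_phase = 1.0),
      "PUMA-2024" = list(offset_amp = 250, offset_scale = 8,
                         scatter_add = 500, sens_amp = 0.08,
                         sens_phase = 4.0)),
    reference_session = "DiffAbs-2018",
    energy_jitter = 0.025,
    sites = c("Paris Canyon", "Georgetown", "Stewart Canyon", "NoName",
              "Immigrant Canyon", "Montello Canyon", "LAK"),
    site_sd_log = 0.05,
    specimen_sd_log = 0.15,
    zone_sd_log = 0.07,
    sediment = list(
      calcitic = conc_profile(Ca = 6000, Sr = 400, K = 300, Ti = 150,
                              Mn = 200, Fe = 800, Rb = 80, Y = 100,
                              Zn = 80, Ga = 60, As = 50),
      ferruginous = conc_profile(Ca = 1200, Sr = 100, K = 600, Ti = 350,
                                 Mn = 500, Fe = 5000, Rb = 350, Y = 250,
                                 Zn = 500, Ga = 300, As = 300)),
    clades = list(
      # calcite ossicles with micrite infill: essentially the calcitic
      # sediment endmember, Sr/Mn enriched, no phosphate
      echinoderm = list(n = 6, mineralogy = "calcitic", blend = 0.25,
                        conc = conc_profile(Ca = 7000, Sr = 650, Mn = 300,
                                            Fe = 700, P = 50, K = 250,
                                            Ti = 130, Rb = 70, Y = 90,
                                            Zn = 70, Ga = 50, As = 40)),
      ammonoid = list(n = 8, mineralogy = "calcitic", blend = 0.30,
                      conc = conc_profile(Ca = 4000, Sr = 300, P = 1000,
                                          Mn = 120, Fe = 500, Zn = 250)),
      coleoid = list(n = 5, mineralogy = "carbonaceous", blend = 0.35,
                     conc = conc_profile(P = 1500, K = 1000, Ti = 550,
                                         V = 220, Fe = 1100, Ni = 280,
                                         Ca = 800)),
      arthropod = list(n = 7, mineralogy = "phosphatic", blend = 0.30,
                       conc = conc_profile(P = 3000, Ca = 3500, Zn = 800,
                                           Ni = 320, Y = 150, Fe = 600)),
      sponge = list(n = 4, mineralogy = "phosphatic", blend = 0.45,
                    conc = conc_profile(P = 2500, Ca = 3000, Ti = 650,
                                        Mn = 650, Fe = 1600)),
      brachiopod = list(n = 4, mineralogy = "phosphatic", blend = 0.30,
                        conc = conc_profile(P = 3500, Ca = 4000, K = 750,
                                            Sr = 280, Mn = 80, Fe = 500)),
      actinopterygian = list(n = 3, mineralogy = "phosphatic", blend = 0.30,
                             conc = conc_profile(P = 4000, Ca = 4500,
                                                 Y = 420, Ce = 260,
                                                 Nd = 210, Zn = 420,
                                                 Fe = 450)),
      sarcopterygian = list(n = 1, mineralogy = "phosphatic", blend = 0.30,
                            conc = conc_profile(P = 3800, Ca = 4200,
                                                Y = 520, Th = 210,
                                                Zn = 300, Sr = 380,
                                                Fe = 450))),
    n_ppa = 2L,        # ammonoid specimens preserved mostly as moulds
    ppa_blend = 0.85,
    control_clades = c("echinoderm", "arthropod"),  # 1st specimen of each
    # elements whose planted contrasts are between classes; Fe, Rb, Ga, As
    # instead carry the within-sediment gradient and are not listed
    discriminant_elements = c("P", "K", "Ca", "Ti", "Mn", "Zn", "Sr", "Y"),
    nondiscriminant_elements = c("Cr", "Cu", "Se", "Br"),
    poisson = TRUE,
    seed = as.integer(seed))
  validate_scenario(sc)
}

#' Validate a simulation scenario
#'
#' @param scenario A scenario list.
#' @return The scenario, classed `xrf_scenario`, with the line table
#'   attached.
#' @export
validate_scenario <- function(scenario) {
  sc <- scenario
  if (is.null(sc$seed)) stopf("scenario seed is mandatory")
  for (cl in names(sc$clades)) {
    p <- sc$clades[[cl]]
    if (any(p$conc < 0)) stopf("negative concentration in clade %s", cl)
    if (p$blend < 0 || p$blend > 1) stopf("blend fraction outside [0,1]")
  }
  if (any(sc$sediment$calcitic < 0) || any(sc$sediment$ferruginous < 0)) {
    stopf("negative sediment concentration")
  }
  if (is.null(sc$line_table)) {
    lines <- emission_lines()
    ratio <- ifelse(lines$line == "Kb1", sc$detector$kb_ka_ratio, 1)
    keep <- lines$energy_kev <= sc$excitation_kev
    sc$line_table <- data.frame(element = lines$element[keep],
                                energy = lines$energy_kev[keep],
                                ratio = ratio[keep],
                                stringsAsFactors = FALSE)
  }
  class(sc) <- "xrf_scenario"
  sc
}

detector_sigma <- function(scenario, energy) {
  (scenario$detector$fwhm_a + scenario$detector$fwhm_b * sqrt(energy)) / 2.355
}

# Expected counts per channel (before Poisson sampling).
spectrum_expectation <- function(concentrations, scenario, session,
                                 jitter = 0) {
  sc <- scenario
  energy <- sc$channels + jitter
  width <- sc$channels[2L] - sc$channels[1L]
  bg <- sc$background
  dens <- bg$amp * exp(-energy / bg$scale) + bg$const
  sp <- sc$sessions[[session]]
  if (is.null(sp)) stopf("unknown session '%s'", session)
  dens <- dens + sp$offset_amp * exp(-energy / sp$offset_scale)
  dens <- dens + (bg$scatter_amp + sp$scatter_add) *
    stats::dnorm(energy, bg$scatter_energy, bg$scatter_sd)
  lt <- sc$line_table
  esc <- sc$detector$escape_fraction
  shift <- sc$detector$escape_shift
  for (el in names(concentrations)) {
    ce <- concentrations[[el]]
    if (ce <= 0) next
    rows <- which(lt$element == el)
    if (length(rows) == 0L) stopf("no emission line data for element %s", el)
    for (r in rows) {
      e0 <- lt$energy[r]
      area <- ce * lt$ratio[r]
      s <- detector_sigma(sc, e0)
      win <- abs(energy - e0) < 6 * s
      dens[win] <- dens[win] + area * stats::dnorm(energy[win], e0, s)
      e_esc <- e0 - shift
      if (e_esc > energy[1L]) {
        s2 <- detector_sigma(sc, max(e_esc, 0.3))
        win <- abs(energy - e_esc) < 6 * s2
        dens[win] <- dens[win] + area * esc * stats::dnorm(energy[win],
                                                           e_esc, s2)
      }
    }
  }
  sens <- 1 + sp$sens_amp * sin(2 * pi * energy / 20.6 + sp$sens_phase)
  lambda <- pmax(0, dens * sens * width * sc$exposure)
  list(energy = energy, lambda = lambda)
}

#' Simulate one µXRF spectrum
#'
#' @param concentrations Named numeric vector, element symbol -> peak-area
#'   concentration (>= 0). Every named element must have line data.
#' @param scenario An `xrf_scenario`.
#' @param session Session whose offset/sensitivity curves apply.
#' @param jitter Energy-axis shift in keV (drawn per acquisition by
#'   [simulate_dataset()]).
#' @param noise Apply Poisson counting noise (`FALSE` gives the expected
#'   counts).
#' @param zone_id Identifier for the resulting spectrum.
#' @return An [xrf_spectrum()].
#' @export
simulate_spectrum <- function(concentrations, scenario,
                              session = scenario$reference_session,
                              jitter = 0, noise = scenario$poisson,
                              zone_id = "sim") {
  stopifnot(inherits(scenario, "xrf_scenario"))
  ex <- spectrum_expectation(concentrations, scenario, session, jitter)
  counts <- if (noise) stats::rpois(length(ex$lambda), ex$lambda) else
    ex$lambda
  xrf_spectrum(ex$energy, counts, zone_id)
}

#' Build the study-design manifest for a scenario (no spectra)
#'
#' Lays out specimens, zones and sessions: each specimen gets 6 zones
#' (3 fossil, 3 sediment) acquired in its own session; the designated
#' control specimens are acquired in every session. Also draws the latent
#' per-specimen sediment gradient position `g`.
#'
#' @param scenario An `xrf_scenario`.
#' @return A list: `manifest` (one row per acquired spectrum) and
#'   `specimens` (one row per specimen with `g`, `ppa`, `control`,
#'   `session`).
#' @export
design_manifest <- function(scenario) {
  stopifnot(inherits(scenario, "xrf_scenario"))
  sc <- scenario
  with_seed(sc$seed, {
    clades <- names(sc$clades)
    spec_rows <- list()
    i <- 0L
    for (cl in clades) {
      n <- sc$clades[[cl]]$n
      for (j in seq_len(n)) {
        i <- i + 1L
        spec_rows[[i]] <- data.frame(
          specimen_id = sprintf("%s%02d", substr(cl, 1L, 3L), j),
          clade = cl,
          ppa = (cl == "ammonoid" && j <= sc$n_ppa),
          control = (cl %in% sc$control_clades && j == 1L),
          stringsAsFactors = FALSE)
      }
    }
    specimens <- do.call(rbind, spec_rows)
    n_spec <- nrow(specimens)
    specimens$site <- rep_len(sc$sites, n_spec)
    sessions <- names(sc$sessions)
    specimens$session <- rep_len(sessions, n_spec)
    specimens$g <- stats::runif(n_spec)
    zones <- c("f1", "f2", "f3", "s1", "s2", "s3")
    man_rows <- list()
    r <- 0L
    for (i in seq_len(n_spec)) {
      sp <- specimens[i, ]
      sess_i <- if (sp$control) sessions else sp$session
      for (se in sess_i) {
        for (z in zones) {
          r <- r + 1L
          fossil <- startsWith(z, "f")
          man_rows[[r]] <- data.frame(
            zone_id = paste(sp$specimen_id, z, sep = "_"),
            file = sprintf("%s_%s_%s.csv", sp$specimen_id, z, se),
            specimen_id = sp$specimen_id,
            site = sp$site,
            clade = sp$clade,
            zone_type = if (fossil) "fossil" else "sediment",
            session = se,
            mineralogy = if (!fossil) "matrix" else
              if (sp$ppa) "calcitic" else sc$clades[[sp$clade]]$mineralogy,
            stringsAsFactors = FALSE)
        }
      }
    }
    list(manifest = validate_manifest(do.call(rbind, man_rows)),
         specimens = specimens)
  })
}

#' Simulate a full labelled µXRF dataset
#'
#' Draws the design from [design_manifest()], then per-site, per-specimen
#' and per-zone lognormal concentration perturbations, blends fossil zones
#' with their specimen's sediment, applies session offsets and a per
#' (specimen, session) energy-axis jitter, and Poisson-samples every
#' spectrum. Bit-reproducible from `(scenario, scenario$seed)`.
#'
#' @param scenario An `xrf_scenario` (see [default_scenario()]).
#' @param dir Optional directory: when given, spectra are written as
#'   delimited files plus `manifest.csv` and ground-truth tables.
#' @return An `xrf_dataset`: `spectra` (list of [xrf_spectrum()]),
#'   `manifest`, `truth` (specimen table, zone concentration matrix,
#'   session parameters, discriminant element sets).
#' @export
simulate_dataset <- function(scenario, dir = NULL) {
  stopifnot(inherits(scenario, "xrf_scenario"))
  sc <- scenario
  design <- design_manifest(sc)
  manifest <- design$manifest
  specimens <- design$specimens
  elements <- names(baseline_conc_union(sc))
  with_seed(sc$seed + 1L, {
    # fixed per-(site, element) geology multiplier
    site_mult <- matrix(exp(stats::rnorm(length(sc$sites) * length(elements),
                                         0, sc$site_sd_log)),
                        nrow = length(sc$sites),
                        dimnames = list(sc$sites, elements))
    n_spec <- nrow(specimens)
    spec_fossil_mult <- matrix(exp(stats::rnorm(n_spec * length(elements),
                                                0, sc$specimen_sd_log)),
                               nrow = n_spec,
                               dimnames = list(specimens$specimen_id,
                                               elements))
    spec_sed_mult <- matrix(exp(stats::rnorm(n_spec * length(elements),
                                             0, sc$specimen_sd_log)),
                            nrow = n_spec,
                            dimnames = list(specimens$specimen_id, elements))
    # latent per-zone concentrations (element x zone)
    zone_ids <- unique(manifest$zone_id)
    zone_conc <- matrix(0, nrow = length(zone_ids), ncol = length(elements),
                        dimnames = list(zone_ids, elements))
    for (zi in seq_along(zone_ids)) {
      z <- zone_ids[zi]
      sp_id <- manifest$specimen_id[match(z, manifest$zone_id)]
      sp <- specimens[specimens$specimen_id == sp_id, ]
      sed <- (1 - sp$g) * sc$sediment$calcitic[elements] +
        sp$g * sc$sediment$ferruginous[elements]
      sed[is.na(sed)] <- 0
      fossil_zone <- manifest$zone_type[match(z, manifest$zone_id)] == "fossil"
      zone_mult <- exp(stats::rnorm(length(elements), 0, sc$zone_sd_log))
      base <- if (fossil_zone) {
        b <- if (sp$ppa) sc$ppa_blend else sc$clades[[sp$clade]]$blend
        cp <- sc$clades[[sp$clade]]$conc[elements]
        cp[is.na(cp)] <- 0
        (1 - b) * cp * spec_fossil_mult[sp_id, ] +
          b * sed * spec_sed_mult[sp_id, ]
      } else {
        sed * spec_sed_mult[sp_id, ]
      }
      zone_conc[zi, ] <- base * site_mult[sp$site, ] * zone_mult
    }
    # per (specimen, session) energy jitter
    key <- unique(manifest[, c("specimen_id", "session")])
    key$jitter <- stats::runif(nrow(key), -sc$energy_jitter,
                               sc$energy_jitter)
    spectra <- vector("list", nrow(manifest))
    for (r in seq_len(nrow(manifest))) {
      row <- manifest[r, ]
      jit <- key$jitter[key$specimen_id == row$specimen_id &
                          key$session == row$session]
      conc <- zone_conc[row$zone_id, ]
      spectra[[r]] <- simulate_spectrum(conc, sc, session = row$session,
                                        jitter = jit, noise = sc$poisson,
                                        zone_id = row$zone_id)
    }
    truth <- list(specimens = specimens, zone_concentrations = zone_conc,
                  session_jitter = key, sessions = sc$sessions,
                  discriminant_elements = sc$discriminant_elements,
                  nondiscriminant_elements = sc$nondiscriminant_elements,
                  seed = sc$seed)
    out <- structure(list(spectra = spectra, manifest = manifest,
                          truth = truth, scenario = sc),
                     class = "xrf_dataset")
    if (!is.null(dir)) write_dataset(out, dir)
    out
  })
}

baseline_conc_union <- function(sc) {
  nm <- unique(c(names(baseline_conc), names(sc$sediment$calcitic),
                 names(sc$sediment$ferruginous),
                 unlist(lapply(sc$clades, function(p) names(p$conc)))))
  stats::setNames(rep(0, length(nm)), nm)
}

#' @export
print.xrf_dataset <- function(x, ...) {
  cat(sprintf("<xrf_dataset> %d spectra, %d specimens, sessions: %s\n",
              length(x$spectra), nrow(x$truth$specimens),
              paste(names(x$scenario$sessions), collapse = ", ")))
  invisible(x)
}

write_dataset <- function(dataset, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  sdir <- file.path(dir, "spectra")
  dir.create(sdir, showWarnings = FALSE)
  for (r in seq_len(nrow(dataset$manifest))) {
    write_spectrum(dataset$spectra[[r]],
                   file.path(sdir, dataset$manifest$file[r]))
  }
  utils::write.csv(dataset$manifest, file.path(dir, "manifest.csv"),
                   row.names = FALSE)
  utils::write.csv(dataset$truth$specimens,
                   file.path(dir, "truth_specimens.csv"), row.names = FALSE)
  utils::write.csv(as.data.frame(dataset$truth$zone_concentrations),
                   file.path(dir, "truth_zone_concentrations.csv"),
                   row.names = TRUE)
  invisible(dir)
}

#' Landmark matrix straight from a simulated dataset
#'
#' Formats every simulated spectrum through the standard chain (subset,
#' log-standardise, landmark) without touching disk.
#'
#' @param dataset An `xrf_dataset`.
#' @return An `xrf_landmarks` object.
#' @export
dataset_landmarks <- function(dataset) {
  stopifnot(inherits(dataset, "xrf_dataset"))
  vecs <- lapply(dataset$spectra, format_spectrum)
  landmark_matrix(vecs, dataset$manifest)
}
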