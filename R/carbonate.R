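# Seawater carbonate-system solution from pH and total alkalinity, with the
# constant formulations that are the CO2SYS defaults: K1/K2 Lueker et al.
# (2000), K0 Weiss (1974), KB Dickson (1990), KW Millero (1995), Ksp Mucci
# (1983), total borate Uppstrom (1974). All constants are expressed on the
# total hydrogen-ion scale at surface pressure; nutrients are assumed zero.

#' Equilibrium constants of the seawater carbonate system
#'
#' Computes the dissociation/solubility constants at the given temperature
#' and salinity, on the total pH scale (mol/kg-sw). The chosen formulations
#' are valid for roughly 2-35 degrees C and 19-43 psu; values outside that
#' envelope are computed anyway with a warning.
#'
#' @param temperature_C Water temperature, degrees Celsius.
#' @param salinity_psu Practical salinity.
#' @return List of class `constants_set`: `K0` (mol/kg/atm), `K1`, `K2`,
#'   `KB`, `KW`, `KS` (free scale), `KF`, `Ksp_calcite`, `Ksp_aragonite`
#'   (mol^2/kg^2), and the salinity-derived totals `TB`, `TS`, `TF` (mol/kg)
#'   plus the SWS-to-total conversion factor used internally.
#' @export
equilibrium_constants <- function(temperature_C, salinity_psu) {
  if (temperature_C < 2 || temperature_C > 35 ||
      salinity_psu < 19 || salinity_psu > 43)
    warning("temperature/salinity outside the formulation envelope ",
            "(2-35 C, 19-43 psu); constants extrapolated", call. = FALSE)
  T <- temperature_C + 273.15
  S <- salinity_psu
  lnT <- log(T)

  # salinity-proportional totals (mol/kg-sw)
  TB <- 0.0004157 * S / 35                    # Uppstrom 1974
  TS <- (0.14 / 96.062) * (S / 1.80655)       # Morris & Riley 1966
  TF <- (0.000067 / 18.998) * (S / 1.80655)   # Riley 1965

  # bisulfate, Dickson 1990 (free scale, mol/kg-sw)
  IonS <- 19.924 * S / (1000 - 1.005 * S)
  lnKS <- -4276.1 / T + 141.328 - 23.093 * lnT +
    (-13856 / T + 324.57 - 47.986 * lnT) * sqrt(IonS) +
    (35474 / T - 771.54 + 114.723 * lnT) * IonS -
    2698 / T * IonS^1.5 + 1776 / T * IonS^2 +
    log(1 - 0.001005 * S)
  KS <- exp(lnKS)

  # hydrogen fluoride, Perez & Fraga 1987 (total scale), moved to free
  KF_total <- exp(874 / T - 9.68 + 0.111 * sqrt(S))
  KF <- KF_total / (1 + TS / KS)

  sws_to_total <- (1 + TS / KS) / (1 + TS / KS + TF / KF)

  # CO2 solubility, Weiss 1974 (mol/kg/atm)
  K0 <- exp(93.4517 * (100 / T) - 60.2409 + 23.3585 * log(T / 100) +
            S * (0.023517 - 0.023656 * (T / 100) +
                 0.0047036 * (T / 100)^2))

  # carbonic acid, Lueker et al. 2000 (total scale)
  pK1 <- 3633.86 / T - 61.2172 + 9.67770 * lnT -
    0.011555 * S + 0.0001152 * S^2
  pK2 <- 471.78 / T + 25.929 - 3.16967 * lnT -
    0.01781 * S + 0.0001122 * S^2
  K1 <- 10^(-pK1); K2 <- 10^(-pK2)

  # boric acid, Dickson 1990 (total scale)
  lnKB <- (-8966.90 - 2890.53 * sqrt(S) - 77.942 * S +
           1.728 * S^1.5 - 0.0996 * S^2) / T +
    148.0248 + 137.1942 * sqrt(S) + 1.62142 * S +
    (-24.4344 - 25.085 * sqrt(S) - 0.2474 * S) * lnT +
    0.053105 * sqrt(S) * T
  KB <- exp(lnKB)

  # water, Millero 1995 (SWS scale), converted to total
  lnKW <- 148.9802 - 13847.26 / T - 23.6521 * lnT +
    (118.67 / T - 5.977 + 1.0495 * lnT) * sqrt(S) - 0.01615 * S
  KW <- exp(lnKW) * sws_to_total

  # calcite / aragonite solubility, Mucci 1983 (mol^2/kg^2)
  log10T <- log10(T)
  logKca <- -171.9065 - 0.077993 * T + 2839.319 / T + 71.595 * log10T +
    (-0.77712 + 0.0028426 * T + 178.34 / T) * sqrt(S) -
    0.07711 * S + 0.0041249 * S^1.5
  logKar <- -171.945 - 0.077993 * T + 2903.293 / T + 71.595 * log10T +
    (-0.068393 + 0.0017276 * T + 88.135 / T) * sqrt(S) -
    0.10018 * S + 0.0059415 * S^1.5

  structure(list(K0 = K0, K1 = K1, K2 = K2, KB = KB, KW = KW, KS = KS,
                 KF = KF, Ksp_calcite = 10^logKca,
                 Ksp_aragonite = 10^logKar,
                 TB = TB, TS = TS, TF = TF, sws_to_total = sws_to_total,
                 temperature_C = temperature_C, salinity_psu = salinity_psu),
            class = "constants_set")
}

#' Construct and validate a water sample
#'
#' @param date Sample date (anything `as.Date` accepts), optional.
#' @param site Site label, optional.
#' @param pH Measured pH.
#' @param pH_scale `"total"` (default) or `"nbs"`; NBS readings are
#'   converted to the total scale through the activity-coefficient
#'   approximation before solving.
#' @param TA_umol_kg Total alkalinity, micromol/kg.
#' @param temperature_C,salinity_psu Conditions at measurement.
#' @return List of class `water_sample`.
#' @export
water_sample <- function(pH, TA_umol_kg, temperature_C, salinity_psu,
                         date = NA, site = NA_character_,
                         pH_scale = c("total", "nbs")) {
  pH_scale <- match.arg(pH_scale)
  if (pH <= 6 || pH >= 9.5) stop("pH outside (6, 9.5)", call. = FALSE)
  if (salinity_psu <= 0 || salinity_psu >= 45)
    stop("salinity outside (0, 45)", call. = FALSE)
  if (TA_umol_kg <= 0) stop("TA must be positive", call. = FALSE)
  structure(list(date = date, site = site, pH = pH, pH_scale = pH_scale,
                 TA_umol_kg = TA_umol_kg, temperature_C = temperature_C,
                 salinity_psu = salinity_psu),
            class = "water_sample")
}

# Total alkalinity (mol/kg) implied by total-scale [H] and DIC, including
# the borate, water, free-proton, bisulfate and fluoride terms.
ta_from_h_dic <- function(H, DIC, k) {
  denom <- H^2 + k$K1 * H + k$K1 * k$K2
  HCO3 <- DIC * k$K1 * H / denom
  CO3 <- DIC * k$K1 * k$K2 / denom
  Hfree <- H / (1 + k$TS / k$KS)
  HCO3 + 2 * CO3 + k$TB * k$KB / (k$KB + H) + k$KW / H -
    Hfree - k$TS / (1 + k$KS / Hfree) - k$TF / (1 + k$KF / Hfree)
}

#' Solve the carbonate system from pH and total alkalinity
#'
#' With hydrogen-ion concentration fixed by the pH, the borate, water and
#' minor acid-base contributions are subtracted from TA to yield carbonate
#' alkalinity, which together with K1/K2 gives the carbonate species, DIC,
#' pCO2 and the calcite/aragonite saturation states (calcium scaled from
#' salinity as 0.01028 * S / 35 mol/kg).
#'
#' @param sample A `water_sample` (or list with fields `pH`, `TA_umol_kg`,
#'   `temperature_C`, `salinity_psu`, optional `pH_scale`).
#' @return List of class `carbonate_state`: `DIC_umol_kg`, `pCO2_uatm`,
#'   `CO3_umol_kg`, `HCO3_umol_kg`, `CO2aq_umol_kg`, `omega_calcite`,
#'   `omega_aragonite`, plus the total-scale pH actually used.
#' @export
solve_from_ph_ta <- function(sample) {
  k <- equilibrium_constants(sample$temperature_C, sample$salinity_psu)
  pH <- sample$pH
  scale <- if (is.null(sample$pH_scale)) "total" else sample$pH_scale
  if (scale == "nbs") {
    # NBS (activity) -> SWS via the Takahashi fH factor, then SWS -> total
    T <- sample$temperature_C + 273.15
    fH <- 1.2948 - 0.002036 * T +
      (0.0004607 - 0.000001475 * T) * sample$salinity_psu^2
    H_sws <- 10^(-pH) / fH
    H <- H_sws * k$sws_to_total
    pH <- -log10(H)
    message("pH converted from NBS to total scale: ", round(sample$pH, 4),
            " -> ", round(pH, 4))
  }
  H <- 10^(-pH)
  TA <- sample$TA_umol_kg * 1e-6
  Hfree <- H / (1 + k$TS / k$KS)
  CA <- TA - k$TB * k$KB / (k$KB + H) - k$KW / H + Hfree +
    k$TS / (1 + k$KS / Hfree) + k$TF / (1 + k$KF / Hfree)
  if (CA <= 0)
    stop("infeasible sample: non-positive carbonate alkalinity after ",
         "borate/water correction", call. = FALSE)
  HCO3 <- CA / (1 + 2 * k$K2 / H)
  CO3 <- HCO3 * k$K2 / H
  CO2aq <- HCO3 * H / k$K1
  Ca <- 0.01028 * sample$salinity_psu / 35
  structure(list(
    DIC_umol_kg = (CO2aq + HCO3 + CO3) * 1e6,
    pCO2_uatm = CO2aq / k$K0 * 1e6,
    CO3_umol_kg = CO3 * 1e6,
    HCO3_umol_kg = HCO3 * 1e6,
    CO2aq_umol_kg = CO2aq * 1e6,
    omega_calcite = Ca * CO3 / k$Ksp_calcite,
    omega_aragonite = Ca * CO3 / k$Ksp_aragonite,
    pH_total = pH, TA_umol_kg = sample$TA_umol_kg,
    temperature_C = sample$temperature_C,
    salinity_psu = sample$salinity_psu), class = "carbonate_state")
}

#' @export
print.carbonate_state <- function(x, ...) {
  cat(sprintf(
    "Carbonate system at pH(T) %.3f, TA %.1f umol/kg, %.1f C, S %.2f:\n",
    x$pH_total, x$TA_umol_kg, x$temperature_C, x$salinity_psu))
  cat(sprintf("  DIC %.1f  HCO3 %.1f  CO3 %.1f  CO2aq %.1f umol/kg\n",
              x$DIC_umol_kg, x$HCO3_umol_kg, x$CO3_umol_kg, x$CO2aq_umol_kg))
  cat(sprintf("  pCO2 %.1f uatm  Omega_ca %.2f  Omega_ar %.2f\n",
              x$pCO2_uatm, x$omega_calcite, x$omega_aragonite))
  invisible(x)
}

#' Total-scale pH from DIC and total alkalinity
#'
#' Inverts the alkalinity balance by safeguarded root bracketing on
#' pH in (6, 9.5), to a tolerance of 1e-10 in pH. Serves as the round-trip
#' oracle for [solve_from_ph_ta()].
#'
#' @param DIC_umol_kg,TA_umol_kg Dissolved inorganic carbon and total
#'   alkalinity, micromol/kg.
#' @param temperature_C,salinity_psu Conditions.
#' @return Total-scale pH.
#' @export
ph_from_dic_ta <- function(DIC_umol_kg, TA_umol_kg, temperature_C,
                           salinity_psu) {
  stopifnot(DIC_umol_kg > 0, TA_umol_kg > 0)
  k <- equilibrium_constants(temperature_C, salinity_psu)
  DIC <- DIC_umol_kg * 1e-6
  TA <- TA_umol_kg * 1e-6
  f <- function(pH) ta_from_h_dic(10^(-pH), DIC, k) - TA
  lo <- f(6); hi <- f(9.5)
  if (sign(lo) == sign(hi))
    stop("no pH in (6, 9.5) balances this (DIC, TA) pair", call. = FALSE)
  stats::uniroot(f, c(6, 9.5), tol = 1e-12)$root
}

#' Read water samples / write carbonate states as CSV
#'
#' Input columns: `date,site,ph,ph_scale,ta_umol_kg,temp_c,sal_psu`
#' (`ph_scale` may be omitted; defaults to `total`).
#'
#' @param path CSV path.
#' @return `read_water_samples` returns a list of `water_sample`s;
#'   `solve_water_samples` a data frame of carbonate states.
#' @export
read_water_samples <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("date", "site", "ph", "ta_umol_kg", "temp_c", "sal_psu")
  if (!all(need %in% names(d)))
    stop("water-sample file missing columns: ",
         paste(setdiff(need, names(d)), collapse = ", "), call. = FALSE)
  if (!"ph_scale" %in% names(d)) d$ph_scale <- "total"
  lapply(seq_len(nrow(d)), function(i)
    water_sample(pH = d$ph[i], TA_umol_kg = d$ta_umol_kg[i],
                 temperature_C = d$temp_c[i], salinity_psu = d$sal_psu[i],
                 date = d$date[i], site = d$site[i],
                 pH_scale = d$ph_scale[i]))
}

#' @rdname read_water_samples
#' @param samples List of `water_sample`s.
#' @export
solve_water_samples <- function(samples) {
  rows <- lapply(samples, function(s) {
    st <- solve_from_ph_ta(s)
    data.frame(date = as.character(s$date), site = s$site,
               pH_total = st$pH_total, TA_umol_kg = st$TA_umol_kg,
               DIC_umol_kg = st$DIC_umol_kg, pCO2_uatm = st$pCO2_uatm,
               CO3_umol_kg = st$CO3_umol_kg, HCO3_umol_kg = st$HCO3_umol_kg,
               CO2aq_umol_kg = st$CO2aq_umol_kg,
               omega_calcite = st$omega_calcite,
               omega_aragonite = st$omega_aragonite)
  })
  out <- do.call(rbind, rows)
  row.names(out) <- NULL
  out
}
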