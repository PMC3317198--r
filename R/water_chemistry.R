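# Atomic masses (IUPAC) used for molar conversions
.CA_MASS <- 40.078
.MG_MASS <- 24.305

#' Water hardness as CaCO3 equivalents
#'
#' Hardness (mg CaCO3/L) = 2.497 Ca + 4.118 Mg, the Standard Methods
#' CaCO3-equivalent coefficients for dissolved calcium and magnesium.
#'
#' @param ca,mg Dissolved Ca and Mg (mg/L, >= 0). Vectorized.
#' @param ca_coef,mg_coef Equivalence coefficients, exposed for alternative
#'   conventions.
#' @return Hardness in mg CaCO3/L.
#' @export
#' @examples
#' hardness(73.33, 30.5)  # ~308.7 mg CaCO3/L, very hard water
hardness <- function(ca, mg, ca_coef = 2.497, mg_coef = 4.118) {
  stop_if(any(ca < 0, na.rm = TRUE) || any(mg < 0, na.rm = TRUE),
          "`ca` and `mg` must be non-negative")
  ca_coef * ca + mg_coef * mg
}

#' Hardness-normalize an LC50 (US EPA conversion)
#'
#' Converts an LC50 measured at one hardness to a reference hardness using
#' the US EPA ambient-water-quality-criteria conversion for copper:
#' \deqn{\mathrm{LC50}_{ref} = \exp\{\ln \mathrm{LC50} - s\,
#'   (\ln H - \ln H_{ref})\} = \mathrm{LC50}\,(H_{ref}/H)^{s}}
#' with pooled slope s = 0.9422 and reference hardness 50 mg CaCO3/L by
#' default. Normalization makes toxicity estimates from waters of very
#' different hardness (e.g. a very hard river vs a soft laboratory water)
#' directly comparable.
#'
#' @param lc50 LC50 (mg/L, > 0). Vectorized.
#' @param hardness Hardness of the test water (mg CaCO3/L, > 0).
#' @param ref_hardness Reference hardness (mg CaCO3/L, > 0), default 50.
#' @param exponent Pooled hardness slope, default 0.9422.
#' @return Normalized LC50 (mg/L) at `ref_hardness`.
#' @export
#' @examples
#' normalize_lc50_hardness(0.655, hardness(73.33, 30.5))  # ~0.12 mg/L
normalize_lc50_hardness <- function(lc50, hardness, ref_hardness = 50,
                                    exponent = 0.9422) {
  stop_if(any(lc50 <= 0, na.rm = TRUE), "`lc50` must be positive")
  stop_if(any(hardness <= 0, na.rm = TRUE) || any(ref_hardness <= 0, na.rm = TRUE),
          "hardness values must be positive")
  lc50 * (ref_hardness / hardness)^exponent
}

#' Calcium-to-magnesium molar ratio
#'
#' (Ca/40.078) / (Mg/24.305). Ratios above 1 indicate hardness dominated by
#' calcium, the more protective cation against copper toxicity to fish.
#'
#' @param ca,mg Dissolved Ca (>= 0) and Mg (> 0), mg/L. Vectorized.
#' @return Dimensionless molar ratio.
#' @export
#' @examples
#' ca_mg_molar_ratio(73.33, 30.5)  # ~1.46
ca_mg_molar_ratio <- function(ca, mg) {
  stop_if(any(ca < 0, na.rm = TRUE), "`ca` must be non-negative")
  stop_if(any(mg <= 0, na.rm = TRUE), "`mg` must be positive")
  (ca / .CA_MASS) / (mg / .MG_MASS)
}

#' Empirical Kd from total suspended solids (BLM-MONTE relation)
#'
#' Kd = 1.04e6 * TSS^-0.7436: the empirical inverse relation between the
#' copper solid/solution partition coefficient and the suspended-solids
#' load. Strictly decreasing in TSS on (0, Inf).
#'
#' @param tss Total suspended solids (mg/L, > 0). Vectorized.
#' @return Empirical Kd estimate.
#' @export
kd_blm_monte <- function(tss) {
  stop_if(any(tss <= 0, na.rm = TRUE), "`tss` must be positive")
  1.04e6 * tss^(-0.7436)
}

#' Copper solid/solution partitioning
#'
#' Particulate copper per unit solid is P.Cu = (T.Cu - D.Cu) / TSS
#' (mg Cu per mg TSS; multiply by 1e6 for ug/g), and the partition
#' coefficient is Kd = P.Cu / D.Cu. The empirical BLM-MONTE Kd from TSS is
#' reported alongside. When D.Cu is 0 the Kd is returned as `NA` with a
#' warning (flagged missing, not a silent zero).
#'
#' @param t_cu Total copper (mg/L). Vectorized.
#' @param d_cu Dissolved copper (mg/L), `d_cu <= t_cu`.
#' @param tss Total suspended solids (mg/L, > 0).
#' @return A tibble: `p_cu_mg_mg`, `p_cu_ug_g`, `kd`, `kd_blm_monte`.
#' @export
#' @examples
#' partition(t_cu = 0.07, d_cu = 0.001, tss = 1637)
partition <- function(t_cu, d_cu, tss) {
  stop_if(any(tss <= 0, na.rm = TRUE), "`tss` must be positive")
  stop_if(any(d_cu > t_cu, na.rm = TRUE),
          "dissolved copper exceeds total copper")
  stop_if(any(d_cu < 0, na.rm = TRUE) || any(t_cu < 0, na.rm = TRUE),
          "copper concentrations must be non-negative")
  p_cu <- (t_cu - d_cu) / tss
  kd <- ifelse(d_cu == 0 & p_cu > 0, NA_real_, ifelse(p_cu == 0, 0, p_cu / d_cu))
  if (any(d_cu == 0 & p_cu > 0, na.rm = TRUE)) {
    warning("Kd undefined where dissolved copper is 0; returned NA", call. = FALSE)
  }
  tibble::tibble(p_cu_mg_mg = p_cu, p_cu_ug_g = p_cu * 1e6,
                 kd = kd, kd_blm_monte = kd_blm_monte(tss))
}

#' Convert particulate copper between mg/mg and ug/g
#'
#' @param p_cu Particulate copper values.
#' @param from,to Units, `"mg_mg"` or `"ug_g"` (1 mg/mg = 1e6 ug/g).
#' @return Converted values.
#' @export
convert_p_cu <- function(p_cu, from = c("mg_mg", "ug_g"), to = c("ug_g", "mg_mg")) {
  from <- match.arg(from); to <- match.arg(to)
  f <- c(mg_mg = 1, ug_g = 1e-6)
  p_cu * f[[from]] / f[[to]]
}

#' Append derived chemistry columns to a monitoring table
#'
#' Adds `hardness_mgCaCO3_L`, `ca_mg_molar_ratio`, `p_cu_mg_mg`, `kd`, and
#' `kd_blm_monte` to a monitoring table carrying `Ca_mg_L`, `Mg_mg_L`,
#' `TCu_mg_L`, `DCu_mg_L`, `TSS_mg_L` columns. Rows with missing inputs get
#' `NA` in the derived columns.
#'
#' @param monitoring A monitoring tibble (see [read_monitoring_csv()]).
#' @return The table with derived columns appended.
#' @export
derive_water_chemistry <- function(monitoring) {
  m <- tibble::as_tibble(monitoring)
  if (all(c("Ca_mg_L", "Mg_mg_L") %in% names(m))) {
    m$hardness_mgCaCO3_L <- hardness(m$Ca_mg_L, m$Mg_mg_L)
    m$ca_mg_molar_ratio <- ifelse(m$Mg_mg_L > 0,
                                  (m$Ca_mg_L / .CA_MASS) / (m$Mg_mg_L / .MG_MASS),
                                  NA_real_)
  }
  if (all(c("TCu_mg_L", "DCu_mg_L", "TSS_mg_L") %in% names(m))) {
    ok <- !is.na(m$TCu_mg_L) & !is.na(m$DCu_mg_L) & !is.na(m$TSS_mg_L) &
      m$TSS_mg_L > 0 & m$DCu_mg_L <= m$TCu_mg_L
    m$p_cu_mg_mg <- m$kd <- m$kd_blm_monte <- NA_real_
    if (any(ok)) {
      pr <- suppressWarnings(
        partition(m$TCu_mg_L[ok], m$DCu_mg_L[ok], m$TSS_mg_L[ok]))
      m$p_cu_mg_mg[ok] <- pr$p_cu_mg_mg
      m$kd[ok] <- pr$kd
      m$kd_blm_monte[ok] <- pr$kd_blm_monte
    }
  }
  m
}
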