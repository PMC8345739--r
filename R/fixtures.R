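#' Canonical metric names
#'
#' The 18 quantitative imaging metrics handled by the package, in canonical
#' order: the two tumor volumes (PET, T2-weighted MRI), the diffusion metrics
#' (ADC, D, D*, f), the DCE water-exchange metrics (Ktrans, ve, tau_i, kep),
#' the FDG uptake metrics (SULmax, SULmean) and the FMISO kinetics metrics
#' (K1, k3max, k3mean, DV, TBRmax, TBRmean).
#'
#' @return Character vector of length 18.
#' @export
qi_metrics <- function() {
  c("Vt_PET", "Vt_MRI", "ADC", "D", "Dstar", "f", "Ktrans", "ve", "tau_i",
    "kep", "SULmax", "SULmean", "K1", "k3max", "k3mean", "DV",
    "TBRmax", "TBRmean")
}

#' Node set used for community detection
#'
#' The 16 metrics retained in the published significance network: all
#' canonical metrics except the PET tumor volume and kep.
#'
#' @return Character vector of length 16.
#' @export
qi_network_metrics <- function() {
  setdiff(qi_metrics(), c("Vt_PET", "kep"))
}

#' Cohort-level metric distributions
#'
#' Mean, SD, units and marginal family for each metric, matching the
#' patient-cohort summary values the simulator is calibrated to (27
#' metastatic head-and-neck lymph nodes). `kep` has no published summary;
#' its defaults derive from Ktrans/ve. `vb`, the PET blood volume fraction,
#' is included for signal generation although it is not a tabulated metric.
#'
#' @return A data.frame with columns `metric`, `mean`, `sd`, `units`,
#'   `family`.
#' @export
qi_metric_defaults <- function() {
  d <- read.csv(system.file("extdata", "metric_defaults.csv",
                            package = "qimnet"),
                stringsAsFactors = FALSE)
  d
}

#' Published Spearman correlation fixture
#'
#' The 18 x 18 Spearman rank-correlation matrix between the quantitative
#' imaging metrics of the reference head-and-neck cohort, together with its
#' significance flags (p < 0.05), shipped as plain-text fixtures. These are
#' inputs to the network stage and calibration targets for the synthetic
#' cohort; the underlying patient data are not public.
#'
#' @return A list with elements `rho` (numeric matrix, unit diagonal),
#'   `significant` (logical matrix, FALSE diagonal), both with canonical
#'   metric dimnames.
#' @examples
#' fx <- table2_correlations()
#' fx$rho["Ktrans", "K1"]
#' @export
table2_correlations <- function() {
  read_m <- function(file) {
    d <- read.csv(system.file("extdata", file, package = "qimnet"),
                  check.names = FALSE)
    m <- as.matrix(d[, -1])
    rownames(m) <- d$metric
    stopifnot(identical(rownames(m), colnames(m)),
              identical(rownames(m), qi_metrics()))
    m
  }
  rho <- read_m("table2_spearman.csv")
  sig <- read_m("table2_significant.csv") == 1
  diag(sig) <- FALSE
  stopifnot(isSymmetric(rho), all(diag(rho) == 1),
            all(abs(rho) <= 1))
  list(rho = rho, significant = sig)
}
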