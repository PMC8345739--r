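#' Pipeline configuration
#'
#' Settings for the end-to-end synthetic study: cohort size and noise,
#' acquisition protocol, network significance level and node set, and the
#' annealing configuration. The defaults reproduce the reference study
#' scale: 27 lesions, 100 voxels per lesion, and seed 20210803.
#'
#' @param n_lesions Lesions in the cohort.
#' @param n_voxels Voxels per lesion for the MRI stages.
#' @param snr Signal-to-noise ratio applied to all modalities (`Inf` for a
#'   noiseless round-trip run).
#' @param seed Global integer seed; all per-lesion seeds derive from it.
#' @param alpha Significance level for network edges.
#' @param include Metric node set for community detection.
#' @param protocol A [default_protocol()].
#' @param annealing An [annealing_config()].
#' @return A list of class `"qimnet_pipeline_config"`.
#' @export
pipeline_config <- function(n_lesions = 27, n_voxels = 100, snr = 50,
                            seed = 20210803L, alpha = 0.05,
                            include = qi_network_metrics(),
                            protocol = default_protocol(),
                            annealing = annealing_config()) {
  stopifnot(n_lesions >= 3, n_voxels >= 1, snr > 0, alpha > 0, alpha <= 1)
  structure(list(n_lesions = n_lesions, n_voxels = n_voxels, snr = snr,
                 seed = as.integer(seed), alpha = alpha, include = include,
                 protocol = protocol, annealing = annealing),
            class = "qimnet_pipeline_config")
}

# ROI summary of per-voxel fits: mean over converged voxels
roi_mean <- function(fits, field, flag_ok = c("ok", "boundary")) {
  vals <- vapply(fits, function(f) f[[field]], numeric(1))
  flags <- vapply(fits, function(f) f$flag, character(1))
  keep <- flags %in% flag_ok & is.finite(vals)
  if (!any(keep)) NA_real_ else mean(vals[keep])
}

# analyze one lesion: simulate raw signals from its ground truth and fit
# every model, returning the fitted metric row
analyze_lesion <- function(truth_row, config, lesion_seed) {
  protocol <- config$protocol
  snr <- config$snr
  out <- list()

  # --- DWI ---
  dwi <- generate_dwi_signal(truth_row, protocol, config$n_voxels, snr,
                             seed = lesion_seed)
  adc_fits <- apply(dwi$signals, 1, function(s) fit_adc(s, dwi$b_values),
                    simplify = FALSE)
  ivim_fits <- apply(dwi$signals, 1, function(s) fit_ivim(s, dwi$b_values),
                     simplify = FALSE)
  out$ADC <- roi_mean(adc_fits, "adc")
  # ADC ground truth implied by the lesion's IVIM parameters: the
  # monoexponential fit of the noiseless biexponential decay
  noiseless <- generate_dwi_signal(truth_row, protocol, 1, Inf,
                                   seed = lesion_seed)
  out$.adc_implied <- fit_adc(noiseless$signals[1, ], noiseless$b_values)$adc
  out$D <- roi_mean(ivim_fits, "d_true")
  out$Dstar <- roi_mean(ivim_fits, "d_star")
  out$f <- roi_mean(ivim_fits, "f")

  # --- DCE ---
  aif <- aif_biexponential(
    bolus_arrival_s = protocol$n_baseline * protocol$dt_dynamic)
  dce <- generate_dce_signal(truth_row, protocol, aif, snr,
                             seed = lesion_seed + 1L,
                             n_voxels = config$n_voxels)
  fxr_fits <- lapply(seq_len(config$n_voxels), function(v) {
    t1 <- estimate_t10(dce$vfa_signals[v, ], protocol$tr,
                       protocol$flip_angles_deg)
    if (!t1$converged) return(list(ktrans = NA_real_, ve = NA_real_,
                                   tau_i = NA_real_, kep = NA_real_,
                                   flag = "t10_failure"))
    fit_fxr(dce$signals[v, ], aif, t1$t10, protocol)
  })
  out$Ktrans <- roi_mean(fxr_fits, "ktrans")
  out$ve <- roi_mean(fxr_fits, "ve")
  out$tau_i <- roi_mean(fxr_fits, "tau_i")
  out$kep <- roi_mean(fxr_fits, "kep")

  # --- FMISO ---
  if_true <- input_function_triphasic()
  blood <- if_frame_means(if_true, protocol$frames)
  set.seed(lesion_seed + 2L)
  if (is.finite(snr)) {
    ipk <- which.max(blood)
    sigma <- (blood[ipk] / snr) *
      sqrt(protocol$frames[ipk, "duration"] / protocol$frames[, "duration"])
    blood <- pmax(blood + rnorm(length(blood), 0, sigma), 0)
  }
  if_fit <- fit_input_function(blood, protocol$frames)
  ifm <- if (if_fit$flag == "ok") if_fit$if_model else if_true
  tac_max <- generate_fmiso_tac(truth_row, if_true, protocol, snr,
                                seed = lesion_seed + 3L)
  truth_mean <- truth_row
  truth_mean$k3 <- truth_row$k3mean
  tac_mean <- generate_fmiso_tac(truth_mean, if_true, protocol, snr,
                                 seed = lesion_seed + 4L)
  fit_max <- fit_2tc(tac_max$tac, ifm, protocol$frames)
  fit_mean <- fit_2tc(tac_mean$tac, ifm, protocol$frames)
  out$K1 <- fit_max$k1
  out$k3max <- fit_max$k3
  out$k3mean <- fit_mean$k3
  out$DV <- fit_max$dv
  nlast <- nrow(protocol$frames)
  out$TBRmax <- tac_max$tac[nlast] / blood[nlast]
  out$TBRmean <- tac_mean$tac[nlast] / blood[nlast]

  # table-level metrics without a raw-signal model: pass-through
  out$Vt_PET <- truth_row$Vt_PET
  out$Vt_MRI <- truth_row$Vt_MRI
  out$SULmax <- truth_row$SULmax
  out$SULmean <- truth_row$SULmean
  out
}

#' Run the full synthetic-study pipeline
#'
#' Simulate a ground-truth cohort, generate raw signals for the three
#' modalities, fit every kinetic model, assemble the lesion x metric table,
#' build the Spearman significance network, detect communities, and
#' summarize parameter recovery. Fully reproducible from the config seed.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Optional output directory; when given, writes
#'   `ground_truth.csv`, `metric_table.csv`, `spearman_rho.csv`,
#'   `spearman_p.csv`, `edges.tsv`, `network.graphml`, `partition.json`
#'   and `recovery.csv`.
#' @return A list with `truth`, `metrics`, `spearman`, `volume_test`,
#'   `network`, `partition`, `recovery`.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = NULL) {
  truth <- sample_ground_truth(config$n_lesions, correlation_spec(),
                               seed = config$seed)
  rows <- lapply(seq_len(config$n_lesions), function(i)
    analyze_lesion(truth[i, ], config, config$seed + 10L * i))
  metrics <- cbind(data.frame(lesion_id = truth$lesion_id),
                   do.call(rbind, lapply(rows, as.data.frame)))
  adc_implied <- metrics$.adc_implied
  metrics <- metrics[, c("lesion_id", qi_metrics())]

  sp <- spearman_matrix(metrics)
  vol <- compare_volumes(metrics$Vt_PET, metrics$Vt_MRI)
  net <- build_significance_network(sp$rho, sp$p, config$include,
                                    config$alpha)
  part <- if (igraph::ecount(net) > 0)
    consensus_partition(net, config$annealing) else NULL

  fitted_cols <- c("ADC", "D", "Dstar", "f", "Ktrans", "ve", "tau_i",
                   "K1", "k3max", "k3mean", "DV")
  recovery <- do.call(rbind, lapply(fitted_cols, function(m) {
    ref <- if (m == "ADC") adc_implied else truth[[m]]
    rel <- (metrics[[m]] - ref) / ref
    data.frame(metric = m, median_rel_error = median(abs(rel), na.rm = TRUE),
               bias = mean(rel, na.rm = TRUE))
  }))

  report <- list(truth = truth, metrics = metrics, spearman = sp,
                 volume_test = vol, network = net, partition = part,
                 recovery = recovery)
  if (!is.null(out_dir)) write_pipeline_outputs(report, out_dir)
  report
}

#' Serialize and restore a pipeline configuration
#'
#' JSON round trip for [pipeline_config()]: `read_pipeline_config()`
#' reconstructs a configuration identical to the one written.
#'
#' @param config A [pipeline_config()].
#' @param path File path for the JSON configuration.
#' @return `write_pipeline_config()` returns `path` invisibly;
#'   `read_pipeline_config()` returns the configuration.
#' @export
write_pipeline_config <- function(config, path) {
  stopifnot(inherits(config, "qimnet_pipeline_config"))
  x <- list(
    n_lesions = config$n_lesions, n_voxels = config$n_voxels,
    snr = if (is.finite(config$snr)) config$snr else "Inf",
    seed = config$seed, alpha = config$alpha, include = config$include,
    protocol = c(unclass(config$protocol)[setdiff(names(config$protocol),
                                                  "frames")],
                 list(frames = unname(apply(config$protocol$frames, 1,
                                            as.numeric, simplify = FALSE)))),
    annealing = unclass(config$annealing))
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_pipeline_config
#' @export
read_pipeline_config <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  fr <- x$protocol$frames
  if (is.list(fr)) fr <- do.call(rbind, lapply(fr, as.numeric))
  fr <- matrix(as.numeric(as.matrix(fr)), ncol = 2)
  prot <- do.call(default_protocol, c(
    x$protocol[setdiff(names(x$protocol), "frames")],
    list(frames = fr)))
  ann <- do.call(annealing_config, x$annealing)
  pipeline_config(n_lesions = x$n_lesions, n_voxels = x$n_voxels,
                  snr = if (identical(x$snr, "Inf")) Inf else x$snr,
                  seed = x$seed, alpha = x$alpha, include = x$include,
                  protocol = prot, annealing = ann)
}

#' Network and communities from the packaged correlation fixture
#'
#' Skips simulation and fitting: ingests the packaged reference Spearman
#' matrix, thresholds it on the published significance flags, and runs the
#' spin-glass consensus. The fixture stores significance as flags rather
#' than p-values, so flagged pairs are assigned a nominal p below any
#' sensible alpha and unflagged pairs one above it.
#'
#' @param include Metric node set (default the 16-network set).
#' @param annealing An [annealing_config()].
#' @return List with `network` (igraph) and `partition`
#'   (`"qimnet_partition"`).
#' @export
analyze_table2_fixture <- function(include = qi_network_metrics(),
                                   annealing = annealing_config()) {
  fx <- table2_correlations()
  p <- ifelse(fx$significant, 0.01, 0.5)
  net <- build_significance_network(fx$rho, p, include, alpha = 0.05)
  list(network = net, partition = consensus_partition(net, annealing))
}

write_pipeline_outputs <- function(report, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  wcsv <- function(d, f) write.csv(d, file.path(out_dir, f), row.names = FALSE)
  wcsv(report$truth, "ground_truth.csv")
  wcsv(report$metrics, "metric_table.csv")
  wcsv(cbind(metric = rownames(report$spearman$rho),
             as.data.frame(report$spearman$rho)), "spearman_rho.csv")
  wcsv(cbind(metric = rownames(report$spearman$p),
             as.data.frame(report$spearman$p)), "spearman_p.csv")
  el <- igraph::as_data_frame(report$network, what = "edges")
  utils::write.table(el[, c("from", "to", "rho", "p")],
                     file.path(out_dir, "edges.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  net <- report$network
  if (!is.null(report$partition)) {
    igraph::V(net)$community <- unname(report$partition$assignment)
    jsonlite::write_json(
      list(assignment = as.list(report$partition$assignment),
           n_communities = report$partition$n_communities,
           hamiltonian = report$partition$hamiltonian,
           stability = report$partition$stability),
      file.path(out_dir, "partition.json"),
      auto_unbox = TRUE, digits = NA, matrix = "rowmajor")
  }
  igraph::write_graph(net, file.path(out_dir, "network.graphml"),
                      format = "graphml")
  wcsv(report$recovery, "recovery.csv")
  invisible(out_dir)
}
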