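# File formats, configuration defaults and report aggregation.
#
# Loss-table format (CSV, header required):
#   sample_id, silica_wt_pct, temperature_K, frequency_Hz, eps_loss
# DSC format (CSV, header required):
#   sample_id, silica_wt_pct, temperature_K, heat_flow_W_per_g
# Temperatures are always kelvin; the composition coordinate is the
# silica weight percent.

#' Analysis defaults
#'
#' The conventions used throughout the pipeline: masterplot and
#' dielectric-strength normalization reference temperature 312 K,
#' kinetic Tg convention tau_alpha = 100 s, coupling crossover time
#' t_c = 2 ps, recrystallization drop threshold 5%, default seed 42.
#'
#' @return Named list of defaults.
#' @export
glassdyn_defaults <- function() {
  list(T_ref_masterplot = 312, T_ref_delta_eps = 312,
       tau_g = 100, t_c = 2e-12, drop_threshold = 0.05, seed = 42)
}

#' Read a dielectric loss table
#'
#' @param path CSV file with columns `sample_id`, `silica_wt_pct`,
#'   `temperature_K`, `frequency_Hz`, `eps_loss`.
#' @return List of [loss_spectrum()] objects, one per (sample,
#'   temperature), ordered by sample then temperature.
#' @export
read_loss_table <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "silica_wt_pct", "temperature_K",
            "frequency_Hz", "eps_loss")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("malformed loss table ", path, ": missing column(s) ",
         paste(miss, collapse = ", "))
  if (nrow(df) == 0) stop("empty loss table: ", path)
  out <- list()
  for (sid in unique(df$sample_id)) {
    sub <- df[df$sample_id == sid, ]
    for (T_K in sort(unique(sub$temperature_K))) {
      ss <- sub[sub$temperature_K == T_K, ]
      ss <- ss[order(ss$frequency_Hz), ]
      out[[length(out) + 1L]] <- loss_spectrum(
        T_K, ss$frequency_Hz, ss$eps_loss,
        sample_id = sid, silica_wt_pct = ss$silica_wt_pct[1])
    }
  }
  out
}

#' Write dielectric loss spectra to a loss table
#'
#' @param spectra list of [loss_spectrum()] objects.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_loss_table <- function(spectra, path) {
  rows <- do.call(rbind, lapply(spectra, function(s)
    data.frame(sample_id = s$sample_id, silica_wt_pct = s$silica_wt_pct,
               temperature_K = s$temperature, frequency_Hz = s$frequencies,
               eps_loss = s$loss)))
  write.csv(rows, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a DSC table
#'
#' @param path CSV file with columns `sample_id`, `silica_wt_pct`,
#'   `temperature_K`, `heat_flow_W_per_g`.
#' @param heating_rate heating rate in K/min (trace metadata).
#' @param exo_up `TRUE` when the file stores exothermic-positive heat
#'   flow (the internal convention); `FALSE` flips the sign on input.
#' @return List of [dsc_trace()] objects, one per sample.
#' @export
read_dsc_table <- function(path, heating_rate = 10, exo_up = TRUE) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "silica_wt_pct", "temperature_K",
            "heat_flow_W_per_g")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("malformed DSC table ", path, ": missing column(s) ",
         paste(miss, collapse = ", "))
  if (nrow(df) == 0) stop("empty DSC table: ", path)
  lapply(unique(df$sample_id), function(sid) {
    ss <- df[df$sample_id == sid, ]
    ss <- ss[order(ss$temperature_K), ]
    hf <- if (exo_up) ss$heat_flow_W_per_g else -ss$heat_flow_W_per_g
    dsc_trace(ss$temperature_K, hf, heating_rate = heating_rate,
              sample_id = sid, silica_wt_pct = ss$silica_wt_pct[1])
  })
}

#' Write DSC traces to a DSC table
#'
#' @param traces list of [dsc_trace()] objects.
#' @param path output CSV path.
#' @param exo_up write exothermic-positive (`TRUE`) or flipped.
#' @return `path`, invisibly.
#' @export
write_dsc_table <- function(traces, path, exo_up = TRUE) {
  rows <- do.call(rbind, lapply(traces, function(x)
    data.frame(sample_id = x$sample_id, silica_wt_pct = x$silica_wt_pct,
               temperature_K = x$temperatures,
               heat_flow_W_per_g = if (exo_up) x$heat_flow else -x$heat_flow)))
  write.csv(rows, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a per-process relaxation table
#'
#' @param points `data.frame` from [extract_relaxation_points()].
#' @param path output TSV path (numbers rounded to 6 significant
#'   digits).
#' @return `path`, invisibly.
#' @export
write_relaxation_table <- function(points, path) {
  num <- vapply(points, is.numeric, logical(1))
  points[num] <- lapply(points[num], signif, digits = 6)
  write.table(points, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a relaxation-map report as JSON
#'
#' Serializes the VFT fit (with standard errors), kinetic Tg, fragility,
#' per-process Arrhenius fits and coupling-model classifications at full
#' double precision.
#'
#' @param map a [relaxation_map()].
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_map_report <- function(map, path) {
  stopifnot(inherits(map, "relaxation_map"))
  rep <- list(
    vft = list(log10_tau_inf = map$vft$log10_tau_inf, T0 = map$vft$T0,
               D = map$vft$D, se = as.list(map$vft$se)),
    Tg_K = map$Tg,
    fragility_m_p = map$fragility$m_p,
    arrhenius = lapply(map$arrhenius, function(a)
      list(log10_tau_inf = a$log10_tau_inf, Ea_kJ_mol = a$Ea,
           se = as.list(a$se))),
    coupling = lapply(map$coupling, function(cp)
      list(n = cp$n, mean_abs_dlog10 = cp$mean_abs_dlog10,
           classification = cp$classification)))
  jsonlite::write_json(rep, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Write a composition-stability report as JSON
#'
#' @param mlc an [fit_mlc()] result.
#' @param trend an [fit_crystallization_trend()] result (optional).
#' @param fractions named list of polymorph-fraction vectors per
#'   composition (optional).
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_stability_report <- function(mlc, trend = NULL, fractions = NULL,
                                   path) {
  rep <- list(mlc = list(w_mlc = mlc$w_mlc, w_mlc_se = mlc$w_mlc_se,
                         slope = mlc$slope, intercept = mlc$intercept,
                         flagged = mlc$flagged))
  if (!is.null(trend))
    rep$crystallization_trend <- list(w_critical = trend$w_critical,
                                      boundary = trend$boundary)
  if (!is.null(fractions))
    rep$polymorph_fractions <- lapply(fractions, as.list)
  jsonlite::write_json(rep, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
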