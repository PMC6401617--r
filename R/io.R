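# CSV readers/writers with `# key: value` metadata headers, plus the
# pipeline driver that chains the analysis stages into one report.
#
# CSV dialect: comma-separated, `.` decimal, UTF-8, units encoded in the
# column names, metadata lines prefixed with `#` before the header row.

.read_csv_meta <- function(path) {
  lines <- readLines(path, warn = FALSE)
  meta_lines <- grep("^\\s*#", lines, value = TRUE)
  meta <- list()
  for (ln in meta_lines) {
    m <- regmatches(ln, regexec("^\\s*#\\s*([^:]+):\\s*(.*)$", ln))[[1]]
    if (length(m) == 3) {
      val <- suppressWarnings(as.numeric(m[3]))
      meta[[trimws(m[2])]] <- if (is.na(val)) trimws(m[3]) else val
    }
  }
  body <- lines[!grepl("^\\s*#", lines)]
  body <- body[nzchar(trimws(body))]
  if (length(body) < 2L)
    stop("corrupt CSV '", path, "': no data rows found")
  df <- tryCatch(
    utils::read.csv(text = paste(body, collapse = "\n"),
                    stringsAsFactors = FALSE, check.names = FALSE),
    error = function(e) stop("corrupt CSV '", path, "': ", conditionMessage(e)))
  for (col in names(df)) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(is.na(v))
    if (length(bad))
      stop("corrupt CSV '", path, "': non-numeric or missing '", col,
           "' at data row ", bad[1])
    df[[col]] <- v
  }
  list(data = df, meta = meta)
}

.write_csv_meta <- function(df, path, meta = list()) {
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  for (key in names(meta))
    writeLines(sprintf("# %s: %s", key, format(meta[[key]], digits = 15)),
               con)
  utils::write.csv(df, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read / write a TCSPC decay or IRF histogram CSV
#'
#' Schema: columns \code{time_ns,counts}; optional metadata in
#' \code{# key: value} header comments.
#'
#' @param path File path.
#' @return \code{read_decay_csv}: a \code{\link{decay_histogram}} with the
#'   metadata attached as attribute \code{"meta"}.
#' @export
read_decay_csv <- function(path) {
  x <- .read_csv_meta(path)
  if (!all(c("time_ns", "counts") %in% names(x$data)))
    stop("decay CSV must have columns time_ns,counts")
  h <- decay_histogram(x$data$time_ns, x$data$counts)
  attr(h, "meta") <- x$meta
  h
}

#' @rdname read_decay_csv
#' @param hist A \code{\link{decay_histogram}}.
#' @param meta Named list of metadata written as \code{# key: value} lines.
#' @export
write_decay_csv <- function(hist, path, meta = list()) {
  stopifnot(inherits(hist, "decay_histogram"))
  .write_csv_meta(data.frame(time_ns = hist$channel_times,
                             counts = hist$counts), path, meta)
}

#' Read / write an isotherm CSV
#'
#' Schema: \code{conc_M,avg_tau_ns[,tau_sd_ns]} with an optional
#' \code{# temperature_C:} header.
#'
#' @param path File path.
#' @return data.frame with attribute \code{temperature_C} (NA if absent).
#' @export
read_isotherm_csv <- function(path) {
  x <- .read_csv_meta(path)
  if (!all(c("conc_M", "avg_tau_ns") %in% names(x$data)))
    stop("isotherm CSV must have columns conc_M,avg_tau_ns")
  out <- x$data
  attr(out, "temperature_C") <-
    if (!is.null(x$meta$temperature_C)) x$meta$temperature_C else NA_real_
  out
}

#' @rdname read_isotherm_csv
#' @param data data.frame as returned by \code{\link{simulate_isotherm}}.
#' @export
write_isotherm_csv <- function(data, path) {
  meta <- list()
  if (!is.null(attr(data, "temperature_C")))
    meta$temperature_C <- attr(data, "temperature_C")
  .write_csv_meta(as.data.frame(data), path, meta)
}

#' Read / write an NMR titration CSV
#'
#' Schema: \code{guest_total_M,shift_ppm[_label]...} with a required
#' \code{# host_total_M:} header.
#'
#' @param path File path.
#' @return data.frame with attribute \code{host_total_M}.
#' @export
read_titration_csv <- function(path) {
  x <- .read_csv_meta(path)
  if (!"guest_total_M" %in% names(x$data) ||
      !any(grepl("^shift_ppm", names(x$data))))
    stop("titration CSV must have guest_total_M and shift_ppm* columns")
  if (is.null(x$meta$host_total_M))
    stop("titration CSV requires a '# host_total_M:' header")
  out <- x$data
  attr(out, "host_total_M") <- x$meta$host_total_M
  out
}

#' @rdname read_titration_csv
#' @param data data.frame as returned by \code{\link{simulate_titration}}.
#' @export
write_titration_csv <- function(data, path) {
  .write_csv_meta(as.data.frame(data), path,
                  list(host_total_M = attr(data, "host_total_M")))
}

#' Read a quenching series CSV (\code{q_conc_M,avg_tau_ns})
#' @param path File path.
#' @return data.frame.
#' @export
read_quench_csv <- function(path) {
  x <- .read_csv_meta(path)
  if (!all(c("q_conc_M", "avg_tau_ns") %in% names(x$data)))
    stop("quench CSV must have columns q_conc_M,avg_tau_ns")
  x$data
}

#' Read a van't Hoff CSV (\code{temp_C,K[,K_sd]})
#' @param path File path.
#' @return data.frame.
#' @export
read_vant_hoff_csv <- function(path) {
  x <- .read_csv_meta(path)
  if (!all(c("temp_C", "K") %in% names(x$data)))
    stop("van't Hoff CSV must have columns temp_C,K")
  x$data
}

#' Run the full analysis pipeline
#'
#' Executes the requested stages in dependency order -- isotherm fits
#' (one per temperature) feed the van't Hoff stage when no explicit K
#' table is supplied; quenching and titration stages run independently --
#' and aggregates one report.  A stage failure is recorded in the report
#' and does not stop later, independent stages.
#'
#' @param config Named list (or path to a YAML file holding one) with any
#'   of the elements:
#'   \describe{
#'     \item{\code{isotherms}}{list of isotherm inputs, each a file path or
#'       a data.frame with attribute \code{temperature_C}.}
#'     \item{\code{vant_hoff}}{file path or data.frame
#'       (\code{temp_C,K[,K_sd]}); if omitted and >= 2 isotherm fits
#'       succeeded, their (temperature, K_D) pairs are used.}
#'     \item{\code{quench}}{file path or data.frame
#'       (\code{q_conc_M,avg_tau_ns}).}
#'     \item{\code{titration}}{list with \code{data} (file path or
#'       data.frame with attribute \code{host_total_M}), optional
#'       \code{mode} ("monomer"/"dimer") and \code{k_dim}.}
#'     \item{\code{decay}}{list with \code{decay} and \code{irf} (file
#'       paths or \code{decay_histogram}s) and optional
#'       \code{n_components}, \code{fit_range}.}
#'   }
#' @return Object of class \code{"analysis_report"}: \code{results} (one
#'   entry per executed stage), \code{errors}, \code{warnings},
#'   \code{provenance} (input digests, package version, timestamp).
#' @export
run_pipeline <- function(config) {
  if (is.character(config) && length(config) == 1L)
    config <- yaml::read_yaml(config)
  stopifnot(is.list(config))
  if (!length(intersect(names(config),
                        c("isotherms", "vant_hoff", "quench", "titration",
                          "decay"))))
    stop("configuration error: no recognized stage in config")

  report <- list(results = list(), errors = list(), warnings = list(),
                 provenance = list(
                   package_version = as.character(utils::packageVersion("suprafit")),
                   timestamp = format(Sys.time(), tz = "UTC"),
                   input_digests = list()))
  note_warn <- function(stage, w)
    report$warnings[[stage]] <<- c(report$warnings[[stage]],
                                   conditionMessage(w))
  run_stage <- function(stage, expr) {
    res <- withCallingHandlers(
      tryCatch(expr, error = function(e) {
        report$errors[[stage]] <<- conditionMessage(e)
        NULL
      }),
      warning = function(w) {
        note_warn(stage, w); invokeRestart("muffleWarning")
      })
    if (!is.null(res)) report$results[[stage]] <<- res
  }
  digest_if_file <- function(x) {
    if (is.character(x) && length(x) == 1L && file.exists(x))
      report$provenance$input_digests[[basename(x)]] <<-
        unname(tools::md5sum(x))
  }

  if (!is.null(config$decay)) run_stage("decay", {
    dc <- config$decay
    digest_if_file(dc$decay); digest_if_file(dc$irf)
    decay <- if (is.character(dc$decay)) read_decay_csv(dc$decay) else dc$decay
    irf <- if (is.character(dc$irf)) read_decay_csv(dc$irf) else dc$irf
    f <- fit_decay(decay, irf,
                   n_components = if (is.null(dc$n_components)) 2L
                                  else dc$n_components,
                   fit_range = if (is.null(dc$fit_range)) "tail"
                               else dc$fit_range)
    list(lifetimes_ns = f$model$lifetimes,
         amplitudes = f$model$amplitudes,
         fractional_contributions = f$fractional_contributions,
         average_lifetime_ns = f$average_lifetime,
         reduced_chi_square = f$reduced_chi_square,
         units = list(lifetimes = "ns"))
  })

  if (!is.null(config$isotherms)) run_stage("isotherm", {
    fits <- lapply(config$isotherms, function(it) {
      digest_if_file(it)
      d <- if (is.character(it)) read_isotherm_csv(it) else it
      sd <- if ("tau_sd_ns" %in% names(d)) d$tau_sd_ns else NULL
      tc <- attr(d, "temperature_C")
      fit_isotherm(d$conc_M, d$avg_tau_ns, tau_sd = sd,
                   temperature = if (is.null(tc)) NA_real_ else tc)
    })
    lapply(fits, function(f)
      list(K_D = f$k_dim, K_D_se = f$k_dim_se,
           tau_monomer_ns = f$tau_mon, tau_monomer_se = f$tau_mon_se,
           tau_dimer_ns = f$tau_dim, tau_dimer_se = f$tau_dim_se,
           temperature_C = f$temperature,
           units = list(K_D = "L/mol", tau = "ns")))
  })
  isotherm_k <- if (!is.null(report$results$isotherm)) {
    tab <- data.frame(
      temp_C = vapply(report$results$isotherm, `[[`, numeric(1),
                      "temperature_C"),
      K = vapply(report$results$isotherm, `[[`, numeric(1), "K_D"))
    tab[!is.na(tab$temp_C), , drop = FALSE]
  } else NULL

  if (!is.null(config$vant_hoff) ||
      (!is.null(isotherm_k) && nrow(isotherm_k) >= 2))
    run_stage("vant_hoff", {
      d <- if (!is.null(config$vant_hoff)) {
        digest_if_file(config$vant_hoff)
        if (is.character(config$vant_hoff))
          read_vant_hoff_csv(config$vant_hoff) else config$vant_hoff
      } else isotherm_k
      sd <- if ("K_sd" %in% names(d)) d$K_sd else NULL
      f <- fit_vant_hoff(d$temp_C, d$K, k_sd = sd)
      list(delta_H = f$delta_h, delta_H_se = f$delta_h_se,
           delta_S = f$delta_s, delta_S_se = f$delta_s_se,
           r_squared = f$r_squared,
           units = list(delta_H = "kJ/mol", delta_S = "J/(K*mol)"))
    })

  if (!is.null(config$quench)) run_stage("quench", {
    digest_if_file(config$quench)
    d <- if (is.character(config$quench)) read_quench_csv(config$quench)
         else config$quench
    f <- fit_stern_volmer(d$q_conc_M, d$avg_tau_ns)
    list(K_SV = f$k_sv, K_SV_se = f$k_sv_se,
         tau_unquenched_ns = f$tau_unquenched,
         k_q = f$k_q, k_q_se = f$k_q_se, r_squared = f$r_squared,
         units = list(K_SV = "L/mol", k_q = "L/(mol*s)", tau = "ns"))
  })

  if (!is.null(config$titration)) run_stage("titration", {
    tc <- config$titration
    digest_if_file(tc$data)
    d <- if (is.character(tc$data)) read_titration_csv(tc$data) else tc$data
    shift_cols <- grep("^shift_ppm", names(d), value = TRUE)
    f <- fit_titration(attr(d, "host_total_M"), d$guest_total_M,
                       d[, shift_cols, drop = FALSE],
                       mode = if (is.null(tc$mode)) "monomer" else tc$mode,
                       k_dim = tc$k_dim)
    list(K_a = f$k_assoc, K_a_se = f$k_assoc_se,
         delta_max_ppm = as.list(f$delta_max),
         saturation_final = f$saturation_final,
         units = list(K_a = "L/mol", delta = "ppm"))
  })

  class(report) <- "analysis_report"
  report
}

#' Serialize / restore an analysis report as JSON
#'
#' @param report An \code{\link{run_pipeline}} result.
#' @param path Output path.
#' @export
write_report <- function(report, path) {
  stopifnot(inherits(report, "analysis_report"))
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, null = "null")
  invisible(path)
}

#' @rdname write_report
#' @export
read_report <- function(path) {
  r <- jsonlite::read_json(path, simplifyVector = TRUE,
                           simplifyDataFrame = FALSE)
  class(r) <- "analysis_report"
  r
}

#' @export
print.analysis_report <- function(x, ...) {
  cat("Analysis report (", length(x$results), "stage(s) )\n")
  for (nm in names(x$results)) cat("  stage:", nm, "- ok\n")
  for (nm in names(x$errors)) cat("  stage:", nm, "- FAILED:", x$errors[[nm]], "\n")
  invisible(x)
}
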