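# CSV dialects: plain comma-separated tables with `# key=value` metadata
# comment lines, the lowest common denominator of what CD and stopped-flow
# instruments export.

fk_io_error <- function(message, ...) fk_stop("fk_io_error", message, ...)

# Parse a dialect file into (metadata list, numeric data.frame). Malformed
# rows are reported with their 1-based file line numbers.
fk_read_table <- function(path) {
  if (!file.exists(path)) fk_io_error(sprintf("file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  is_meta <- grepl("^\\s*#", lines)
  is_blank <- !nzchar(trimws(lines))
  meta <- list()
  for (ln in lines[is_meta]) {
    kv <- strsplit(sub("^\\s*#\\s*", "", ln), "=", fixed = TRUE)[[1]]
    if (length(kv) == 2L) meta[[trimws(kv[1])]] <- trimws(kv[2])
  }
  body <- which(!is_meta & !is_blank)
  if (length(body) < 2L) fk_io_error(sprintf("%s: no data rows", path))
  header <- trimws(strsplit(lines[body[1]], ",", fixed = TRUE)[[1]])
  rows <- body[-1]
  cells <- lapply(rows, function(i) trimws(strsplit(lines[i], ",", fixed = TRUE)[[1]]))
  bad_len <- which(vapply(cells, length, integer(1)) != length(header))
  if (length(bad_len))
    fk_io_error(sprintf("%s: line %d has %d fields, expected %d",
                        path, rows[bad_len[1]], length(cells[[bad_len[1]]]),
                        length(header)))
  mat <- suppressWarnings(
    vapply(cells, function(x) as.numeric(x), numeric(length(header))))
  mat <- matrix(mat, ncol = length(header), byrow = TRUE,
                dimnames = list(NULL, header))
  bad_num <- which(apply(mat, 1, anyNA))
  if (length(bad_num))
    fk_io_error(sprintf("%s: non-numeric cell on line %d", path, rows[bad_num[1]]))
  list(meta = meta, data = as.data.frame(mat))
}

fk_meta_num <- function(meta, key, default = NA_real_) {
  if (is.null(meta[[key]])) default else as.numeric(meta[[key]])
}

#' Read and write the package's CSV dialects
#'
#' All dialects are comma-separated tables with a header row and optional
#' `# key=value` metadata comment lines. `read_curve()` expects columns
#' `perturbation,signal[,sigma]` with metadata `probe`, `mode`, `pH`,
#' `ionic_strength`, `temperature`; `read_transient()` expects
#' `time,signal` with `experiment`, `final_urea`, and for association
#' experiments either `c_N` or the pair `c_N_premix` + `mix_ratio` (e.g.
#' `1:11`), from which the post-mix concentration is computed;
#' `read_chevron()` expects `urea,k_obs[,sigma]` with `temperature`;
#' `read_salt_series()` expects either `ionic_strength,dG[,dG_sigma]`
#' (chemical source) or `ionic_strength,Tm,dHm` (thermal source), inferred
#' from the columns. The writers emit the same dialects, so
#' write-then-read round-trips values and metadata.
#'
#' @param path File path.
#' @param x The object to write.
#' @return The corresponding data container ([denaturation_curve()],
#'   [kinetic_transient()], [chevron_dataset()], [salt_series()]); writers
#'   return `path` invisibly.
#' @name foldkin_io
NULL

#' @rdname foldkin_io
#' @export
read_curve <- function(path) {
  tb <- fk_read_table(path)
  need <- c("perturbation", "signal")
  if (!all(need %in% names(tb$data)))
    fk_io_error(sprintf("%s: missing required columns %s", path,
                        paste(setdiff(need, names(tb$data)), collapse = ", ")))
  denaturation_curve(
    tb$data$perturbation, tb$data$signal,
    probe = if (is.null(tb$meta$probe)) "CD222" else tb$meta$probe,
    mode = if (is.null(tb$meta$mode)) "chemical" else tb$meta$mode,
    sigma = tb$data$sigma,
    pH = fk_meta_num(tb$meta, "pH"),
    ionic_strength = fk_meta_num(tb$meta, "ionic_strength"),
    temperature = fk_meta_num(tb$meta, "temperature"),
    label = if (is.null(tb$meta$label)) "" else tb$meta$label)
}

#' @rdname foldkin_io
#' @export
read_transient <- function(path) {
  tb <- fk_read_table(path)
  need <- c("time", "signal")
  if (!all(need %in% names(tb$data)))
    fk_io_error(sprintf("%s: missing required columns %s", path,
                        paste(setdiff(need, names(tb$data)), collapse = ", ")))
  c_N <- fk_meta_num(tb$meta, "c_N")
  if (is.na(c_N) && !is.null(tb$meta$c_N_premix)) {
    if (is.null(tb$meta$mix_ratio))
      fk_io_error(sprintf("%s: c_N_premix given without mix_ratio", path))
    c_N <- postmix_concentration(as.numeric(tb$meta$c_N_premix),
                                 tb$meta$mix_ratio)
  }
  tryCatch(
    kinetic_transient(
      tb$data$time, tb$data$signal,
      experiment = if (is.null(tb$meta$experiment)) "folding" else tb$meta$experiment,
      final_urea = fk_meta_num(tb$meta, "final_urea"),
      c_N = c_N,
      label = if (is.null(tb$meta$label)) "" else tb$meta$label),
    fk_invalid_input = function(e) {
      fk_io_error(sprintf("%s: %s", path, conditionMessage(e)))
    })
}

#' @rdname foldkin_io
#' @export
read_chevron <- function(path) {
  tb <- fk_read_table(path)
  need <- c("urea", "k_obs")
  if (!all(need %in% names(tb$data)))
    fk_io_error(sprintf("%s: missing required columns %s", path,
                        paste(setdiff(need, names(tb$data)), collapse = ", ")))
  chevron_dataset(tb$data$urea, tb$data$k_obs, sigma = tb$data$sigma,
                  temperature = fk_meta_num(tb$meta, "temperature", 298))
}

#' @rdname foldkin_io
#' @export
read_salt_series <- function(path) {
  tb <- fk_read_table(path)
  lab <- if (is.null(tb$meta$label)) "" else tb$meta$label
  if (all(c("Tm", "dHm") %in% names(tb$data))) {
    salt_series(tb$data$ionic_strength, Tm = tb$data$Tm, dHm = tb$data$dHm,
                source = "thermal", label = lab)
  } else if ("dG" %in% names(tb$data)) {
    salt_series(tb$data$ionic_strength, dG = tb$data$dG, source = "chemical",
                label = lab)
  } else {
    fk_io_error(sprintf("%s: need columns ionic_strength,dG or ionic_strength,Tm,dHm",
                        path))
  }
}

fk_write_table <- function(path, meta, data) {
  meta <- meta[!vapply(meta, function(v) is.null(v) || (is.numeric(v) && is.na(v)) ||
                         identical(v, ""), logical(1))]
  hdr <- vapply(names(meta), function(k) sprintf("# %s=%s", k, meta[[k]]),
                character(1))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  utils::write.csv(data, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname foldkin_io
#' @export
write_curve <- function(x, path) {
  stopifnot(inherits(x, "denaturation_curve"))
  d <- data.frame(perturbation = x$perturbation, signal = x$signal)
  if (!is.null(x$sigma)) d$sigma <- x$sigma
  fk_write_table(path, c(list(probe = x$probe, mode = x$mode), x$condition), d)
}

#' @rdname foldkin_io
#' @export
write_transient <- function(x, path) {
  stopifnot(inherits(x, "kinetic_transient"))
  fk_write_table(path, x$meta, data.frame(time = x$time, signal = x$signal))
}

#' @rdname foldkin_io
#' @export
write_chevron <- function(x, path) {
  stopifnot(inherits(x, "chevron_dataset"))
  d <- data.frame(urea = x$urea, k_obs = x$k_obs)
  if (!is.null(x$sigma)) d$sigma <- x$sigma
  fk_write_table(path, list(temperature = x$temperature), d)
}

#' @rdname foldkin_io
#' @export
write_salt_series <- function(x, path) {
  stopifnot(inherits(x, "salt_series"))
  d <- if (x$source == "chemical")
    data.frame(ionic_strength = x$ionic_strength, dG = x$dG)
  else
    data.frame(ionic_strength = x$ionic_strength, Tm = x$Tm, dHm = x$dHm)
  fk_write_table(path, list(label = x$label), d)
}

#' Assemble a per-homologue result report
#'
#' Collects fit results for one homologue into a single report mirroring the
#' standard result tables: equilibrium (m-value, midpoint, dG per probe),
#' thermal (T_m, dH_m), kinetics (k_f, m_f, k_u, m_u, dG, beta_T) and
#' association (k_ass, k_diss, K_d). Derived cells are computed by the
#' derivation operations from the fitted cells, never re-entered. Values are
#' stored unrounded; the print method applies the reporting convention
#' (2 decimals for dG, m-values and K_d in nM; 1 decimal for T_m and dH_m).
#'
#' @param label Homologue label.
#' @param equilibrium A `chemical_fit` or a named list of them (per probe).
#' @param thermal A `thermal_fit`.
#' @param kinetics A `chevron_fit`.
#' @param association An `association_fit`.
#' @param dissociation A `dissociation_fit`.
#' @param consistency_threshold Relative-discrepancy threshold for the
#'   equilibrium/kinetic consistency flag.
#' @return An object of class `homologue_report`; `write_report()` writes
#'   its unrounded values as JSON and returns the path invisibly.
#' @export
build_report <- function(label = "", equilibrium = NULL, thermal = NULL,
                         kinetics = NULL, association = NULL,
                         dissociation = NULL, consistency_threshold = 0.2) {
  if (is.null(equilibrium) && is.null(thermal) && is.null(kinetics) &&
      is.null(association) && is.null(dissociation))
    fk_invalid_input("build_report needs at least one fit result")
  out <- list(label = label)
  if (!is.null(equilibrium)) {
    if (inherits(equilibrium, "chemical_fit"))
      equilibrium <- list(fit = equilibrium)
    out$equilibrium <- lapply(equilibrium, function(f) {
      list(m = f$m_DN, midpoint = f$urea50, dG = f$dG_DN, dG_se = f$dG_se)
    })
  }
  if (!is.null(thermal))
    out$thermal <- list(Tm = thermal$T_m, dHm = thermal$dH_m, dCp = thermal$dCp)
  if (!is.null(kinetics))
    out$kinetics <- list(k_f = kinetics$k_f, m_f = kinetics$m_TS_D,
                         k_u = kinetics$k_u, m_u = kinetics$m_TS_N,
                         dG = kinetics$derived$dG_kin,
                         beta_T = kinetics$derived$beta_T,
                         m_sum = kinetics$derived$m_kin_sum)
  if (!is.null(association) || !is.null(dissociation)) {
    assoc <- list()
    if (!is.null(association)) {
      assoc$k_ass <- association$k_ass
      assoc$k_ass_se <- unname(association$std_errors["k_ass"])
    }
    if (!is.null(dissociation)) {
      assoc$k_diss <- dissociation$k_diss
      assoc$k_diss_se <- unname(dissociation$std_errors["k_diss"])
    }
    if (!is.null(association) && !is.null(dissociation)) {
      kd <- compute_Kd(assoc$k_diss, assoc$k_ass, assoc$k_diss_se, assoc$k_ass_se)
      assoc$K_d <- kd$K_d
      assoc$K_d_se <- kd$se
    }
    out$association <- assoc
  }
  if (!is.null(kinetics) && !is.null(out$equilibrium)) {
    cons <- consistency_report(
      list(dG = out$equilibrium[[1]]$dG, m = out$equilibrium[[1]]$m),
      list(dG = out$kinetics$dG, m_sum = out$kinetics$m_sum),
      threshold = consistency_threshold)
    out$consistency <- list(
      rel_discrepancy_dG = unname(cons$rel_discrepancy["dG"]),
      rel_discrepancy_m = unname(cons$rel_discrepancy["m"]),
      consistent = cons$consistent)
  }
  structure(out, class = "homologue_report")
}

#' @export
print.homologue_report <- function(x, ...) {
  cat(sprintf("=== %s ===\n", if (nzchar(x$label)) x$label else "homologue report"))
  for (probe in names(x$equilibrium)) {
    e <- x$equilibrium[[probe]]
    cat(sprintf("  equilibrium [%s]: m = %.2f kcal/(mol M), [urea]50 = %.2f M, dG = %.2f kcal/mol\n",
                probe, e$m, e$midpoint, e$dG))
  }
  if (!is.null(x$thermal))
    cat(sprintf("  thermal: T_m = %.1f K, dH_m = %.1f kcal/mol\n",
                x$thermal$Tm, x$thermal$dHm))
  if (!is.null(x$kinetics))
    cat(sprintf("  kinetics: k_f = %.0f 1/s, m_f = %.2f, k_u = %.2f 1/s, m_u = %.2f, dG = %.2f kcal/mol, beta_T = %.2f\n",
                x$kinetics$k_f, x$kinetics$m_f, x$kinetics$k_u, x$kinetics$m_u,
                x$kinetics$dG, x$kinetics$beta_T))
  if (!is.null(x$association)) {
    a <- x$association
    cat("  association:")
    if (!is.null(a$k_ass)) cat(sprintf(" k_ass = %.3g 1/(M s),", a$k_ass))
    if (!is.null(a$k_diss)) cat(sprintf(" k_diss = %.2f 1/s,", a$k_diss))
    if (!is.null(a$K_d)) cat(sprintf(" K_d = %.2f nM", a$K_d * 1e9))
    cat("\n")
  }
  if (!is.null(x$consistency))
    cat(sprintf("  consistency: dG %.1f%%, m %.1f%% -> %s\n",
                100 * x$consistency$rel_discrepancy_dG,
                100 * x$consistency$rel_discrepancy_m,
                if (x$consistency$consistent) "two-state consistent"
                else "NOT consistent"))
  invisible(x)
}

#' @rdname build_report
#' @param report A `homologue_report`.
#' @param path Output JSON path.
#' @export
write_report <- function(report, path) {
  stopifnot(inherits(report, "homologue_report"))
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
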