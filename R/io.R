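# All tables are comma-separated with a required header and an optional
# leading "# units: ..." comment line. Writes go through a temp file in the
# target directory followed by an atomic rename, so an interrupted run never
# leaves a half-written table.

.write_atomic <- function(path, writer) {
  tmp <- tempfile(tmpdir = dirname(path), fileext = ".tmp")
  on.exit(if (file.exists(tmp)) unlink(tmp), add = TRUE)
  writer(tmp)
  if (!file.rename(tmp, path))
    stop("could not move temporary file onto ", path, call. = FALSE)
  invisible(path)
}

.read_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  first <- readLines(path, n = 1L)
  units <- NULL
  skip <- 0L
  if (startsWith(first, "#")) {
    units <- trimws(sub("^#\\s*units:\\s*", "", first))
    skip <- 1L
  }
  df <- utils::read.csv(path, skip = skip, check.names = TRUE)
  attr(df, "units") <- units
  df
}

#' Read a time-activity-curve table
#'
#' Expects a comma-separated table with header columns `frame_start_s`,
#' `frame_end_s`, `concentration` (optional `sd`), optionally preceded by a
#' `# units: ...` comment line. Frames must be contiguous, non-overlapping
#' and of positive duration; violations are reported with the offending row
#' number.
#'
#' @param path file path.
#' @return A [tac]; the units string, if present, is attached as attribute
#'   `"units"`.
#' @export
read_tac_table <- function(path) {
  df <- .read_table(path)
  need <- c("frame_start_s", "frame_end_s", "concentration")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("missing column(s) in ", path, ": ", paste(miss, collapse = ", "),
         call. = FALSE)
  bad_dur <- which(df$frame_end_s <= df$frame_start_s)
  if (length(bad_dur))
    stop(sprintf("non-positive frame duration at row %d of %s",
                 bad_dur[1L], path), call. = FALSE)
  if (nrow(df) > 1L) {
    gap <- which(abs(df$frame_start_s[-1L] -
                       df$frame_end_s[-nrow(df)]) > 1e-9)
    if (length(gap))
      stop(sprintf("frames overlap or leave a gap at row %d of %s",
                   gap[1L] + 1L, path), call. = FALSE)
  }
  sched <- frame_schedule(df$frame_start_s, df$frame_end_s)
  out <- tac(sched, df$concentration,
             sd = if ("sd" %in% names(df)) df$sd)
  attr(out, "units") <- attr(df, "units")
  out
}

#' Write a time-activity-curve table
#'
#' @param x a [tac].
#' @param path output file path (written atomically).
#' @param units optional units string recorded as a `# units:` comment.
#' @return `path`, invisibly.
#' @export
write_tac_table <- function(x, path, units = NULL) {
  stopifnot(inherits(x, "tac"))
  df <- data.frame(frame_start_s = x$start_s, frame_end_s = x$end_s,
                   concentration = x$value)
  if ("sd" %in% names(x)) df$sd <- x$sd
  .write_atomic(path, function(tmp) {
    con <- file(tmp, "w")
    on.exit(close(con), add = TRUE)
    if (!is.null(units)) writeLines(paste("# units:", units), con)
    utils::write.csv(df, con, row.names = FALSE, quote = FALSE)
  })
}

#' Read a blood-curve table into a sampled input function
#'
#' Expects columns `time_s`, `concentration` (comma-separated, header
#' required). Times are converted to minutes; the curve becomes a sampled
#' [input_from_samples] input function.
#'
#' @param path file path.
#' @return An `input_sampled` object.
#' @export
read_blood_table <- function(path) {
  df <- .read_table(path)
  need <- c("time_s", "concentration")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("missing column(s) in ", path, ": ", paste(miss, collapse = ", "),
         call. = FALSE)
  input_from_samples(df$time_s / 60, df$concentration)
}

#' Write a blood-curve table
#'
#' @param time_s sample times (s).
#' @param concentration blood concentrations.
#' @param path output file path (written atomically).
#' @param units optional units comment.
#' @export
write_blood_table <- function(time_s, concentration, path, units = NULL) {
  df <- data.frame(time_s = time_s, concentration = concentration)
  .write_atomic(path, function(tmp) {
    con <- file(tmp, "w")
    on.exit(close(con), add = TRUE)
    if (!is.null(units)) writeLines(paste("# units:", units), con)
    utils::write.csv(df, con, row.names = FALSE, quote = FALSE)
  })
}

#' Read a cell-assay well table
#'
#' Expects columns `well`, `condition`, `membrane_counts`,
#' `internalized_counts`, `protein_mg` (optional `total_counts`).
#'
#' @param path file path.
#' @return A data.frame suitable for [internalization_summary].
#' @export
read_assay_table <- function(path) {
  df <- .read_table(path)
  need <- c("well", "condition", "membrane_counts", "internalized_counts",
            "protein_mg")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("missing column(s) in ", path, ": ", paste(miss, collapse = ", "),
         call. = FALSE)
  df
}

#' Write a synthetic dataset to a directory
#'
#' Writes each subject's tissue TAC, the shared blood curve, the noiseless
#' model curve and a plain-text manifest recording every parameter and seed,
#' sufficient to regenerate the dataset byte-for-byte with
#' [generate_dataset]. All writes are atomic.
#'
#' @param ds a [generate_dataset] result.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(ds, dir) {
  stopifnot(inherits(ds, "tac_dataset"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (i in seq_along(ds$tissue))
    write_tac_table(ds$tissue[[i]],
                    file.path(dir, sprintf("tissue_subject%02d.csv", i)),
                    units = "SUV-like concentration")
  write_tac_table(ds$truth, file.path(dir, "tissue_noiseless.csv"),
                  units = "SUV-like concentration")
  write_tac_table(ds$blood, file.path(dir, "blood_frames.csv"),
                  units = "SUV-like concentration")
  m <- ds$manifest
  flat <- unlist(m)
  .write_atomic(file.path(dir, "manifest.txt"), function(tmp) {
    writeLines(paste0(names(flat), ": ",
                      vapply(flat, format, "", digits = 17)), tmp)
  })
  invisible(dir)
}

#' Write a fit report
#'
#' Writes a two-part plain-text report for a fitted compartment model: a
#' comma-separated parameter table (estimate, standard error) followed by
#' goodness-of-fit and the derived trapping metrics as key-value lines.
#'
#' @param fit a [fit_tac] result.
#' @param path output file path (written atomically).
#' @return `path`, invisibly.
#' @export
write_fit_report <- function(fit, path) {
  stopifnot(inherits(fit, "tac_fit"))
  .write_atomic(path, function(tmp) {
    con <- file(tmp, "w")
    on.exit(close(con), add = TRUE)
    writeLines("parameter,estimate,se", con)
    writeLines(sprintf("%s,%.10g,%.6g", names(fit$par), fit$par, fit$se), con)
    writeLines(c("",
      sprintf("# model: %s", fit$model),
      sprintf("# n_frames: %d", fit$n_frames),
      sprintf("# weights: %s", fit$weight_rule),
      sprintf("# wrss: %.10g", fit$wrss),
      sprintf("# aicc: %.10g", fit$aicc),
      sprintf("# converged: %s", fit$converged),
      sprintf("# degenerate: %s", fit$degenerate)), con)
    if (fit$converged) {
      dm <- derived_metrics(fit$estimates)
      writeLines(c(
        sprintf("# delivery_ratio: %.10g", dm$delivery_ratio),
        sprintf("# binding_fraction: %.10g", dm$binding_fraction),
        sprintf("# retention_ratio: %.10g", dm$retention_ratio),
        sprintf("# vt: %.10g", dm$vt)), con)
    }
  })
}
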