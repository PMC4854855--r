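#' Standardized uptake value
#'
#' \deqn{SUV = \frac{\textrm{activity per mL tissue}}
#'   {\textrm{injected activity} / \textrm{body weight}}}
#' with the conventional small-animal units: tissue concentration in kBq/mL,
#' injected dose in MBq, body weight in g. The result carries units of g/mL
#' but is conventionally reported unitless.
#'
#' @param activity_conc tissue activity concentration (kBq/mL), `>= 0`.
#' @param injected_mbq injected activity (MBq), `> 0`.
#' @param body_weight_g body weight (g), `> 0`.
#' @param tissue,time_min optional labels stored on the result.
#' @return An object of class `suv` (numeric, with labels).
#' @examples
#' suv(100, injected_mbq = 5, body_weight_g = 20)  # 0.4
#' @export
suv <- function(activity_conc, injected_mbq, body_weight_g,
                tissue = NA_character_, time_min = NA_real_) {
  if (injected_mbq <= 0 || body_weight_g <= 0)
    stop("injected activity and body weight must be positive", call. = FALSE)
  if (any(activity_conc < 0))
    stop("activity concentration must be nonnegative", call. = FALSE)
  v <- activity_conc / (injected_mbq * 1000 / body_weight_g)  # MBq -> kBq
  structure(v, class = "suv", tissue = tissue, time_min = time_min)
}

#' @export
print.suv <- function(x, digits = 3, ...) {
  lab <- attr(x, "tissue"); tm <- attr(x, "time_min")
  cat(sprintf("SUV%s%s = %s\n",
              if (!is.na(tm)) sprintf("_%gmin", tm) else "",
              if (!is.na(lab)) paste0(" (", lab, ")") else "",
              paste(signif(unclass(x), digits), collapse = ", ")))
  invisible(x)
}

#' Tumor-to-reference uptake ratio
#'
#' @param suv_tumor tumor SUV (or any uptake measure), `>= 0`.
#' @param suv_ref reference-tissue SUV (blood, muscle), `> 0`.
#' @return The exact quotient, at full precision.
#' @examples
#' tumor_to_reference(1.1, 0.1)  # 11
#' @export
tumor_to_reference <- function(suv_tumor, suv_ref) {
  if (any(suv_ref <= 0))
    stop("reference uptake must be positive", call. = FALSE)
  as.numeric(suv_tumor) / as.numeric(suv_ref)
}

#' Percent uptake reduction under receptor blocking
#'
#' @param suv_control uptake without blocking, `> 0`.
#' @param suv_blocked uptake after pre-dosing with the cold compound.
#' @return `100 * (control - blocked) / control`, in percent.
#' @examples
#' blocking_reduction(1.1, 0.22)  # 80
#' @export
blocking_reduction <- function(suv_control, suv_blocked) {
  if (any(suv_control <= 0))
    stop("control uptake must be positive", call. = FALSE)
  100 * (as.numeric(suv_control) - as.numeric(suv_blocked)) /
    as.numeric(suv_control)
}

#' Internalized fraction of cell-associated radioactivity
#'
#' Fraction of total cell-associated activity that is inside the cell (as
#' opposed to membrane-bound), in percent. Full precision is returned;
#' rounding to integer percent is a reporting choice, not part of the math.
#'
#' @param membrane membrane-bound uptake (any common unit, e.g. \% of total
#'   uptake per mg protein).
#' @param internalized internalized uptake, same unit.
#' @return `100 * internalized / (membrane + internalized)`.
#' @examples
#' internalized_fraction(45.47, 35.05)  # 43.53... -> reported as 44%
#' @export
internalized_fraction <- function(membrane, internalized) {
  tot <- membrane + internalized
  if (any(tot <= 0)) stop("total uptake must be positive", call. = FALSE)
  if (any(membrane < 0) || any(internalized < 0))
    stop("uptake values must be nonnegative", call. = FALSE)
  100 * internalized / tot
}

#' Uptake normalized as percent of total per mg protein
#'
#' The standard cell-assay normalization: counts in a fraction
#' (membrane-bound or internalized) as a percentage of total added
#' activity, per mg of total cell protein in the well.
#'
#' @param fraction_counts counts in the fraction of interest.
#' @param total_counts total counts added to the well, `> 0`.
#' @param protein_mg total protein in the well (mg), `> 0`.
#' @return `100 * (fraction_counts / total_counts) / protein_mg`, in
#'   \% of total uptake / mg protein.
#' @export
percent_of_total_per_mg <- function(fraction_counts, total_counts, protein_mg) {
  if (any(total_counts <= 0) || any(protein_mg <= 0))
    stop("total counts and protein mass must be positive", call. = FALSE)
  if (any(fraction_counts < 0))
    stop("fraction counts must be nonnegative", call. = FALSE)
  100 * (fraction_counts / total_counts) / protein_mg
}

#' Unpaired two-sample t test from summary statistics
#'
#' Recomputes the unpaired Student's t test from published group summaries
#' (mean, SEM, n) rather than raw values. Group standard deviations are
#' recovered as `s_i = sem_i * sqrt(n_i)`. The pooled variant uses the
#' pooled variance with `df = n1 + n2 - 2`; the Welch variant uses the
#' Satterthwaite approximation.
#'
#' @param mean1,sem1,n1 summary statistics of group 1 (`n1 >= 2`,
#'   `sem1 > 0`).
#' @param mean2,sem2,n2 summary statistics of group 2.
#' @param variant `"pooled"` (classical Student) or `"welch"`.
#' @return A list with `t`, `df`, `p` (two-sided), `variant`.
#' @examples
#' unpaired_t_from_summary(1.1, 0.1, 5, 0.2, 0.05, 4)
#' @export
unpaired_t_from_summary <- function(mean1, sem1, n1, mean2, sem2, n2,
                                    variant = c("pooled", "welch")) {
  variant <- match.arg(variant)
  if (n1 < 2 || n2 < 2) stop("both groups need n >= 2", call. = FALSE)
  if (sem1 <= 0 || sem2 <= 0) stop("SEMs must be positive", call. = FALSE)
  v1 <- (sem1 * sqrt(n1))^2
  v2 <- (sem2 * sqrt(n2))^2
  if (variant == "pooled") {
    sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
    tstat <- (mean1 - mean2) / sqrt(sp2 * (1 / n1 + 1 / n2))
    df <- n1 + n2 - 2
  } else {
    se2 <- v1 / n1 + v2 / n2
    tstat <- (mean1 - mean2) / sqrt(se2)
    df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  }
  list(t = tstat, df = df,
       p = 2 * stats::pt(abs(tstat), df, lower.tail = FALSE),
       variant = variant)
}

#' Summarize an internalization assay table
#'
#' Aggregates a per-well assay table into per-condition means and SEMs of
#' membrane-bound and internalized uptake (normalized per mg protein) and
#' the internalized fraction of cell-associated activity.
#'
#' @param wells a data.frame with columns `well`, `condition`,
#'   `membrane_counts`, `internalized_counts`, `protein_mg`, and either a
#'   `total_counts` column or a single `total_counts` argument.
#' @param total_counts total activity added per well, used when the table
#'   has no `total_counts` column.
#' @return A data.frame, one row per condition: mean and SEM of
#'   membrane-bound and internalized \% of total uptake/mg protein, and the
#'   internalized fraction (percent, full precision plus integer-rounded
#'   report column).
#' @export
internalization_summary <- function(wells, total_counts = NULL) {
  need <- c("well", "condition", "membrane_counts", "internalized_counts",
            "protein_mg")
  if (!all(need %in% names(wells)))
    stop("assay table must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  tot <- if ("total_counts" %in% names(wells)) wells$total_counts
         else if (!is.null(total_counts)) total_counts
         else stop("total_counts column or argument required", call. = FALSE)
  memb <- percent_of_total_per_mg(wells$membrane_counts, tot, wells$protein_mg)
  int <- percent_of_total_per_mg(wells$internalized_counts, tot, wells$protein_mg)
  sem <- function(v) stats::sd(v) / sqrt(length(v))
  out <- do.call(rbind, lapply(split(seq_len(nrow(wells)), wells$condition),
    function(idx) {
      m <- memb[idx]; i <- int[idx]
      frac <- internalized_fraction(mean(m), mean(i))
      data.frame(condition = wells$condition[idx][1L],
                 n = length(idx),
                 membrane_mean = mean(m), membrane_sem = sem(m),
                 internalized_mean = mean(i), internalized_sem = sem(i),
                 internalized_fraction = frac,
                 internalized_fraction_report = round(frac))
    }))
  rownames(out) <- NULL
  out
}
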