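#' Net luminescence of dual-luciferase readings
#'
#' The Renilla channel is treated as background and subtracted from the
#' firefly channel.  Negative results (background exceeding signal) are
#' returned, not clipped, and flagged.
#'
#' @param readings Data frame with columns `firefly_rlu` and `renilla_rlu`
#'   (and any id columns, preserved).
#' @return The data frame with `net_rlu` and logical
#'   `background_exceeds_signal` columns appended.
#' @export
net_luminescence <- function(readings) {
  df <- as.data.frame(readings)
  if (!all(c("firefly_rlu", "renilla_rlu") %in% names(df)))
    stop(errorCondition("need firefly_rlu and renilla_rlu columns",
                        class = c("erg_missing_column", "error", "condition")))
  if (any(df$firefly_rlu < 0) || any(df$renilla_rlu < 0))
    stop("channel readings must be >= 0")
  df$net_rlu <- df$firefly_rlu - df$renilla_rlu
  df$background_exceeds_signal <- df$net_rlu < 0
  df
}

#' Fold induction of reporter activity over vehicle
#'
#' Mean net luminescence of the treated group divided by the mean of the
#' vehicle group.  Scale-invariant to the RLU unit.
#'
#' @param treated_nets,vehicle_nets Numeric vectors of net (background-
#'   subtracted) luminescence.
#' @return Fold induction (scalar).
#' @export
fold_induction <- function(treated_nets, vehicle_nets) {
  vm <- mean(vehicle_nets)
  if (!is.finite(vm) || vm <= 0)
    stop(errorCondition(
      "vehicle-normalization failure: vehicle mean is zero or negative",
      class = c("erg_bad_normalizer", "error", "condition")))
  mean(treated_nets) / vm
}

#' Relative qPCR expression by the 2^-ddCt method
#'
#' Technical Ct replicates are averaged per (sample, gene) first; per
#' sample, dCt = Ct_target - Ct_reference; ddCt is taken against the mean
#' dCt of the control group, and fold change is 2^(-ddCt) (amplification
#' efficiency fixed at 2).  Groups are compared by dCt with an unpaired
#' Student's t-test.  Fold changes are invariant to a constant added to
#' every Ct.
#'
#' @param records Long data frame with columns `sample_id`, `group`,
#'   `gene`, `ct` (one row per technical replicate).
#' @param target_gene,ref_gene Gene labels; the reference (e.g. GAPDH or
#'   L32) must be present for every sample.
#' @param control_group Group used as the calibrator.
#' @return List with `samples` (per sample: group, dct, ddct, fold),
#'   `groups` (per group: mean fold, n), and `test` (unpaired t on dCt,
#'   `NULL` when there is only one group).
#' @export
qpcr_relative_expression <- function(records, target_gene, ref_gene,
                                     control_group) {
  df <- as.data.frame(records)
  need <- c("sample_id", "group", "gene", "ct")
  if (!all(need %in% names(df)))
    stop(errorCondition("need sample_id, group, gene, ct columns",
                        class = c("erg_missing_column", "error", "condition")))
  if (any(df$ct <= 0)) stop("Ct values must be positive")
  df <- df[df$gene %in% c(target_gene, ref_gene), ]
  agg <- stats::aggregate(ct ~ sample_id + group + gene, data = df,
                          FUN = mean)
  tgt <- agg[agg$gene == target_gene, ]
  ref <- agg[agg$gene == ref_gene, ]
  if (nrow(tgt) == 0) stop("target gene absent")
  i <- match(tgt$sample_id, ref$sample_id)
  if (anyNA(i))
    stop(errorCondition(
      paste0("reference gene ", ref_gene, " missing for sample(s): ",
             paste(tgt$sample_id[is.na(i)], collapse = ", ")),
      class = c("erg_missing_reference", "error", "condition")))
  samples <- data.frame(sample_id = tgt$sample_id, group = tgt$group,
                        dct = tgt$ct - ref$ct[i], stringsAsFactors = FALSE)
  if (!control_group %in% samples$group) stop("control group absent")
  cal <- mean(samples$dct[samples$group == control_group])
  samples$ddct <- samples$dct - cal
  samples$fold <- 2^(-samples$ddct)
  groups <- do.call(rbind, lapply(split(samples, samples$group), function(d)
    data.frame(group = d$group[1], mean_fold = mean(d$fold),
               n = nrow(d), stringsAsFactors = FALSE)))
  rownames(groups) <- NULL
  grp <- unique(samples$group)
  test <- NULL
  other <- setdiff(grp, control_group)
  if (length(other) == 1) {
    a <- samples$dct[samples$group == other]
    b <- samples$dct[samples$group == control_group]
    if (length(a) >= 2 && length(b) >= 2) test <- unpaired_t(a, b)
  }
  list(samples = samples, groups = groups, test = test)
}

#' Fit a standard curve
#'
#' Ordinary least-squares line mapping absorbance to concentration.
#'
#' @param concentration,absorbance Numeric vectors (>= 2 distinct
#'   concentrations).
#' @return List of class `standard_curve` with `slope`, `intercept` (for
#'   concentration = intercept + slope * absorbance) and the input range.
#' @export
standard_curve_fit <- function(concentration, absorbance) {
  if (length(concentration) < 2 || length(unique(concentration)) < 2)
    stop(errorCondition("need >= 2 distinct standard concentrations",
                        class = c("erg_bad_standards", "error", "condition")))
  if (length(unique(absorbance)) < 2)
    stop(errorCondition("standards have identical absorbances",
                        class = c("erg_bad_standards", "error", "condition")))
  fit <- stats::lm(concentration ~ absorbance)
  structure(list(slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 absorbance_range = range(absorbance)),
            class = "standard_curve")
}

#' Quantify samples against a standard curve, normalized to tissue mass
#'
#' Converts absorbance readings to concentration with the fitted line and
#' divides by tissue mass.  Readings outside the standards' absorbance
#' range are extrapolated with a warning and flagged.
#'
#' @param curve A `standard_curve` from [standard_curve_fit()], or a data
#'   frame with `concentration` and `absorbance` columns to fit on the fly.
#' @param absorbances Numeric sample readings.
#' @param tissue_mass_g Tissue mass (g); scalar or one per sample.
#' @return Data frame with `absorbance`, `concentration`,
#'   `concentration_per_g`, `extrapolated`.
#' @export
standard_curve_quantify <- function(curve, absorbances, tissue_mass_g = 1) {
  if (is.data.frame(curve))
    curve <- standard_curve_fit(curve$concentration, curve$absorbance)
  if (any(tissue_mass_g <= 0)) stop("tissue mass must be positive")
  conc <- curve$intercept + curve$slope * absorbances
  extra <- absorbances < curve$absorbance_range[1] |
    absorbances > curve$absorbance_range[2]
  if (any(extra))
    warning(sprintf("%d reading(s) outside the standard range: extrapolated",
                    sum(extra)))
  data.frame(absorbance = absorbances, concentration = conc,
             concentration_per_g = conc / tissue_mass_g,
             extrapolated = extra)
}
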