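# Per-CpG scanning pipeline: probe filtering, covariate residualization,
# site-wise joint testing with BH discovery, and two-cohort validation
# accounting with direction-consistency checks.

#' Read a beta-value (or detection p-value) matrix from delimited text
#'
#' Expects sites in rows and samples in columns: first column the probe
#' id, header row the sample ids, tab- or comma-delimited (sniffed from
#' the header line).  Missing values may be empty or `NA`.
#'
#' @param file path to a TSV/CSV file.
#' @return numeric matrix with site ids as row names and sample ids as
#'   column names.
#' @export
read_beta_matrix <- function(file) {
  header <- readLines(file, n = 1L)
  sep <- if (grepl("\t", header)) "\t" else ","
  d <- read.table(file, header = TRUE, sep = sep, row.names = 1L,
                  check.names = FALSE, na.strings = c("", "NA"))
  m <- as.matrix(d)
  storage.mode(m) <- "double"
  if (anyDuplicated(rownames(m))) stop_invalid("duplicate site ids")
  if (anyDuplicated(colnames(m))) stop_invalid("duplicate sample ids")
  m
}

#' Read a phenotype table from delimited text
#'
#' First column sample id, a `group` column coded 0 (control) / 1 (case),
#' and any further numeric covariate columns (age, cell-type proportions,
#' ...).
#'
#' @param file path to a TSV/CSV file.
#' @return data frame with row names = sample ids and a `group` column.
#' @export
read_phenotypes <- function(file) {
  header <- readLines(file, n = 1L)
  sep <- if (grepl("\t", header)) "\t" else ","
  d <- read.table(file, header = TRUE, sep = sep, row.names = 1L,
                  check.names = FALSE)
  if (!"group" %in% names(d))
    stop_invalid("phenotype table must contain a 'group' column")
  d
}

#' Filter CpG sites of a beta-value matrix
#'
#' Applies, in order: removal of sites with any missing value; removal of
#' sites whose probe id starts with one of `drop_prefixes` (non-CpG "ch"
#' probes on Illumina arrays); removal of sites with any detection p-value
#' greater than *or equal to* `detection_p_max` (the boundary is
#' inclusive).  The number of sites removed by each rule is reported via
#' `message()`.
#'
#' @param beta numeric matrix, sites x samples, row names = probe ids.
#' @param drop_missing drop sites with at least one missing value.
#' @param drop_prefixes character vector of probe-id prefixes to drop;
#'   `character(0)` disables the rule.
#' @param detection_p optional matrix of detection p-values aligned with
#'   `beta`.
#' @param detection_p_max threshold for the detection rule, or `NULL` to
#'   disable.
#' @return the filtered matrix.
#' @export
filter_sites <- function(beta, drop_missing = TRUE,
                         drop_prefixes = "ch", detection_p = NULL,
                         detection_p_max = NULL) {
  stopifnot(is.matrix(beta), !is.null(rownames(beta)))
  if (!is.null(detection_p_max) && is.null(detection_p))
    stop_invalid("detection_p_max given but no detection_p matrix")
  keep <- rep(TRUE, nrow(beta))
  if (drop_missing) {
    ok <- complete.cases(beta)
    message(sum(keep & !ok), " site(s) removed: missing values")
    keep <- keep & ok
  }
  if (length(drop_prefixes)) {
    pat <- paste0("^(", paste(drop_prefixes, collapse = "|"), ")")
    hit <- grepl(pat, rownames(beta))
    message(sum(keep & hit), " site(s) removed: probe-name prefix")
    keep <- keep & !hit
  }
  if (!is.null(detection_p_max)) {
    if (!identical(dim(detection_p), dim(beta)))
      stop_invalid("detection_p must have the same dimensions as beta")
    bad <- apply(detection_p, 1L, function(p)
      any(!is.na(p) & p >= detection_p_max))
    message(sum(keep & bad), " site(s) removed: detection p-value")
    keep <- keep & !bad
  }
  beta[keep, , drop = FALSE]
}

#' Regress covariates out of a beta-value matrix
#'
#' Replaces each site's values by the ordinary-least-squares residuals of
#' the regression of beta on the named covariates (intercept included).
#' The group label is deliberately not part of the design: the joint tests
#' are applied to the residuals afterwards.  Residualized values may leave
#' the `[0, 1]` beta range.
#'
#' @param beta numeric matrix, sites x samples.
#' @param phenotypes data frame with row names = sample ids, aligned with
#'   (or alignable to) the columns of `beta`.
#' @param covariates character vector of column names in `phenotypes`.
#' @return matrix of residuals, same shape as `beta`.
#' @export
residualize <- function(beta, phenotypes, covariates) {
  stopifnot(is.matrix(beta))
  miss <- setdiff(covariates, names(phenotypes))
  if (length(miss))
    stop_invalid("covariate(s) not in phenotype table: ",
                 paste(miss, collapse = ", "))
  ph <- phenotypes[colnames(beta), covariates, drop = FALSE]
  if (anyNA(ph)) stop_invalid("missing covariate values")
  X <- model.matrix(~ ., data = ph)
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    dropped <- colnames(X)[qx$pivot[(qx$rank + 1L):ncol(X)]]
    stop_invalid("design matrix is rank deficient; collinear column(s): ",
                 paste(dropped, collapse = ", "))
  }
  res <- t(qr.resid(qx, t(beta)))
  dimnames(res) <- dimnames(beta)
  res
}

#' Median and dispersion direction summary of a two-group sample
#'
#' Directions used by the validation step: `median_diff` is
#' `median(cases) - median(controls)`; `mad_diff` is the difference of
#' mean absolute deviations, case minus control, each deviation taken
#' about its group's median (default, the robust reading) or mean.
#'
#' @inheritParams joint_score_test
#' @param mad_center center the absolute deviations about the group
#'   `"median"` (default) or `"mean"`.
#' @return named numeric vector `c(median_diff, mad_diff)`.
#' @export
direction_summary <- function(x, group, mad_center = c("median", "mean")) {
  mad_center <- match.arg(mad_center)
  s <- check_two_group(x, group, min_per_group = 1L)
  x0 <- s$x[s$y == 0L]; x1 <- s$x[s$y == 1L]
  ctr <- if (mad_center == "median") median else mean
  c(median_diff = median(x1) - median(x0),
    mad_diff = mean(abs(x1 - ctr(x1))) - mean(abs(x0 - ctr(x0))))
}

#' Site-by-site joint testing of a methylation matrix
#'
#' Applies one of the six joint tests to every row of a (possibly
#' residualized) beta-value matrix, flags degenerate sites, adjusts the
#' p-values of the non-degenerate sites by Benjamini-Hochberg, and
#' records the direction summaries computed from the values actually
#' tested.  Degenerate sites are excluded from the BH input (this changes
#' the number of tests m, so their count is reported via `message()`).
#'
#' @param beta numeric matrix, sites x samples.
#' @param group binary labels aligned with the columns of `beta`, or a
#'   phenotype data frame with a `group` column (aligned by sample id).
#' @param test test name (see [joint_tests()]).
#' @param trim trimming proportion for iAW.TM.
#' @param mad_center passed to [direction_summary()].
#' @return a data frame (one row per site) with columns `site_id`,
#'   `statistic`, `p_value`, `fdr_adjusted_p`, `median_diff`, `mad_diff`
#'   and `status` (`"ok"` or `"degenerate"`).
#' @export
methyl_scan <- function(beta, group, test = "iAW.BF", trim = 0.25,
                        mad_center = c("median", "mean")) {
  stopifnot(is.matrix(beta))
  mad_center <- match.arg(mad_center)
  if (is.data.frame(group)) {
    common <- intersect(colnames(beta), rownames(group))
    if (length(common) == 0L)
      stop_invalid("no sample ids shared between matrix and phenotypes")
    dropped <- setdiff(colnames(beta), common)
    if (length(dropped))
      message(length(dropped), " sample(s) in the matrix without ",
              "phenotype dropped")
    beta <- beta[, common, drop = FALSE]
    group <- group[common, "group"]
  }
  if (ncol(beta) != length(group))
    stop_invalid("group labels do not align with matrix columns")
  n <- nrow(beta)
  out <- data.frame(site_id = rownames(beta),
                    statistic = NA_real_, p_value = NA_real_,
                    fdr_adjusted_p = NA_real_,
                    median_diff = NA_real_, mad_diff = NA_real_,
                    status = "ok", stringsAsFactors = FALSE)
  for (i in seq_len(n)) {
    x <- beta[i, ]
    res <- tryCatch(run_joint_test(x, group, test, trim = trim),
                    jointDV_degenerate = function(e) NULL,
                    jointDV_invalid_input = function(e) NULL)
    if (is.null(res)) {
      out$status[i] <- "degenerate"
    } else {
      out$statistic[i] <- unname(res$statistic)
      out$p_value[i] <- res$p.value
    }
    dirn <- direction_summary(x, group, mad_center)
    out$median_diff[i] <- dirn[["median_diff"]]
    out$mad_diff[i] <- dirn[["mad_diff"]]
  }
  ok <- out$status == "ok"
  out$fdr_adjusted_p[ok] <- p.adjust(out$p_value[ok], method = "BH")
  if (any(!ok))
    message(sum(!ok), " degenerate site(s) excluded from the BH ",
            "adjustment (m = ", sum(ok), ")")
  attr(out, "test") <- test
  attr(out, "mad_center") <- mad_center
  out
}

#' Discovery/validation accounting across two cohorts
#'
#' Counts, for one test, the discovery-cohort sites significant at the
#' FDR threshold (`nSig`), those among them with validation-cohort
#' unadjusted p-value below `validation_p` (`nValidation`), and splits the
#' validated sites into truly validated (`nTV`: the sign of the median
#' difference agrees between cohorts AND the sign of the mean-absolute-
#' deviation difference agrees) and falsely validated (`nFV`).  A zero
#' direction difference in either cohort counts as inconsistent.
#' `pTV`/`pFV` are percentages of `nValidation` (`NA` when no site
#' validates).  Sites degenerate in either cohort never validate.
#'
#' @param discovery,validation scan result data frames from
#'   [methyl_scan()] on the two cohorts, sharing site ids.
#' @param fdr_threshold FDR cutoff for discovery significance.
#' @param validation_p unadjusted p-value cutoff in the validation cohort.
#' @param direction `"both"` (default) requires both the mean-direction
#'   and the variability-direction signs to agree; `"either"` requires at
#'   least one.
#' @return an object of class `"validation_summary"`: a one-row data
#'   frame with columns `nSig`, `nValidation`, `nTV`, `pTV`, `nFV`, `pFV`.
#' @export
discovery_validation <- function(discovery, validation,
                                 fdr_threshold = 0.05,
                                 validation_p = 0.05,
                                 direction = c("both", "either")) {
  direction <- match.arg(direction)
  shared <- intersect(discovery$site_id, validation$site_id)
  if (length(shared) == 0L)
    stop_invalid("discovery and validation share no site ids")
  sig <- discovery$status == "ok" &
    !is.na(discovery$fdr_adjusted_p) &
    discovery$fdr_adjusted_p < fdr_threshold
  nSig <- sum(sig)
  sig_ids <- discovery$site_id[sig]
  vi <- match(sig_ids, validation$site_id)
  present <- !is.na(vi)
  val_ok <- present & validation$status[vi] == "ok" &
    !is.na(validation$p_value[vi]) &
    validation$p_value[vi] < validation_p
  nValidation <- sum(val_ok)
  di <- match(sig_ids, discovery$site_id)
  same_sign <- function(a, b) sign(a) != 0 & sign(a) == sign(b)
  med_ok <- same_sign(discovery$median_diff[di], validation$median_diff[vi])
  mad_ok <- same_sign(discovery$mad_diff[di], validation$mad_diff[vi])
  consistent <- if (direction == "both") med_ok & mad_ok else med_ok | mad_ok
  nTV <- sum(val_ok & consistent, na.rm = TRUE)
  nFV <- nValidation - nTV
  out <- data.frame(nSig = nSig, nValidation = nValidation, nTV = nTV,
                    pTV = if (nValidation > 0) 100 * nTV / nValidation
                          else NA_real_,
                    nFV = nFV,
                    pFV = if (nValidation > 0) 100 * nFV / nValidation
                          else NA_real_)
  class(out) <- c("validation_summary", "data.frame")
  out
}

#' Stratified half-split of a cohort
#'
#' Randomly assigns samples to a training and a validation half,
#' stratified by group so that cases and controls are split as evenly as
#' their counts allow (the larger half of an odd group goes to training).
#' A seed is mandatory: the split must be reproducible.
#'
#' @param group binary labels (0/1) for all samples.
#' @param seed integer RNG seed.
#' @return list with integer index vectors `training` and `validation`.
#' @export
split_cohort <- function(group, seed) {
  if (missing(seed) || is.null(seed))
    stop_invalid("a seed is required for a reproducible split")
  s <- check_two_group(seq_along(group), group)
  set.seed(seed)
  training <- integer(0)
  for (g in c(0L, 1L)) {
    idx <- which(s$y == g)
    n_train <- ceiling(length(idx) / 2)
    training <- c(training, sample(idx, n_train))
  }
  training <- sort(training)
  list(training = training,
       validation = setdiff(seq_along(group), training))
}
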