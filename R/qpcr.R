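#' Synthetic qPCR time-course generator
#'
#' Converts per-gene fold-change profiles into Cq values via the primer
#' efficiencies (\eqn{Cq = Cq_{base} - \log_E fold}) and adds Gaussian Cq
#' noise, emulating an induction experiment read out by quantitative PCR.
#' The reference gene is flat by construction (fold 1 at every timepoint).
#'
#' @param config List with elements:
#'   \describe{
#'     \item{timepoints}{numeric vector of timepoint labels (e.g. minutes)}
#'     \item{genes}{named list; per gene a list with `fold` (vector over
#'       timepoints), `efficiency` (in (1, 2]), `base_cq` (Cq at fold 1)}
#'     \item{reference_gene}{name of the reference gene (must be in `genes`
#'       and flat)}
#'     \item{replicates}{biological replicates per timepoint (default 3)}
#'     \item{noise_sd}{Gaussian Cq noise SD in cycles (default 0.1)}
#'   }
#' @param seed Integer seed.
#' @return Data frame with columns `sample_id`, `timepoint`, `replicate`,
#'   `gene`, `Cq`, `efficiency` — the input to [relative_expression()].
#' @export
generate_qpcr_timecourse <- function(config, seed = 1) {
  set.seed(seed)
  tp <- config$timepoints
  genes <- config$genes
  reps <- if (is.null(config$replicates)) 3L else config$replicates
  noise <- if (is.null(config$noise_sd)) 0.1 else config$noise_sd
  ref <- config$reference_gene
  if (!ref %in% names(genes)) stop("reference gene missing from genes")
  if (any(abs(genes[[ref]]$fold - 1) > 1e-12))
    stop("reference gene profile must be flat (fold 1)")
  rows <- list()
  for (g in names(genes)) {
    eff <- genes[[g]]$efficiency
    if (eff <= 1 || eff > 2) stop("efficiency must be in (1, 2]")
    fold <- genes[[g]]$fold
    if (length(fold) != length(tp)) stop("fold profile length mismatch")
    for (i in seq_along(tp)) {
      for (r in seq_len(reps)) {
        cq <- genes[[g]]$base_cq - log(fold[i]) / log(eff) +
          if (noise > 0) stats::rnorm(1L, 0, noise) else 0
        rows[[length(rows) + 1L]] <- data.frame(
          sample_id = sprintf("t%g_r%d", tp[i], r),
          timepoint = tp[i], replicate = r, gene = g, Cq = cq,
          efficiency = eff, stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, c(rows, make.row.names = FALSE))
}

#' Packaged induction-panel configuration
#'
#' Fold-change profiles emulating the acute response of liver clock genes to
#' a resetting treatment applied at 180 degrees: transient Per1 induction
#' peaking at 60 min and returning toward baseline by 120 min, sustained Per2
#' induction that stays elevated at 120 min, flat Bmal1, and a flat Actb
#' reference.
#'
#' @param noise_sd Cq noise SD in cycles. Default 0.1.
#' @param replicates Biological replicates per timepoint. Default 3.
#' @return A config list for [generate_qpcr_timecourse()].
#' @export
qpcr_induction_config <- function(noise_sd = 0.1, replicates = 3) {
  list(
    timepoints = c(0, 30, 60, 120),
    genes = list(
      Per1 = list(fold = c(1, 2.5, 4, 1.2), efficiency = 2, base_cq = 26),
      Per2 = list(fold = c(1, 2, 3.5, 3.2), efficiency = 2, base_cq = 25),
      Bmal1 = list(fold = c(1, 1, 1, 1), efficiency = 2, base_cq = 24),
      Actb = list(fold = c(1, 1, 1, 1), efficiency = 2, base_cq = 18)),
    reference_gene = "Actb",
    replicates = replicates, noise_sd = noise_sd)
}

#' Efficiency-corrected relative expression (modified ddCt)
#'
#' Relative quantity of a target gene against a reference gene, each with its
#' own primer efficiency, calibrated to a chosen sample or group:
#' \deqn{ratio = \frac{E_{target}^{Cq_{cal,target} - Cq_{sample,target}}}
#'              {E_{ref}^{Cq_{cal,ref} - Cq_{sample,ref}}}}
#' Technical replicates (identical `sample_id` x gene) are collapsed by mean
#' Cq before the ratios are formed. With both efficiencies equal to 2 this is
#' the classic 2^-ddCt.
#'
#' @param records Data frame with columns `sample_id`, `gene`, `Cq`,
#'   `efficiency`, and optionally grouping columns (e.g. `timepoint`).
#' @param target_gene,reference_gene Gene labels present in `records`.
#' @param calibrator Either a `sample_id` or, if `calibrator_by` is given, a
#'   value of that column; the calibrator Cq is the mean over the matching
#'   samples.
#' @param calibrator_by Optional column name by which `calibrator` selects
#'   samples (e.g. `"timepoint"`).
#' @return Data frame with one row per sample: `sample_id`, any grouping
#'   columns, `relative_expression`. The calibrator sample(s) map to 1 (up to
#'   noise).
#' @export
relative_expression <- function(records, target_gene, reference_gene,
                                calibrator, calibrator_by = NULL) {
  stopifnot(all(c("sample_id", "gene", "Cq", "efficiency") %in% names(records)))
  if (any(records$efficiency <= 1 | records$efficiency > 2))
    stop("efficiency must be in (1, 2]")
  if (any(records$Cq <= 0 | records$Cq >= 45))
    stop("Cq values must lie in (0, 45)")
  collapse <- function(gene) {
    sub <- records[records$gene == gene, , drop = FALSE]
    if (nrow(sub) == 0L) stop("gene '", gene, "' missing from records")
    agg <- stats::aggregate(Cq ~ sample_id, data = sub, FUN = mean)
    eff <- sub$efficiency[1L]
    extra <- setdiff(names(sub), c("gene", "Cq", "efficiency", "replicate"))
    meta <- unique(sub[, extra, drop = FALSE])
    list(cq = stats::setNames(agg$Cq, agg$sample_id), eff = eff, meta = meta)
  }
  tg <- collapse(target_gene)
  rf <- collapse(reference_gene)
  ids <- intersect(names(tg$cq), names(rf$cq))
  if (length(ids) == 0L) stop("no samples carry both target and reference")
  cal_ids <- if (is.null(calibrator_by)) {
    as.character(calibrator)
  } else {
    unique(records$sample_id[records[[calibrator_by]] == calibrator])
  }
  cal_ids <- intersect(cal_ids, ids)
  if (length(cal_ids) == 0L) stop("calibrator matches no sample")
  cal_t <- mean(tg$cq[cal_ids])
  cal_r <- mean(rf$cq[cal_ids])
  ratio <- tg$eff^(cal_t - tg$cq[ids]) / rf$eff^(cal_r - rf$cq[ids])
  out <- data.frame(sample_id = ids, relative_expression = as.numeric(ratio),
                    stringsAsFactors = FALSE)
  merge(tg$meta, out, by = "sample_id", sort = FALSE)
}

#' Normalize an expression profile
#'
#' Two conventions for presenting relative-expression profiles: circadian
#' profiles are normalized against the average over all timepoints
#' (`"circadian_mean"`; the normalized profile means to 1), induction
#' analyses against the untreated 0-min group (`"untreated_zero"`).
#'
#' @param values Numeric vector of relative quantities.
#' @param mode `"circadian_mean"` or `"untreated_zero"`.
#' @param groups For `"untreated_zero"`: vector (same length as `values`)
#'   identifying the timepoint of each value; the baseline is the mean of
#'   values whose group equals `zero_label`.
#' @param zero_label Group label of the untreated condition. Default `0`.
#' @return Normalized numeric vector.
#' @export
normalize_profile <- function(values, mode = c("circadian_mean", "untreated_zero"),
                              groups = NULL, zero_label = 0) {
  mode <- match.arg(mode)
  if (mode == "circadian_mean") {
    if (length(values) < 2L) stop("need at least 2 timepoints")
    m <- mean(values)
    if (m == 0) stop("zero mean profile cannot be normalized")
    return(values / m)
  }
  if (is.null(groups)) stop("untreated_zero needs `groups`")
  base <- values[groups == zero_label]
  if (length(base) == 0L) stop("0-min group missing")
  m <- mean(base)
  if (m == 0) stop("zero baseline cannot be normalized")
  values / m
}
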