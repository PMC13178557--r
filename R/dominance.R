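#' Classify proteins as CFC- or CE-dominant
#'
#' Applies the comparative dominance rule on top of a fitted Huber
#' regression of CE on CFC effect sizes. The dominance score of a protein
#' is `effect_cfc - effect_ce`. With `predicted_ce` the regression
#' prediction at the protein's CFC effect size:
#'
#' * **CFC-dominant**: observed CFC effect size above the predicted CE
#'   value, positive dominance score, and `q_cfc < q_threshold`;
#' * **CE-dominant**: observed CE effect size above the predicted CE value,
#'   negative dominance score, and `q_ce < q_threshold`;
#' * **none** otherwise. The two classes are mutually exclusive by the
#'   opposite sign requirements on the dominance score.
#'
#' `rule = "ce_residual"` selects an alternative reading of the first CFC
#' clause in which a protein is CFC-dominant when its *observed CE* effect
#' size falls below the prediction (negative CE residual) instead of its
#' CFC effect size exceeding it. Both readings are defensible; the default
#' compares the observed CFC effect size with the prediction.
#'
#' Bootstrap prediction intervals (see [bootstrap_prediction_ci()]) are
#' descriptive: they are attached when supplied but play no part in the
#' classification, which uses only effect sizes, their difference, and
#' q-values.
#'
#' @param effects data frame with columns `protein_id`, `effect_cfc`,
#'   `effect_ce`, `q_cfc`, `q_ce` (see [merge_effect_tables()]). Rows with
#'   a missing effect in either condition are excluded and reported in the
#'   `excluded` attribute.
#' @param fit a [huber_fit()] of CE on CFC effect sizes.
#' @param annotations optional data frame `protein_id`, `syngo_location`
#'   (values `Presynapse`, `Postsynapse`, `Both`, `Synapse`); unannotated
#'   proteins get location `None`.
#' @param rule `"observed_vs_predicted"` (default) or `"ce_residual"`.
#' @param q_threshold significance threshold (default 0.01).
#' @param ci optional [bootstrap_prediction_ci()] result evaluated at
#'   `effects$effect_cfc` (same order); adds `ci_low`/`ci_high` columns.
#' @return A data frame of class `"dominance_table"`: `protein_id`,
#'   `effect_cfc`, `effect_ce`, `q_cfc`, `q_ce`, `predicted_ce`,
#'   `dominance_score`, `klass` (`CFC-dominant`/`CE-dominant`/`none`),
#'   `syngo_location`, and optionally `ci_low`, `ci_high`.
#' @examples
#' eff <- data.frame(protein_id = "p1", effect_cfc = 1, effect_ce = 0.2,
#'                   q_cfc = 0.001, q_ce = 0.5)
#' fit <- huber_fit(c(-1, 0, 1, 2), 0.65 * c(-1, 0, 1, 2) + 0.06)
#' classify_dominance(eff, fit)$klass
#' @export
classify_dominance <- function(effects, fit, annotations = NULL,
                               rule = c("observed_vs_predicted",
                                        "ce_residual"),
                               q_threshold = 0.01, ci = NULL) {
  rule <- match.arg(rule)
  stopifnot(inherits(fit, "huber_fit"))
  need <- c("protein_id", "effect_cfc", "effect_ce", "q_cfc", "q_ce")
  if (!all(need %in% names(effects))) {
    stop("effects must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  complete <- !is.na(effects$effect_cfc) & !is.na(effects$effect_ce) &
    !is.na(effects$q_cfc) & !is.na(effects$q_ce)
  excluded <- effects$protein_id[!complete]
  eff <- effects[complete, , drop = FALSE]

  predicted_ce <- predict(fit, eff$effect_cfc)
  score <- eff$effect_cfc - eff$effect_ce
  cfc_clause <- if (rule == "observed_vs_predicted") {
    eff$effect_cfc > predicted_ce
  } else {
    eff$effect_ce < predicted_ce
  }
  is_cfc <- cfc_clause & score > 0 & eff$q_cfc < q_threshold
  is_ce <- eff$effect_ce > predicted_ce & score < 0 & eff$q_ce < q_threshold
  klass <- ifelse(is_cfc, "CFC-dominant",
                  ifelse(is_ce, "CE-dominant", "none"))

  loc <- rep("None", nrow(eff))
  if (!is.null(annotations)) {
    stopifnot(all(c("protein_id", "syngo_location") %in% names(annotations)))
    idx <- match(eff$protein_id, annotations$protein_id)
    hit <- !is.na(idx)
    loc[hit] <- as.character(annotations$syngo_location[idx[hit]])
    loc[is.na(loc) | loc == ""] <- "None"
  }

  out <- data.frame(protein_id = eff$protein_id,
                    effect_cfc = eff$effect_cfc,
                    effect_ce = eff$effect_ce,
                    q_cfc = eff$q_cfc, q_ce = eff$q_ce,
                    predicted_ce = predicted_ce,
                    dominance_score = score,
                    klass = klass,
                    syngo_location = loc,
                    stringsAsFactors = FALSE)
  if (!is.null(ci)) {
    stopifnot(nrow(ci) == nrow(effects))
    out$ci_low <- ci$ci_low[complete]
    out$ci_high <- ci$ci_high[complete]
  }
  rownames(out) <- NULL
  attr(out, "excluded") <- excluded
  attr(out, "rule") <- rule
  class(out) <- c("dominance_table", "data.frame")
  out
}

#' Extract dominant proteins from a dominance table
#'
#' @param tab a [classify_dominance()] result.
#' @param syngo_only keep only synaptically annotated proteins
#'   (`syngo_location != "None"`), the subset used for compartment
#'   statistics (default `TRUE`).
#' @return The subset of rows with `klass != "none"`.
#' @export
dominant_proteins <- function(tab, syngo_only = TRUE) {
  keep <- tab$klass != "none"
  if (syngo_only) keep <- keep & tab$syngo_location != "None"
  out <- tab[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}
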