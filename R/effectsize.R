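#' Within-mouse paired log2 differences for one condition
#'
#' For each protein, forms the vector of labelled-minus-unlabelled
#' (`pos - neg`) log2 abundance differences across mice of one condition.
#' Pairing is by `mouse_id`, never by column position. Two filters mirror
#' the upstream quantification rules: a protein must be quantified
#' (non-missing) in at least `min_group_fraction` of the samples of *each*
#' label group, and must retain at least two complete pairs (both members
#' non-missing for the same mouse).
#'
#' @param abundance numeric matrix of log2 abundances, rows = proteins
#'   (rownames are protein ids), columns = samples (colnames are sample
#'   ids). Missing values allowed.
#' @param meta data frame with columns `sample_id`, `mouse_id`, `label`
#'   (`pos`/`neg`) and `condition`.
#' @param condition which condition to analyse (must occur in `meta`).
#' @param min_group_fraction minimum fraction of samples per label group in
#'   which a protein must be quantified (default 0.5).
#' @return A list of class `"paired_differences"` with:
#'   \describe{
#'     \item{differences}{matrix of pos - neg differences, rows = retained
#'       proteins, columns = mice (NA for incomplete pairs).}
#'     \item{n_pairs}{named integer vector of complete pairs per protein.}
#'     \item{pos, neg}{the matched per-label matrices (for group-variance
#'       effect-size denominators).}
#'     \item{dropped}{data frame `protein_id`, `reason`
#'       (`low_detection` or `insufficient_pairs`).}
#'     \item{condition}{the condition analysed.}
#'   }
#' @export
paired_differences <- function(abundance, meta, condition,
                               min_group_fraction = 0.5) {
  stopifnot(is.matrix(abundance), !is.null(rownames(abundance)),
            !is.null(colnames(abundance)))
  if (anyDuplicated(rownames(abundance))) {
    stop("duplicate protein ids in abundance matrix", call. = FALSE)
  }
  if (!condition %in% meta$condition) {
    stop(sprintf("unknown condition '%s'", condition), call. = FALSE)
  }
  check_proportion(min_group_fraction, "min_group_fraction")
  mc <- meta[meta$condition == condition, , drop = FALSE]
  pos <- mc[mc$label == "pos", , drop = FALSE]
  neg <- mc[mc$label == "neg", , drop = FALSE]
  if (anyDuplicated(pos$mouse_id) || anyDuplicated(neg$mouse_id)) {
    stop("more than one sample per (mouse, label, condition)", call. = FALSE)
  }
  mice <- intersect(pos$mouse_id, neg$mouse_id)
  if (length(mice) < 2L) {
    stop("fewer than two complete mouse pairs in condition ", condition,
         call. = FALSE)
  }
  a <- abundance[, pos$sample_id[match(mice, pos$mouse_id)], drop = FALSE]
  b <- abundance[, neg$sample_id[match(mice, neg$mouse_id)], drop = FALSE]
  colnames(a) <- colnames(b) <- mice

  detected <- rowMeans(!is.na(a)) >= min_group_fraction &
    rowMeans(!is.na(b)) >= min_group_fraction
  d <- a - b
  n_pairs <- rowSums(!is.na(d))
  keep <- detected & n_pairs >= 2L
  if (!any(keep)) {
    stop("no proteins with valid pairs in condition ", condition,
         call. = FALSE)
  }
  dropped <- data.frame(
    protein_id = rownames(abundance)[!keep],
    reason = ifelse(!detected[!keep], "low_detection", "insufficient_pairs"),
    stringsAsFactors = FALSE)
  structure(list(differences = d[keep, , drop = FALSE],
                 n_pairs = n_pairs[keep],
                 pos = a[keep, , drop = FALSE],
                 neg = b[keep, , drop = FALSE],
                 dropped = dropped,
                 condition = condition),
            class = "paired_differences")
}

#' Paired test, effect sizes and BH-FDR q-values
#'
#' A two-sided paired t-statistic on each protein's difference vector is
#' the declared stand-in for the upstream peptide-level robust-regression
#' model: the dominance analysis consumes only (effect size, q) pairs,
#' whose shape this preserves. The effect size is the mean paired log2
#' difference standardised to the abundance variance across biological
#' replicates; by default the denominator is the sample SD of the paired
#' differences (`"paired_sd"`), with the root mean of the two group
#' variances (`"group_sd"`) available as an alternative standardisation.
#' The SD is floored at `sd_floor` so zero-variance proteins yield a
#' finite, flagged effect size. q-values are Benjamini-Hochberg adjusted
#' across all retained proteins of the condition.
#'
#' @param pd a [paired_differences()] result.
#' @param sd_floor lower bound on the SD denominator (default 1e-6).
#' @param q_threshold significance threshold on q (default 0.01).
#' @param effect_denominator `"paired_sd"` (default) or `"group_sd"`.
#' @return An effect table (data frame) with columns `protein_id`,
#'   `condition`, `log2fc`, `effect_size`, `p_value`, `q_value`, `n_pairs`,
#'   `significant`, `degenerate_variance`.
#' @examples
#' # differences (0, 0, 2, 2): log2fc 1, sd 1.1547, effect size 0.866
#' sim <- generate_paired_abundances(synth_proteome_config(n_proteins = 20))
#' et <- paired_test_and_fdr(paired_differences(sim$abundance, sim$meta, "CFC"))
#' head(et)
#' @export
paired_test_and_fdr <- function(pd, sd_floor = 1e-6, q_threshold = 0.01,
                                effect_denominator = c("paired_sd",
                                                       "group_sd")) {
  effect_denominator <- match.arg(effect_denominator)
  d <- pd$differences
  if (is.null(d) || nrow(d) == 0L) {
    stop("empty difference set", call. = FALSE)
  }
  check_positive(sd_floor, "sd_floor")
  n <- pd$n_pairs
  log2fc <- rowMeans(d, na.rm = TRUE)
  sd_diff <- row_sds(d)
  degenerate <- sd_diff < sd_floor
  sd_test <- pmax(sd_diff, sd_floor)
  tstat <- log2fc / (sd_test / sqrt(n))
  p <- 2 * pt(-abs(tstat), df = n - 1)
  q <- p.adjust(p, method = "BH")
  denom <- if (effect_denominator == "paired_sd") {
    sd_diff
  } else {
    sqrt((row_sds(pd$pos)^2 + row_sds(pd$neg)^2) / 2)
  }
  effect <- log2fc / pmax(denom, sd_floor)
  out <- data.frame(protein_id = rownames(d),
                    condition = pd$condition,
                    log2fc = log2fc,
                    effect_size = effect,
                    p_value = p,
                    q_value = q,
                    n_pairs = as.integer(n),
                    significant = q < q_threshold,
                    degenerate_variance = degenerate,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Paired differential expression for one condition
#'
#' Convenience wrapper chaining [paired_differences()] and
#' [paired_test_and_fdr()].
#'
#' @inheritParams paired_differences
#' @inheritParams paired_test_and_fdr
#' @return An effect table; see [paired_test_and_fdr()].
#' @export
dea <- function(abundance, meta, condition, min_group_fraction = 0.5,
                sd_floor = 1e-6, q_threshold = 0.01,
                effect_denominator = c("paired_sd", "group_sd")) {
  pd <- paired_differences(abundance, meta, condition, min_group_fraction)
  paired_test_and_fdr(pd, sd_floor = sd_floor, q_threshold = q_threshold,
                      effect_denominator = match.arg(effect_denominator))
}

#' Merge per-condition effect tables into a dominance input table
#'
#' Joins the CFC and CE effect tables on `protein_id`, keeping only
#' proteins quantified in both conditions (no imputation).
#'
#' @param cfc,ce effect tables from [paired_test_and_fdr()] for the CFC and
#'   CE conditions.
#' @return Data frame with `protein_id`, `effect_cfc`, `effect_ce`,
#'   `q_cfc`, `q_ce`, `log2fc_cfc`, `log2fc_ce`.
#' @export
merge_effect_tables <- function(cfc, ce) {
  need <- c("protein_id", "effect_size", "q_value", "log2fc")
  stopifnot(all(need %in% names(cfc)), all(need %in% names(ce)))
  m <- merge(cfc[, need], ce[, need], by = "protein_id",
             suffixes = c("_cfc", "_ce"))
  data.frame(protein_id = m$protein_id,
             effect_cfc = m$effect_size_cfc,
             effect_ce = m$effect_size_ce,
             q_cfc = m$q_value_cfc,
             q_ce = m$q_value_ce,
             log2fc_cfc = m$log2fc_cfc,
             log2fc_ce = m$log2fc_ce,
             stringsAsFactors = FALSE)
}
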