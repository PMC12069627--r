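## qpcr_mtdnaq: relative quantification of mitochondrial DNA from Ct values.
##
## Conventions fixed here (qbase+-style defaults): amplification efficiency
## 2.0 (100%) for all genes, normalization factor = geometric mean of the two
## reference genes, calibrator = geometric mean across samples, so each
## gene's calibrated normalized relative quantities (CNRQ) center at 1. Any
## other calibrator choice differs only by a global factor, which downstream
## standardization removes.

#' Compute calibrated normalized relative quantities (CNRQ) from Ct values
#'
#' Implements the delta-delta-Ct chain: per gene g and sample s the relative
#' quantity is `rq = efficiency^(-ct)`; the normalized quantity divides the
#' target rq by the geometric mean of the reference-gene rqs of the same
#' sample; the CNRQ divides by the geometric mean of that gene's normalized
#' quantities across samples. Samples missing any reference gene are dropped
#' with a warning (recorded in `attr(, "dropped")`); missing target genes are
#' left for [impute_missing_gene()].
#'
#' @param ct Long-format data.frame with columns `sample_id`, `gene`, `ct`.
#' @param targets Target (mitochondrial) gene names.
#' @param references Reference (genomic) gene names.
#' @param efficiency Amplification factor per cycle (> 1; 2 = 100%).
#' @return Data.frame `sample_id`, `gene`, `rq`, `cnrq`, `imputed` with one
#'   row per observed target measurement.
#' @export
relative_quantities <- function(ct, targets = c("ND5", "CYTB"),
                                references = c("APP", "B2M"),
                                efficiency = 2) {
  stopifnot(all(c("sample_id", "gene", "ct") %in% names(ct)),
            efficiency > 1, length(references) >= 1)
  ct <- ct[!is.na(ct$ct), , drop = FALSE]
  if (any(ct$ct <= 0)) stop("Ct values must be positive")
  if (anyDuplicated(ct[, c("sample_id", "gene")]))
    stop("more than one Ct record per (sample, gene)")

  refs <- ct[ct$gene %in% references, , drop = FALSE]
  n_ref <- table(factor(refs$sample_id, levels = unique(ct$sample_id)))
  ok <- names(n_ref)[n_ref == length(references)]
  dropped <- setdiff(unique(ct$sample_id), ok)
  if (length(dropped) > 0)
    warning(length(dropped), " sample(s) dropped: missing reference gene(s)")

  refs <- refs[refs$sample_id %in% ok, , drop = FALSE]
  nf <- tapply(efficiency^(-refs$ct), refs$sample_id, geo_mean)

  tg <- ct[ct$gene %in% targets & ct$sample_id %in% ok, , drop = FALSE]
  tg$rq <- efficiency^(-tg$ct)
  tg$nrq <- tg$rq / as.numeric(nf[tg$sample_id])
  cal <- tapply(tg$nrq, tg$gene, geo_mean)
  tg$cnrq <- tg$nrq / as.numeric(cal[tg$gene])
  out <- data.frame(sample_id = tg$sample_id, gene = tg$gene, rq = tg$rq,
                    cnrq = tg$cnrq, imputed = FALSE,
                    row.names = NULL, stringsAsFactors = FALSE)
  out <- out[order(out$sample_id, out$gene), , drop = FALSE]
  attr(out, "dropped") <- dropped
  attr(out, "targets") <- targets
  out
}

#' Impute a missing target gene by stochastic regression
#'
#' For samples with exactly one of the two target genes measured, the missing
#' gene's log2 CNRQ is predicted from the observed gene's log2 CNRQ by least
#' squares on complete cases, plus a single normal residual draw with SD
#' equal to the fit's residual SD (stochastic regression, one draw per
#' missing value). Quantities are multiplicative, hence the log2 scale.
#' Samples missing both targets are excluded with a warning.
#'
#' @param rqt Output of [relative_quantities()].
#' @param seed Integer seed; fixed seed gives identical imputations.
#' @return `rqt` with imputed rows appended (`imputed = TRUE`).
#' @export
impute_missing_gene <- function(rqt, seed = 1L) {
  targets <- attr(rqt, "targets")
  if (is.null(targets)) targets <- unique(rqt$gene)
  stopifnot(length(targets) == 2)
  wide <- stats::reshape(
    rqt[rqt$gene %in% targets, c("sample_id", "gene", "cnrq")],
    idvar = "sample_id", timevar = "gene", direction = "wide")
  names(wide) <- sub("^cnrq\\.", "", names(wide))
  g1 <- targets[1]; g2 <- targets[2]
  has1 <- !is.na(wide[[g1]]); has2 <- !is.na(wide[[g2]])
  if (!any(!has1 | !has2)) return(rqt)  # nothing to impute
  complete <- has1 & has2
  if (sum(complete) < 10)
    stop("need >= 10 complete cases for the imputation regression")

  set.seed(sub_seed(seed, "impute"))
  l1 <- log2(wide[[g1]]); l2 <- log2(wide[[g2]])
  impute_one <- function(y, x, need) {
    fit <- stats::lm(y ~ x, subset = complete)
    sig <- suppressWarnings(summary(fit)$sigma)  # perfect fits are fine here
    if (!is.finite(sig)) sig <- 0
    pred <- stats::coef(fit)[1] + stats::coef(fit)[2] * x[need]
    2^(pred + stats::rnorm(sum(need), 0, sig))
  }
  out <- rqt
  need1 <- !has1 & has2
  if (any(need1)) {
    v <- impute_one(l1, l2, need1)
    out <- rbind(out, data.frame(sample_id = wide$sample_id[need1],
                                 gene = g1, rq = NA_real_, cnrq = v,
                                 imputed = TRUE, stringsAsFactors = FALSE))
  }
  need2 <- !has2 & has1
  if (any(need2)) {
    v <- impute_one(l2, l1, need2)
    out <- rbind(out, data.frame(sample_id = wide$sample_id[need2],
                                 gene = g2, rq = NA_real_, cnrq = v,
                                 imputed = TRUE, stringsAsFactors = FALSE))
  }
  both_missing <- !has1 & !has2
  if (any(both_missing)) {
    warning(sum(both_missing), " sample(s) excluded: both target genes missing")
    out <- out[!out$sample_id %in% wide$sample_id[both_missing], , drop = FALSE]
  }
  out <- out[order(out$sample_id, out$gene), , drop = FALSE]
  attr(out, "targets") <- targets
  attr(out, "dropped") <- attr(rqt, "dropped")
  out
}

#' Per-sample mtDNA quantity score
#'
#' The arithmetic mean of the two target genes' CNRQs, the study metric for
#' mitochondrial DNA quantity.
#'
#' @param rqt A relative-quantity table with both target genes present for
#'   every sample (run [impute_missing_gene()] first if needed).
#' @return Data.frame `sample_id`, `mtdnaq`.
#' @export
mtdnaq_score <- function(rqt) {
  targets <- attr(rqt, "targets")
  if (is.null(targets)) targets <- unique(rqt$gene)
  tg <- rqt[rqt$gene %in% targets, , drop = FALSE]
  cnt <- table(tg$sample_id)
  if (any(cnt != length(targets)))
    stop("sample(s) missing a target gene after imputation: ",
         paste(names(cnt)[cnt != length(targets)], collapse = ", "))
  agg <- tapply(tg$cnrq, tg$sample_id, mean)
  data.frame(sample_id = names(agg), mtdnaq = as.numeric(agg),
             row.names = NULL, stringsAsFactors = FALSE)
}
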