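# Plate-assay quantification: RT-qPCR relative expression by reference-gene
# normalization with calibrator scaling, and oocyte surface-expression RLU
# normalization with many-vs-control testing.

#' RT-qPCR relative expression with reference-gene normalization
#'
#' Technical duplicates are collapsed by the arithmetic mean of their Cq
#' (a pair disagreeing by more than `dup_tol` cycles is discarded with a
#' warning). Per sample, `dCq = Cq(gene) - ref(Cq of reference genes)` and
#' the relative quantity is `efficiency^(-dCq)`; per-gene quantities are then
#' expressed relative to the calibrator gene's tissue mean (which is exactly
#' 1 by construction). Non-detects (missing Cq or Cq at/above `cq_max`) are
#' reported per sample and excluded from means.
#'
#' The default reference aggregation (`ref_method = "quantity_geomean"`) is
#' the geometric mean of the reference genes' expression quantities, i.e. the
#' arithmetic mean of their Cq values -- the aggregation under which a
#' per-sample loading offset added to every Cq cancels exactly.
#' `"cq_geomean"` (geometric mean taken on the Cq scale itself) is available
#' as an option; it differs only marginally at typical Cq but is not exactly
#' shift-invariant.
#'
#' @param t Cq table: `data.frame` with columns `tissue`, `gene`, `sample`,
#'   `replicate`, `cq` (as from [gen_cq_table()]).
#' @param ref_genes Reference genes (e.g. Hprt/Sdha/Tfrc); must be detected
#'   in every sample used.
#' @param calibrator Calibrator gene per tissue (e.g. Kcnq2 for neural
#'   tissue, Kcnq1 for heart); must be detected in at least one sample.
#' @param efficiency Amplification efficiency (2 = one doubling per cycle).
#' @param cq_max Detection ceiling; Cq at/above this is a non-detect.
#' @param dup_tol Maximal allowed disagreement of technical duplicates
#'   (cycles).
#' @param ref_method Reference aggregation (see Details).
#' @return List with `per_sample` (`tissue`, `gene`, `sample`, `cq`,
#'   `rel_quantity`, `rel_to_calibrator`, `detected`) and `per_gene`
#'   (`tissue`, `gene`, `n_detected`, `mean_rel`, `sem_rel`).
#' @export
relative_expression <- function(t, ref_genes, calibrator, efficiency = 2,
                                cq_max = 40, dup_tol = 1,
                                ref_method = c("quantity_geomean",
                                               "cq_geomean")) {
  ref_method <- match.arg(ref_method)
  stopifnot(all(c("tissue", "gene", "sample", "cq") %in% names(t)))
  t$cq[!is.na(t$cq) & t$cq >= cq_max] <- NA_real_

  # collapse technical duplicates
  key <- interaction(t$tissue, t$gene, t$sample, drop = TRUE)
  collapsed <- do.call(rbind, lapply(split(t, key), function(d) {
    cqs <- d$cq[!is.na(d$cq)]
    cq <- if (length(cqs) == 0L) {
      NA_real_
    } else if (length(cqs) >= 2L && diff(range(cqs)) > dup_tol) {
      warning(sprintf("duplicates for %s/%s/%s differ by > %g cycles; pair discarded",
                      d$tissue[1L], d$gene[1L], d$sample[1L], dup_tol))
      NA_real_
    } else {
      mean(cqs)
    }
    data.frame(tissue = d$tissue[1L], gene = d$gene[1L],
               sample = d$sample[1L], cq = cq, stringsAsFactors = FALSE)
  }))
  rownames(collapsed) <- NULL

  out <- lapply(split(collapsed, collapsed$tissue), function(ct) {
    wide_ref <- lapply(split(ct, ct$sample), function(d) {
      rcq <- d$cq[match(ref_genes, d$gene)]
      if (anyNA(rcq)) {
        stop("reference gene non-detect in sample ", d$sample[1L],
             " (tissue ", d$tissue[1L], ")")
      }
      switch(ref_method,
             quantity_geomean = mean(rcq),
             cq_geomean = exp(mean(log(rcq))))
    })
    ct$ref_cq <- unlist(wide_ref)[ct$sample]
    ct$rel_quantity <- efficiency^(-(ct$cq - ct$ref_cq))
    ct$detected <- !is.na(ct$cq)
    cal <- ct$rel_quantity[ct$gene == calibrator & ct$detected]
    if (!length(cal)) {
      stop("calibrator '", calibrator, "' undetected in every sample of tissue ",
           ct$tissue[1L])
    }
    ct$rel_to_calibrator <- ct$rel_quantity / mean(cal)
    ct
  })
  per_sample <- do.call(rbind, out)
  rownames(per_sample) <- NULL
  per_sample$ref_cq <- NULL

  per_gene <- do.call(rbind, lapply(
    split(per_sample, interaction(per_sample$tissue, per_sample$gene,
                                  drop = TRUE)),
    function(d) {
      v <- d$rel_to_calibrator[d$detected]
      data.frame(tissue = d$tissue[1L], gene = d$gene[1L],
                 n_detected = length(v),
                 mean_rel = if (length(v)) mean(v) else NA_real_,
                 sem_rel = if (length(v) > 1L) stats::sd(v) / sqrt(length(v))
                           else NA_real_,
                 stringsAsFactors = FALSE)
    }))
  rownames(per_gene) <- NULL
  list(per_sample = per_sample, per_gene = per_gene)
}

#' Normalise oocyte surface-expression luminescence and test vs control
#'
#' Per experiment: the mean background (uninjected) RLU is subtracted
#' (negative per-oocyte values clipped to 0) and values are divided by the
#' experiment's mean background-subtracted control signal, cancelling any
#' per-experiment multiplicative batch factor. Pooled normalised values are
#' then compared by ordinary one-way ANOVA with post hoc Dunnett tests
#' against the control group; stars at P <= 0.05 / 0.01 / 0.001.
#'
#' @param t RLU table: `data.frame` with `experiment`, `group`, `oocyte`,
#'   `rlu` (as from [gen_rlu_table()]).
#' @param control_group Kv7-alone control group (normalised mean exactly 1).
#' @param background_group Uninjected negative-control group.
#' @return List with `normalized` (input rows minus the background group,
#'   plus `rlu_norm`), `summary` (per-group n, mean, sem, p_value, stars),
#'   `anova` (the `aov` fit), `dunnett`.
#' @export
normalize_rlu <- function(t, control_group = "control",
                          background_group = "uninjected") {
  stopifnot(all(c("experiment", "group", "rlu") %in% names(t)))
  if (!control_group %in% t$group) stop("control group absent")
  if (!background_group %in% t$group) stop("background group absent")

  norm_parts <- lapply(split(t, t$experiment), function(d) {
    if (!control_group %in% d$group) {
      warning("experiment ", d$experiment[1L],
              " lacks the control group; excluded")
      return(NULL)
    }
    bg <- mean(d$rlu[d$group == background_group])
    d$rlu_norm <- pmax(d$rlu - bg, 0)
    ctrl <- mean(d$rlu_norm[d$group == control_group])
    if (ctrl <= 0) {
      warning("experiment ", d$experiment[1L],
              " has no control signal above background; excluded")
      return(NULL)
    }
    d$rlu_norm <- d$rlu_norm / ctrl
    d[d$group != background_group, ]
  })
  normalized <- do.call(rbind, norm_parts)
  if (is.null(normalized) || !nrow(normalized)) {
    stop("no experiment with a usable control group")
  }
  rownames(normalized) <- NULL

  normalized$group <- stats::relevel(factor(normalized$group),
                                     ref = control_group)
  fit <- stats::aov(rlu_norm ~ group, data = normalized)
  dn <- summary(multcomp::glht(fit, linfct = multcomp::mcp(group = "Dunnett")))
  pvals <- as.numeric(dn$test$pvalues)
  cmp_groups <- sub(" - .*$", "", names(dn$test$coefficients))

  smry <- do.call(rbind, lapply(split(normalized$rlu_norm, normalized$group),
                                function(v) {
    data.frame(n = length(v), mean = mean(v),
               sem = stats::sd(v) / sqrt(length(v)))
  }))
  smry$group <- rownames(smry); rownames(smry) <- NULL
  smry$p_value <- NA_real_
  smry$p_value[match(cmp_groups, smry$group)] <- pvals
  smry$stars <- ifelse(is.na(smry$p_value), "", .stars(smry$p_value))
  smry <- smry[, c("group", "n", "mean", "sem", "p_value", "stars")]

  list(normalized = normalized, summary = smry, anova = fit, dunnett = dn)
}
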