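#' Relative expression by the delta-delta-Cq method
#'
#' Per sample, `dCq = Cq_target - mean(Cq_reference)` (technical
#' replicates of a gene are averaged on the Cq scale first; multiple
#' reference genes are averaged arithmetically on the Cq scale). Per gene
#' and treatment group, `ddCq = mean(dCq_treated) - mean(dCq_control)`
#' and the fold change versus control is `2^(-ddCq)` (control = 1;
#' amplification efficiency fixed at the classic value of 2). Group
#' differences in dCq are tested per gene by a two-sample t-test for two
#' groups or one-way ANOVA with Tukey post hoc contrasts against the
#' control for three or more.
#'
#' Because every sample's reference Cq is subtracted, adding a constant
#' to all Cq values of a sample (a plate offset) leaves all fold changes
#' unchanged.
#'
#' @param cq_table Long data frame with columns `sample`, `group`,
#'   `gene`, `cq` (e.g. from [generate_cq_table()]).
#' @param control Control group name.
#' @param ref_genes Reference gene names; every sample must carry each.
#' @return Data frame, one row per non-reference gene per non-control
#'   group: `gene`, `group`, `dcq`, `ddcq`, `fold_change`
#'   (`= 2^-ddcq` exactly), `n`, `p_value`.
#' @export
ddcq <- function(cq_table, control, ref_genes = c("HPRT1", "GAPDH")) {
  need <- c("sample", "group", "gene", "cq")
  if (!all(need %in% names(cq_table)))
    stop("cq_table needs columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  if (!control %in% cq_table$group)
    stop(sprintf("control group '%s' not present", control), call. = FALSE)
  if (any(cq_table$cq < 5 | cq_table$cq > 45, na.rm = TRUE))
    warning("Cq values outside the typical 5-45 cycle range")

  # mean Cq per sample x gene (technical replicates collapse here)
  cqm <- stats::aggregate(cq ~ sample + group + gene, data = cq_table,
                          FUN = mean)
  ref <- cqm[cqm$gene %in% ref_genes, ]
  miss <- setdiff(unique(cqm$sample), unique(ref$sample))
  if (length(ref_genes) == 0 || length(miss) ||
      !all(ref_genes %in% cq_table$gene))
    stop("reference gene(s) missing in sample(s): ",
         paste(c(miss, setdiff(ref_genes, cq_table$gene)), collapse = ", "),
         call. = FALSE)
  refm <- stats::aggregate(cq ~ sample, data = ref, FUN = mean)
  cqm$dcq <- cqm$cq - refm$cq[match(cqm$sample, refm$sample)]

  genes <- setdiff(unique(cqm$gene), ref_genes)
  groups <- setdiff(unique(cqm$group), control)
  out <- list()
  for (g in genes) {
    dg <- cqm[cqm$gene == g, ]
    ctrl_mean <- mean(dg$dcq[dg$group == control])
    ngroups <- length(unique(dg$group))
    pvals <- rep(NA_real_, length(groups))
    names(pvals) <- groups
    if (ngroups == 2) {
      tg <- groups[groups %in% dg$group]
      if (length(tg) == 1 && sum(dg$group == tg) >= 2)
        pvals[tg] <- tryCatch(
          stats::t.test(dg$dcq[dg$group == tg],
                        dg$dcq[dg$group == control])$p.value,
          error = function(e) NA_real_)  # zero-variance (noiseless) data
    } else if (ngroups > 2) {
      dg$group <- factor(dg$group)
      dg$group <- stats::relevel(dg$group, ref = control)
      fit <- stats::aov(dcq ~ group, data = dg)
      tk <- tryCatch(stats::TukeyHSD(fit)$group, error = function(e) NULL)
      for (tg in groups) {
        hit <- rownames(tk) %in% paste0(tg, "-", control)
        if (any(hit)) pvals[tg] <- tk[hit, "p adj"]
      }
    }
    for (tg in groups) {
      sel <- dg$group == tg
      if (!any(sel)) next
      dd <- mean(dg$dcq[sel]) - ctrl_mean
      out[[length(out) + 1L]] <- data.frame(
        gene = g, group = tg, dcq = mean(dg$dcq[sel]), ddcq = dd,
        fold_change = 2^(-dd), n = sum(sel), p_value = pvals[[tg]])
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Filter differentially expressed genes by fold change and p-value
#'
#' A gene is kept iff its fold change is at least `fc` in either
#' direction (`FC >= fc` or `FC <= 1/fc`) and its p-value is below `p`.
#' Directionality is carried as a signed fold change (`+FC` up, `-1/FC`
#' expressed as `-FC` down) to match the usual "+/- fold" notation.
#'
#' @param de_table Data frame with columns `gene`, `fold_change`
#'   (positive, vs control) and `p_value`.
#' @param fc Fold-change threshold (default 3).
#' @param p P-value threshold (default 0.05).
#' @return Object of class `"deg_set"`: list with `genes` (character),
#'   `table` (the kept rows plus `signed_fc`), `fc`, `p`.
#' @export
filter_degs <- function(de_table, fc = 3, p = 0.05) {
  need <- c("gene", "fold_change", "p_value")
  if (!all(need %in% names(de_table)))
    stop("de_table needs columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  stopifnot(fc >= 1, all(de_table$fold_change > 0))
  keep <- (de_table$fold_change >= fc | de_table$fold_change <= 1 / fc) &
    de_table$p_value < p
  kept <- de_table[keep, , drop = FALSE]
  kept$signed_fc <- ifelse(kept$fold_change >= 1, kept$fold_change,
                           -1 / kept$fold_change)
  structure(list(genes = unique(kept$gene), table = kept, fc = fc, p = p),
            class = "deg_set")
}

#' Three-set Venn region counts
#'
#' Counts the 7 disjoint regions of three finite id sets; the counts sum
#' to `|A union B union C|`.
#'
#' @param set_a,set_b,set_c Vectors of ids (or `"deg_set"` objects).
#' @return Named list: `a_only`, `b_only`, `c_only`, `ab_only`,
#'   `ac_only`, `bc_only`, `abc`, plus `totals` (per-set sizes).
#' @export
#' @examples
#' venn3(1:5, 4:8, 5:6)$abc  # 1
venn3 <- function(set_a, set_b, set_c) {
  g <- function(s) if (inherits(s, "deg_set")) s$genes else unique(s)
  a <- g(set_a); b <- g(set_b); c <- g(set_c)
  ids <- unique(c(a, b, c))
  ina <- ids %in% a; inb <- ids %in% b; inc <- ids %in% c
  list(a_only = sum(ina & !inb & !inc),
       b_only = sum(!ina & inb & !inc),
       c_only = sum(!ina & !inb & inc),
       ab_only = sum(ina & inb & !inc),
       ac_only = sum(ina & !inb & inc),
       bc_only = sum(!ina & inb & inc),
       abc = sum(ina & inb & inc),
       totals = c(a = length(a), b = length(b), c = length(c)))
}
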