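#' Four-parameter logistic response
#'
#' `response = bottom + (top - bottom) / (1 + (x / ic50)^hill)`. With
#' `hill > 0` the curve decreases from `top` (low concentration) to
#' `bottom` (high concentration), the usual shape of an inhibition
#' readout.
#'
#' @param x Concentrations (molar).
#' @param top,bottom Asymptotes (response units).
#' @param ic50 Half-maximal concentration (molar, > 0).
#' @param hill Hill slope.
#' @return Numeric vector of responses.
#' @export
#' @examples
#' fourpl(1e-6, top = 100, bottom = 0, ic50 = 1e-6, hill = 1)  # 50
fourpl <- function(x, top, bottom, ic50, hill) {
  stopifnot(ic50 > 0)
  bottom + (top - bottom) / (1 + (x / ic50)^hill)
}

#' Specification of a simulated dose-response series
#'
#' @param top,bottom,ic50,hill True 4PL parameters; `ic50` in molar.
#' @param concentrations Molar concentrations, strictly positive; default
#'   is the 10-point half-log series from 10 uM down. See
#'   [conc_series()].
#' @param n_replicates Replicates per concentration (>= 1).
#' @param cv Multiplicative lognormal noise CV (>= 0).
#' @param seed Integer seed.
#' @return List of class `"dose_series_spec"`.
#' @export
dose_series_spec <- function(top = 100, bottom = 0, ic50 = 1e-6, hill = 1,
                             concentrations = conc_series("10pt"),
                             n_replicates = 3L, cv = 0.1, seed = 1L) {
  assert_scalar(ic50, "ic50", positive = TRUE)
  assert_scalar(cv, "cv", nonneg = TRUE)
  stopifnot(all(concentrations > 0), !is.unsorted(rev(concentrations)) ||
              !is.unsorted(concentrations), n_replicates >= 1)
  concentrations <- sort(unique(concentrations))
  structure(list(top = top, bottom = bottom, ic50 = ic50, hill = hill,
                 concentrations = concentrations,
                 n_replicates = as.integer(n_replicates), cv = cv,
                 seed = as.integer(seed)),
            class = "dose_series_spec")
}

#' Standard concentration series
#'
#' `"10pt"` is a 10-point half-log dilution from 10 uM; `"6pt"` is a
#' 6-point log-spaced series from 10 uM down to 0.625 uM, the layout used
#' for confirmation screens.
#'
#' @param layout `"10pt"` or `"6pt"`.
#' @return Molar concentrations, ascending.
#' @export
conc_series <- function(layout = c("10pt", "6pt")) {
  layout <- match.arg(layout)
  if (layout == "10pt") sort(10e-6 * 10^(-(0:9) / 2))
  else sort(exp(seq(log(10e-6), log(0.625e-6), length.out = 6)))
}

#' Generate a replicated dose-response table with multiplicative noise
#'
#' Responses are the exact 4PL curve at each concentration multiplied by
#' lognormal noise with mean 1 and the configured CV.
#'
#' @param spec A [dose_series_spec()].
#' @return Data frame (`concentration`, `replicate`, `response`), plus the
#'   true parameters as attribute `"truth"`.
#' @export
generate_dose_series <- function(spec) {
  stopifnot(inherits(spec, "dose_series_spec"))
  conc <- rep(spec$concentrations, each = spec$n_replicates)
  mu <- fourpl(conc, spec$top, spec$bottom, spec$ic50, spec$hill)
  resp <- with_seed(spec$seed, {
    if (spec$cv <= 0) mu else {
      sdl <- sqrt(log(1 + spec$cv^2))
      mu * stats::rlnorm(length(mu), meanlog = -sdl^2 / 2, sdlog = sdl)
    }
  })
  out <- data.frame(concentration = conc,
                    replicate = rep(seq_len(spec$n_replicates),
                                    times = length(spec$concentrations)),
                    response = resp)
  attr(out, "truth") <- spec[c("top", "bottom", "ic50", "hill")]
  out
}

#' Specification of a simulated qPCR Cq table
#'
#' Cq values follow `Cq = baseline - log2(relative expression) + noise`,
#' so a gene with true fold change 2 versus control sits exactly one cycle
#' lower. Reference genes have true fold change 1 in every group.
#'
#' @param genes Character vector of target gene names.
#' @param groups Treatment group names; the first is taken as control
#'   unless `control` says otherwise.
#' @param log2fc Matrix of true log2 fold changes vs control
#'   (genes x groups); the control column is forced to 0.
#' @param ref_genes Reference gene names (zero true effect everywhere).
#' @param control Control group name.
#' @param n_replicates Replicates per group (>= 2).
#' @param noise_sd Cq noise SD in cycles.
#' @param sample_offset_sd SD of a per-sample constant Cq offset
#'   (pipetting/plate effects; cancels in the delta-delta-Cq).
#' @param baseline Baseline Cq per gene (recycled; default 25 cycles).
#' @param seed Integer seed.
#' @return List of class `"cq_spec"`.
#' @export
cq_spec <- function(genes, groups, log2fc, ref_genes = c("HPRT1", "GAPDH"),
                    control = groups[1], n_replicates = 3L, noise_sd = 0.1,
                    sample_offset_sd = 0, baseline = 25, seed = 1L) {
  stopifnot(n_replicates >= 2, noise_sd >= 0, control %in% groups,
            length(genes) >= 1)
  all_genes <- union(genes, ref_genes)
  fc <- matrix(0, length(all_genes), length(groups),
               dimnames = list(all_genes, groups))
  if (!missing(log2fc) && !is.null(log2fc)) {
    log2fc <- as.matrix(log2fc)
    fc[rownames(log2fc), colnames(log2fc)] <- log2fc
  }
  fc[ref_genes, ] <- 0   # reference genes: true fold change exactly 1
  fc[, control] <- 0
  baseline <- rep_len(baseline, length(all_genes))
  names(baseline) <- all_genes
  structure(list(genes = all_genes, groups = groups, log2fc = fc,
                 ref_genes = ref_genes, control = control,
                 n_replicates = as.integer(n_replicates),
                 noise_sd = noise_sd, sample_offset_sd = sample_offset_sd,
                 baseline = baseline, seed = as.integer(seed)),
            class = "cq_spec")
}

#' Generate a long-format Cq table from a [cq_spec()]
#'
#' @param spec A [cq_spec()].
#' @return Data frame (`sample`, `group`, `replicate`, `gene`, `cq`) with
#'   the reference genes marked in attribute `"ref_genes"` and the true
#'   log2 fold-change matrix in attribute `"truth"`.
#' @export
generate_cq_table <- function(spec) {
  stopifnot(inherits(spec, "cq_spec"))
  rows <- expand.grid(replicate = seq_len(spec$n_replicates),
                      group = spec$groups, gene = spec$genes,
                      stringsAsFactors = FALSE)
  rows$sample <- paste(rows$group, rows$replicate, sep = "_")
  mu <- spec$baseline[rows$gene] - spec$log2fc[cbind(rows$gene, rows$group)]
  rows$cq <- with_seed(spec$seed, {
    offs <- stats::rnorm(length(unique(rows$sample)), 0,
                         spec$sample_offset_sd)
    names(offs) <- unique(rows$sample)
    mu + offs[rows$sample] + stats::rnorm(nrow(rows), 0, spec$noise_sd)
  })
  out <- rows[, c("sample", "group", "replicate", "gene", "cq")]
  attr(out, "ref_genes") <- spec$ref_genes
  attr(out, "truth") <- spec$log2fc
  out
}

#' Generate a synthetic compound set with clustered fingerprints and
#' target activities
#'
#' Compounds fall into planted structural families: each family has a
#' random binary fingerprint "scaffold" and members differ from it by a
#' few bit flips, so within-family Tanimoto distances are far below
#' between-family distances. Each family is annotated against its own
#' small target panel with potencies above the profiling cutoff, plus
#' weaker off-family activities below it.
#'
#' @param n Number of compounds (>= 2).
#' @param seed Integer seed.
#' @param n_families Number of planted families.
#' @param bits Fingerprint length (default 2048).
#' @param on_bits Bits set in each family scaffold.
#' @param flips Bit flips per member.
#' @param targets_per_family Annotated targets per family.
#' @return List with `fingerprints` (n x bits 0/1 matrix, compound ids as
#'   rownames), `activities` (data frame: `compound`, `target`,
#'   `endpoint`, `value` = pXC50), `families` (integer vector of truth
#'   labels), and `class_map` (data frame `target`, `class`).
#' @export
generate_compound_set <- function(n, seed, n_families = 3L, bits = 2048L,
                                  on_bits = NULL, flips = NULL,
                                  targets_per_family = 3L) {
  on_bits <- on_bits %||% min(60L, bits %/% 4L)
  flips <- flips %||% max(2L, on_bits %/% 10L)
  stopifnot(n >= 2, n_families >= 1, bits > on_bits + flips)
  classes <- c("CDK", "PI3K/AKT/mTOR", "EGFR", "CHEK")
  with_seed(seed, {
    fam <- rep_len(seq_len(n_families), n)
    ids <- sprintf("C%02d", seq_len(n))
    scaff <- lapply(seq_len(n_families), function(f)
      sample.int(bits, on_bits))
    fp <- matrix(0L, n, bits, dimnames = list(ids, NULL))
    for (i in seq_len(n)) {
      v <- integer(bits)
      v[scaff[[fam[i]]]] <- 1L
      fl <- sample.int(bits, flips)
      v[fl] <- 1L - v[fl]
      fp[i, ] <- v
    }
    tg <- lapply(seq_len(n_families), function(f)
      sprintf("T%d_%d", f, seq_len(targets_per_family)))
    act <- do.call(rbind, lapply(seq_len(n), function(i) {
      own <- data.frame(compound = ids[i], target = tg[[fam[i]]],
                        endpoint = "IC50",
                        value = stats::runif(targets_per_family, 7.2, 9.5))
      other <- unlist(tg[-fam[i]])
      off <- data.frame(compound = ids[i],
                        target = sample(other, min(2, length(other))),
                        endpoint = "IC50",
                        value = stats::runif(min(2, length(other)), 4.5, 6.5))
      rbind(own, off)
    }))
    cls <- data.frame(target = unlist(tg),
                      class = rep(rep_len(classes, n_families),
                                  each = targets_per_family))
    list(fingerprints = fp, activities = act, families = fam,
         class_map = cls)
  })
}
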