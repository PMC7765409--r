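#' Tanimoto distance between two binary fingerprints
#'
#' `1 - |a AND b| / |a OR b|`; the distance between two all-zero
#' fingerprints is defined as 0.
#'
#' @param fp_a,fp_b Binary (0/1 or logical) vectors of equal length.
#' @return Distance in `[0, 1]`.
#' @export
#' @examples
#' tanimoto_distance(c(1, 1, 1, 0), c(0, 1, 1, 1))  # 0.5
tanimoto_distance <- function(fp_a, fp_b) {
  if (length(fp_a) != length(fp_b))
    stop("fingerprint bit lengths differ", call. = FALSE)
  a <- as.logical(fp_a); b <- as.logical(fp_b)
  un <- sum(a | b)
  if (un == 0) return(0)
  1 - sum(a & b) / un
}

#' Pairwise Tanimoto distance matrix of a fingerprint set
#'
#' @param fingerprints Binary matrix, one compound per row (rownames are
#'   compound ids).
#' @return Symmetric distance matrix with zero diagonal.
#' @export
tanimoto_matrix <- function(fingerprints) {
  m <- as.matrix(fingerprints)
  stopifnot(all(m %in% c(0, 1)))
  inter <- tcrossprod(m)
  ones <- rowSums(m)
  un <- outer(ones, ones, "+") - inter
  d <- ifelse(un > 0, 1 - inter / un, 0)
  diag(d) <- 0
  dimnames(d) <- list(rownames(m), rownames(m))
  d
}

#' Ward agglomerative clustering of a dissimilarity matrix
#'
#' Agglomerates by Ward's minimum-variance criterion via the
#' Lance-Williams recurrence applied to squared dissimilarities (the
#' "ward.D2" convention: merge heights are on the scale of the input
#' distances, and two points at distance d merge at height d).
#' Deterministic tie-breaking: among merges of minimal objective, the
#' pair whose clusters contain the lexicographically smallest leaf
#' indices is merged first. Merge heights are checked to be
#' non-decreasing on every run.
#'
#' @param d Symmetric non-negative matrix with zero diagonal (or a
#'   `dist`).
#' @return Object of class `"ward_linkage"`: `merge` (hclust-style n-1 x 2
#'   matrix), `height`, `order` (leaf order for dendrogram rendering),
#'   `labels`, `sizes` (resulting cluster size at each merge).
#' @export
ward_cluster <- function(d) {
  if (inherits(d, "dist")) d <- as.matrix(d)
  stopifnot(is.matrix(d), nrow(d) == ncol(d))
  if (any(d < 0) || any(abs(diag(d)) > 1e-12) ||
      any(abs(d - t(d)) > 1e-8))
    stop("distance matrix must be symmetric, non-negative, zero-diagonal",
         call. = FALSE)
  n <- nrow(d)
  stopifnot(n >= 2)
  labels <- rownames(d) %||% as.character(seq_len(n))

  D2 <- d^2
  active <- seq_len(n)                     # active cluster slots
  size <- rep(1L, n)
  min_leaf <- seq_len(n)                   # tie-break key per cluster
  node <- -seq_len(n)                      # hclust coding: leaves negative
  merge <- matrix(0L, n - 1L, 2L)
  height <- numeric(n - 1L)
  sizes <- integer(n - 1L)

  for (m in seq_len(n - 1L)) {
    best <- NULL
    for (ii in seq_along(active)[-length(active)]) {
      for (jj in (ii + 1L):length(active)) {
        a <- active[ii]; b <- active[jj]
        v <- D2[a, b]
        key <- sort(c(min_leaf[a], min_leaf[b]))
        if (is.null(best) || v < best$v - 1e-12 ||
            (abs(v - best$v) <= 1e-12 &&
             (key[1] < best$key[1] ||
              (key[1] == best$key[1] && key[2] < best$key[2])))) {
          best <- list(v = v, a = a, b = b, key = key)
        }
      }
    }
    a <- best$a; b <- best$b
    height[m] <- sqrt(max(best$v, 0))
    merge[m, ] <- {
      ka <- node[a]; kb <- node[b]
      # hclust convention: singletons (negative) listed before clusters;
      # two singletons by ascending leaf index, two clusters ascending
      if ((ka < 0 && kb < 0 && ka < kb) || (ka > 0 && kb < 0) ||
          (ka > 0 && kb > 0 && ka > kb)) c(kb, ka) else c(ka, kb)
    }
    na <- size[a]; nb <- size[b]
    sizes[m] <- na + nb
    for (k in setdiff(active, c(a, b))) {
      D2[a, k] <- D2[k, a] <-
        ((na + size[k]) * D2[a, k] + (nb + size[k]) * D2[b, k] -
           size[k] * D2[a, b]) / (na + nb + size[k])
    }
    size[a] <- na + nb
    min_leaf[a] <- min(min_leaf[a], min_leaf[b])
    node[a] <- m
    active <- setdiff(active, b)
  }
  if (any(diff(height) < -1e-8))
    stop("internal error: Ward merge heights decreased", call. = FALSE)

  # leaf order by recursive traversal of the merge tree
  expand <- function(i) {
    if (i < 0) -i
    else c(expand(merge[i, 1]), expand(merge[i, 2]))
  }
  structure(list(merge = merge, height = height,
                 order = if (n > 1) expand(n - 1L) else 1L,
                 labels = labels, sizes = sizes, method = "ward.D2"),
            class = "ward_linkage")
}

#' @export
as.hclust.ward_linkage <- function(x, ...) {
  structure(list(merge = x$merge, height = x$height, order = x$order,
                 labels = x$labels, method = x$method,
                 call = match.call(), dist.method = "user"),
            class = "hclust")
}

#' Cut a Ward linkage into flat clusters
#'
#' @param linkage A `"ward_linkage"` from [ward_cluster()].
#' @param k Number of clusters (1..n), or
#' @param h Height below which to cut.
#' @return Integer cluster labels named by compound, stable across runs
#'   (clusters numbered by first appearance in input order).
#' @export
cut_clusters <- function(linkage, k = NULL, h = NULL) {
  stopifnot(inherits(linkage, "ward_linkage"))
  n <- length(linkage$labels)
  if (!is.null(k) && (k < 1 || k > n))
    stop(sprintf("k must be in 1..%d", n), call. = FALSE)
  stats::cutree(as.hclust.ward_linkage(linkage), k = k, h = h)
}

#' Newick string for a linkage (dendrogram export)
#'
#' @param linkage A `"ward_linkage"`.
#' @return Newick-format character scalar with branch lengths derived
#'   from merge heights.
#' @export
linkage_newick <- function(linkage) {
  stopifnot(inherits(linkage, "ward_linkage"))
  hts <- c(rep(0, length(linkage$labels)), linkage$height)
  node_h <- function(i) if (i < 0) 0 else linkage$height[i]
  build <- function(i, parent_h) {
    if (i < 0)
      sprintf("%s:%g", linkage$labels[-i], parent_h)
    else
      sprintf("(%s,%s):%g", build(linkage$merge[i, 1], linkage$height[i]),
              build(linkage$merge[i, 2], linkage$height[i]),
              parent_h - linkage$height[i])
  }
  m <- nrow(linkage$merge)
  sprintf("(%s,%s);", build(linkage$merge[m, 1], linkage$height[m]),
          build(linkage$merge[m, 2], linkage$height[m]))
}

#' Build a compound x target pXC50 activity matrix
#'
#' Aggregates repeated activity records per compound-target pair: median
#' within one (source, endpoint) stratum, then the maximum across strata
#' (a compound with multiple measured activities reports its highest).
#' Records without a `source` column are treated as coming from distinct
#' sources, so repeated bare values reduce by the maximum.
#' Entries below the cutoff stay in the matrix but are hidden in the
#' masked view, the analogue of graying sub-threshold potencies in a
#' heatmap.
#'
#' @param records Data frame with columns `compound`, `target`, `value`
#'   (pXC50) and optionally `endpoint` and `source`.
#' @param cutoff Activity cutoff (default 7.0, i.e. 100 nM).
#' @param aggregate `"median_then_max"` (default) or `"max"`.
#' @return Object of class `"activity_matrix"`: list with `matrix`
#'   (compounds x targets, NA where unmeasured), `cutoff`.
#' @export
build_activity_matrix <- function(records, cutoff = 7.0,
                                  aggregate = c("median_then_max", "max")) {
  aggregate <- match.arg(aggregate)
  need <- c("compound", "target", "value")
  if (!all(need %in% names(records)))
    stop("records need columns compound, target, value", call. = FALSE)
  bad <- which(!is.finite(suppressWarnings(as.numeric(records$value))))
  if (length(bad))
    stop(sprintf("non-numeric activity value in record %d (%s / %s)",
                 bad[1], records$compound[bad[1]], records$target[bad[1]]),
         call. = FALSE)
  records$value <- as.numeric(records$value)
  if (nrow(records) == 0) {
    return(structure(list(matrix = matrix(NA_real_, 0, 0), cutoff = cutoff),
                     class = "activity_matrix"))
  }
  strat <- interaction(records[["source"]] %||% seq_len(nrow(records)),
                       records[["endpoint"]] %||% "one", drop = TRUE)
  key <- paste(records$compound, records$target, sep = "\r")
  agg <- if (aggregate == "median_then_max") {
    med <- stats::aggregate(value ~ key + strat,
                            data = data.frame(value = records$value,
                                              key = key, strat = strat),
                            FUN = stats::median)
    stats::aggregate(value ~ key, data = med, FUN = max)
  } else {
    stats::aggregate(value ~ key,
                     data = data.frame(value = records$value, key = key),
                     FUN = max)
  }
  parts <- do.call(rbind, strsplit(agg$key, "\r", fixed = TRUE))
  compounds <- sort(unique(records$compound))
  targets <- sort(unique(records$target))
  m <- matrix(NA_real_, length(compounds), length(targets),
              dimnames = list(compounds, targets))
  m[cbind(parts[, 1], parts[, 2])] <- agg$value
  structure(list(matrix = m, cutoff = cutoff),
            class = "activity_matrix")
}

#' Cutoff-masked view of an activity matrix
#'
#' @param x An `"activity_matrix"`.
#' @return Matrix with entries below the cutoff set to NA.
#' @export
masked_view <- function(x) {
  stopifnot(inherits(x, "activity_matrix"))
  m <- x$matrix
  m[!is.na(m) & m < x$cutoff] <- NA_real_
  m
}

#' Rank target classes by above-cutoff activity
#'
#' Orders target classes by the number of compound-target pairs with
#' pXC50 at or above the cutoff; ties break alphabetically. Targets
#' without a class map to `"unclassified"`.
#'
#' @param x An `"activity_matrix"`.
#' @param class_map Data frame with columns `target`, `class`.
#' @return Data frame `class`, `n_active_pairs`, `n_targets`, ordered.
#' @export
rank_target_classes <- function(x, class_map) {
  stopifnot(inherits(x, "activity_matrix"))
  m <- x$matrix
  if (length(m) == 0 || all(is.na(m)))
    return(data.frame(class = character(0), n_active_pairs = integer(0),
                      n_targets = integer(0)))
  cls <- class_map$class[match(colnames(m), class_map$target)]
  cls[is.na(cls)] <- "unclassified"
  above <- !is.na(m) & m >= x$cutoff
  n_act <- tapply(colSums(above), cls, sum)
  n_tgt <- tapply(rep(1L, ncol(m)), cls, sum)
  out <- data.frame(class = names(n_act),
                    n_active_pairs = as.integer(n_act),
                    n_targets = as.integer(n_tgt))
  out[order(-out$n_active_pairs, out$class), , drop = FALSE]
}

#' Read fingerprints from a CSV of bitstrings
#'
#' Expected columns: `id`, `bits` (a string of 0/1 characters, equal
#' lengths). This is the precomputed-fingerprint path; see
#' [fingerprints_from_smiles()] for computing from structures.
#'
#' @param path CSV file path.
#' @return Binary matrix (compounds x bits) with ids as rownames and
#'   attribute `provenance = "precomputed"`.
#' @export
read_fingerprints <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE,
                       colClasses = "character")  # keep bitstrings verbatim
  stopifnot(all(c("id", "bits") %in% names(d)), !anyDuplicated(d$id))
  lens <- nchar(d$bits)
  if (length(unique(lens)) != 1)
    stop("fingerprint bit lengths differ", call. = FALSE)
  m <- do.call(rbind, lapply(strsplit(d$bits, ""), as.integer))
  rownames(m) <- d$id
  attr(m, "provenance") <- "precomputed"
  m
}

#' Compute fingerprints from SMILES (optional toolkit path)
#'
#' Delegates to the OpenBabel toolkit (via the ChemmineOB package, if
#' installed) to compute path-based FP2 fingerprints from SMILES. Note:
#' FP2 is a linear-fragment fingerprint, not a circular/ECFP one;
#' clustering built on it is a structural-similarity surrogate. When the
#' toolkit is unavailable use [read_fingerprints()] with precomputed
#' bits.
#'
#' @param smiles Named character vector of SMILES (names are ids).
#' @return Binary matrix with attribute `provenance = "computed-from-smiles"`.
#' @export
fingerprints_from_smiles <- function(smiles) {
  if (!requireNamespace("ChemmineOB", quietly = TRUE))
    stop("ChemmineOB is not installed; supply precomputed fingerprints ",
         "via read_fingerprints()", call. = FALSE)
  ids <- names(smiles) %||% sprintf("C%02d", seq_along(smiles))
  fps <- lapply(smiles, function(s) {
    ChemmineOB::fingerprint_OB(ChemmineOB::forEachMol("SMILES", s,
                                                      identity), "FP2")
  })
  m <- do.call(rbind, lapply(fps, function(f) as.integer(f[1, ] > 0)))
  rownames(m) <- ids
  attr(m, "provenance") <- "computed-from-smiles"
  m
}
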